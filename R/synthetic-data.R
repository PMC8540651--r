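## Deterministic synthetic fixtures. These generators encode ground truth,
## not physics: toy pockets with scripted contact residues around a reactive
## cysteine, ligands of prescribed composition, pose ensembles with exactly
## prescribed heavy-atom RMSD, a covalent-geometry complex built at bond
## length, and scripted trajectories with loop opening and binding events.
## Residue numbering reuses the TRPA1 landmarks (C621, and the N615/Q676
## gate atoms) so analysis defaults apply to fixtures unchanged.

## residue templates: anchor atom first (placed closest to the site), then
## atoms at increasing outward depth
RES_TEMPLATES <- list(
  CYS = data.frame(name = c("SG", "CB", "CA", "N"),
                   element = c("S", "C", "C", "N"),
                   depth = c(0, 1.8, 3.3, 4.8), stringsAsFactors = FALSE),
  ASN = data.frame(name = c("N", "CA", "CB", "CG", "OD1"),
                   element = c("N", "C", "C", "C", "O"),
                   depth = c(0, 1.5, 3.0, 4.5, 5.7), stringsAsFactors = FALSE),
  GLN = data.frame(name = c("OE1", "CD", "CG", "CB", "CA", "N"),
                   element = c("O", "C", "C", "C", "C", "N"),
                   depth = c(0, 1.2, 2.7, 4.2, 5.7, 7.1),
                   stringsAsFactors = FALSE),
  LEU = data.frame(name = c("CD1", "CG", "CB", "CA", "N"),
                   element = c("C", "C", "C", "C", "N"),
                   depth = c(0, 1.5, 3.0, 4.5, 6.0), stringsAsFactors = FALSE),
  PHE = data.frame(name = c("CZ", "CE1", "CD1", "CG", "CB", "CA"),
                   element = c("C", "C", "C", "C", "C", "C"),
                   depth = c(0, 1.4, 2.8, 4.2, 5.7, 7.2),
                   stringsAsFactors = FALSE),
  SER = data.frame(name = c("OG", "CB", "CA", "N"),
                   element = c("O", "C", "C", "N"),
                   depth = c(0, 1.4, 2.9, 4.4), stringsAsFactors = FALSE)
)

## element-level parameter rows (AMBER-like magnitudes) covering every
## element the generators emit
default_element_params <- function() {
  param_set(data.frame(
    res_name = "", atom_name = "",
    element = c("C", "N", "O", "S", "H"),
    charge = c(0.05, -0.35, -0.40, -0.15, 0.10),
    eps = c(0.086, 0.170, 0.210, 0.250, 0.0157),
    rmin_half = c(1.908, 1.824, 1.661, 2.000, 0.600),
    solv_S = c(-0.00143, -0.00162, -0.00251, -0.00214, 0.00051),
    solv_V = c(33.51, 22.45, 17.16, 33.51, 0.0),
    hb = c("none", "donor", "acceptor", "none", "none"),
    stringsAsFactors = FALSE
  ))
}

## evenly spread unit directions (spherical Fibonacci lattice), jittered a
## little so different seeds give different pockets
pocket_directions <- function(n, jitter_sd = 0.05) {
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  th <- golden * (k - 1)
  u <- cbind(rho * cos(th), rho * sin(th), z)
  u <- u + matrix(stats::rnorm(3 * n, sd = jitter_sd), n, 3)
  u / sqrt(rowSums(u^2))
}

#' Generate a toy binding pocket around a reactive cysteine
#'
#' Places `n_residues` small residues on directions spread around a site
#' center. The anchor atom of each of the first `n_contact` residues sits
#' exactly `contact_dist` from the center (within heavy-atom contact range
#' of a site-centered ligand); the remaining residues sit at `far_dist`,
#' outside contact range. One residue is the reactive cysteine C621 with
#' its `SG` anchor; the N615/Q676 gate residues are included next when room
#' allows. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param n_residues number of residues (>= 1).
#' @param includes_reactive_cys place CYS 621 as the first residue.
#' @param n_contact how many residues (in roster order) are in scripted
#'   contact with a site-centered ligand; default all.
#' @param contact_dist,far_dist anchor-atom distances from the site center,
#'   Angstrom.
#' @return list with `structure` (the pocket, protein role), `params`
#'   (a [param_set()] resolving every generated atom), `contact_residues`
#'   (data frame of the scripted contact residues), `site_center`, and
#'   `cys` (an [atom_spec()] for the reactive sulfur, or `NULL`).
#' @export
make_toy_pocket <- function(seed, n_residues = 8, includes_reactive_cys = TRUE,
                            n_contact = n_residues,
                            contact_dist = 2.9, far_dist = 7.5) {
  stopifnot(n_residues >= 1, n_contact >= 0, n_contact <= n_residues,
            far_dist > contact_dist)
  set.seed(seed)
  roster <- list()
  if (includes_reactive_cys)
    roster[[length(roster) + 1L]] <- list(resname = "CYS", resno = 621L)
  if (length(roster) < n_residues)
    roster[[length(roster) + 1L]] <- list(resname = "ASN", resno = 615L)
  if (length(roster) < n_residues)
    roster[[length(roster) + 1L]] <- list(resname = "GLN", resno = 676L)
  filler_names <- c("LEU", "PHE", "SER")
  filler_no <- setdiff(610:700, c(615L, 621L, 676L))
  k <- 0L
  while (length(roster) < n_residues) {
    k <- k + 1L
    roster[[length(roster) + 1L]] <-
      list(resname = filler_names[(k - 1L) %% length(filler_names) + 1L],
           resno = filler_no[k])
  }
  roster <- roster[seq_len(n_residues)]
  u <- pocket_directions(n_residues)
  rows <- list()
  serial <- 0L
  for (i in seq_len(n_residues)) {
    tpl <- RES_TEMPLATES[[roster[[i]]$resname]]
    base <- if (i <= n_contact) contact_dist else far_dist
    ## perpendicular offsets keep |pos| >= base + depth, so the anchor stays
    ## the nearest atom of its residue
    perp <- pick_perpendicular(u[i, ])
    for (j in seq_len(nrow(tpl))) {
      serial <- serial + 1L
      pos <- u[i, ] * (base + tpl$depth[j]) +
        perp * 0.4 * ((j - 1) %% 2)
      rows[[serial]] <- data.frame(
        serial = serial, name = tpl$name[j], element = tpl$element[j],
        chain = "A", resno = roster[[i]]$resno,
        resname = roster[[i]]$resname,
        x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  contact <- do.call(rbind, lapply(roster[seq_len(n_contact)], function(r)
    data.frame(chain = "A", resno = r$resno, resname = r$resname,
               stringsAsFactors = FALSE)))
  if (is.null(contact))
    contact <- data.frame(chain = character(), resno = integer(),
                          resname = character(), stringsAsFactors = FALSE)
  list(structure = structure3d(atoms, role = "protein"),
       params = default_element_params(),
       contact_residues = contact,
       site_center = c(0, 0, 0),
       cys = if (includes_reactive_cys) atom_spec(621, "SG") else NULL)
}

pick_perpendicular <- function(v) {
  w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- w - sum(w * v) * v
  p / sqrt(sum(p^2))
}

#' Generate a compact ligand of prescribed composition
#'
#' Heavy atoms (and optional hydrogens) are placed deterministically inside
#' a small sphere, so a site-centered ligand contacts exactly the scripted
#' pocket residues. `make_bitc_ligand()` emits the benzyl isothiocyanate
#' composition (8 C, 1 N, 1 S, 7 H; 10 heavy atoms) with the isothiocyanate
#' carbon `C7` annotated as the electrophilic warhead.
#'
#' @param seed integer seed.
#' @param composition named integer vector of heavy-atom element counts,
#'   e.g. `c(C = 8, N = 1, S = 1)`.
#' @param n_hydrogen number of hydrogens to add.
#' @param center 3-vector, Angstrom.
#' @param spread placement radius, Angstrom.
#' @param resname,resno ligand residue identity (default `LIG` 900).
#' @return list with `structure` (ligand role) and `warhead` (an
#'   [atom_spec()] for the first sulfur-adjacent carbon, or the first heavy
#'   atom when the composition has no marked warhead).
#' @export
make_ligand <- function(seed, composition = c(C = 8, N = 1, S = 1),
                        n_hydrogen = 7, center = c(0, 0, 0), spread = 0.35,
                        resname = "LIG", resno = 900L) {
  stopifnot(sum(composition) >= 1, n_hydrogen >= 0, spread >= 0)
  set.seed(seed)
  elements <- rep(names(composition), composition)
  counts <- stats::setNames(rep(0L, length(unique(elements))),
                            unique(elements))
  names_out <- character(length(elements))
  for (i in seq_along(elements)) {
    counts[elements[i]] <- counts[elements[i]] + 1L
    names_out[i] <- paste0(elements[i], counts[elements[i]])
  }
  all_el <- c(elements, rep("H", n_hydrogen))
  all_names <- c(names_out, if (n_hydrogen > 0) paste0("H", seq_len(n_hydrogen)))
  n <- length(all_el)
  pos <- matrix(stats::rnorm(3 * n), n, 3)
  nrm <- sqrt(rowSums(pos^2))
  radius <- spread * stats::runif(n)^(1 / 3)
  pos <- pos / nrm * radius
  pos <- sweep(pos, 2, center, "+")
  atoms <- data.frame(serial = seq_len(n), name = all_names,
                      element = all_el, chain = "L",
                      resno = as.integer(resno), resname = resname,
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      stringsAsFactors = FALSE)
  warhead_name <- if (any(elements == "C")) {
    paste0("C", sum(elements == "C"))  # last carbon: the electrophile
  } else names_out[1]
  list(structure = structure3d(atoms, role = "ligand", model = 1L),
       warhead = atom_spec(resno, warhead_name))
}

#' @rdname make_ligand
#' @export
make_bitc_ligand <- function(seed = 1, center = c(0, 0, 0), spread = 0.35) {
  out <- make_ligand(seed, composition = c(C = 8, N = 1, S = 1),
                     n_hydrogen = 7, center = center, spread = spread)
  out$warhead <- atom_spec(900L, "C8")
  out
}

#' Build a covalent-geometry complex (synthetic)
#'
#' A toy pocket plus a ligand positioned so that its warhead carbon lies at
#' exactly `bond_length` (default 1.8 Angstrom, a typical C-S single bond)
#' from the C621 sulfur -- a synthetic stand-in for a deposited covalent
#' complex, used to exercise covalent-geometry measurements.
#'
#' @param seed integer seed.
#' @param bond_length warhead-to-sulfur distance, Angstrom.
#' @param n_residues pocket size.
#' @return list with `target`, `ligand`, `warhead`, `params`, `site`
#'   (C621 `SG` spec) and `bond_length`.
#' @export
make_covalent_complex <- function(seed, bond_length = 1.8, n_residues = 6) {
  pocket <- make_toy_pocket(seed, n_residues = n_residues,
                            includes_reactive_cys = TRUE)
  lig <- make_bitc_ligand(seed + 1, center = c(0, 0, 0), spread = 0.35)
  tgt <- pocket$structure
  sg <- coords_of(tgt)[resolve_atom(tgt, pocket$cys), ]
  inward <- pocket$site_center - sg
  inward <- inward / sqrt(sum(inward^2))
  goal <- sg + bond_length * inward
  wh_idx <- resolve_atom(lig$structure, lig$warhead)
  shift <- goal - coords_of(lig$structure)[wh_idx, ]
  lig$structure <- set_coords(lig$structure,
                              sweep(coords_of(lig$structure), 2, shift, "+"))
  list(target = tgt, ligand = lig$structure, warhead = lig$warhead,
       params = pocket$params, site = pocket$cys, bond_length = bond_length)
}

#' Generate a pose ensemble with prescribed RMSD values
#'
#' Each pose is the reference displaced by a rigid translation plus
#' per-atom Gaussian jitter, with the displacement field rescaled so the
#' achieved heavy-atom RMSD equals the requested target (the RMSD of
#' `reference + s * D` is linear in `s`, so the scale is exact). A target of
#' 0 reproduces the reference.
#'
#' @param reference ligand [structure3d()].
#' @param rmsd_targets non-negative RMSD targets, Angstrom.
#' @param energies calculated free energies, one per pose, kcal/mol.
#' @param seed integer seed.
#' @param warhead optional [atom_spec()] annotation carried on the
#'   ensemble.
#' @return a [pose_ensemble()] whose pose `i` has heavy-atom RMSD
#'   `rmsd_targets[i]` to `reference`.
#' @export
make_pose_ensemble <- function(reference, rmsd_targets, energies, seed,
                               warhead = NULL) {
  stopifnot(is.structure3d(reference),
            length(rmsd_targets) == length(energies))
  if (any(rmsd_targets < 0))
    stop("RMSD targets must be 0 or positive")
  set.seed(seed)
  n <- nrow(reference$atoms)
  heavy <- reference$atoms$is_heavy
  poses <- vector("list", length(rmsd_targets))
  for (i in seq_along(rmsd_targets)) {
    target <- rmsd_targets[i]
    if (target == 0) {
      poses[[i]] <- reference
      next
    }
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    D <- matrix(dir, n, 3, byrow = TRUE) + matrix(stats::rnorm(3 * n, sd = 0.3), n, 3)
    achieved <- sqrt(mean(rowSums(D[heavy, , drop = FALSE]^2)))
    s <- target / achieved
    poses[[i]] <- set_coords(reference, coords_of(reference) + s * D)
  }
  pose_ensemble(reference, poses, energies, warhead = warhead)
}

## ---- scripted trajectories --------------------------------------------------

#' Script a trajectory scenario
#'
#' Declares the qualitative outcome of a simulated binding experiment: loop
#' behaviour (constant closed, constant open, or a closed-to-open ramp) and
#' the ligand's bound/unbound segments. The four kinds mirror the canonical
#' outcomes of the analysed simulations: nothing happens (`static`), an
#' unbinding-binding excursion with a stable open loop (`unbind_rebind`),
#' loop opening with dissociation then re-association
#' (`loop_open_reassociate`), and dissociation with no loop change
#' (`dissociate_only`).
#'
#' @param kind scenario kind.
#' @param n_frames number of frames.
#' @param event_frames frames at which the ligand changes binding state
#'   (defaults per kind: none; 30, 60; 20, 80; 30).
#' @param closed_dist,open_dist gate-atom distances of the closed and open
#'   loop plateaus, Angstrom (`open_dist > closed_dist`).
#' @param loop_open_frame first frame of the closed-to-open ramp
#'   (`loop_open_reassociate` only; default midway between the two events).
#' @param ramp_frames length of the opening ramp, frames.
#' @param noise isotropic Gaussian positional noise per atom per frame,
#'   Angstrom (default 0.1).
#' @param dt frame spacing, ps.
#' @param seed integer seed.
#' @return an object of class `scenario_script`.
#' @export
scenario_script <- function(kind = c("static", "unbind_rebind",
                                     "loop_open_reassociate",
                                     "dissociate_only"),
                            n_frames = 100, event_frames = NULL,
                            closed_dist = 6, open_dist = 14,
                            loop_open_frame = NULL, ramp_frames = 20,
                            noise = 0.1, dt = 1, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(event_frames)) {
    ## defaults scale with the run length
    frac <- switch(kind,
                   static = numeric(0),
                   unbind_rebind = c(0.3, 0.6),
                   loop_open_reassociate = c(0.2, 0.8),
                   dissociate_only = 0.3)
    event_frames <- pmax(2L, as.integer(round(frac * n_frames)))
  }
  n_events <- switch(kind, static = 0L, unbind_rebind = 2L,
                     loop_open_reassociate = 2L, dissociate_only = 1L)
  if (length(event_frames) != n_events)
    stop("scenario '", kind, "' needs ", n_events, " event frame(s)")
  if (n_events > 0 &&
      (any(event_frames < 2) || any(event_frames > n_frames) ||
       any(diff(event_frames) <= 0)))
    stop("event frames must be increasing and within 2..n_frames")
  if (!(open_dist > closed_dist))
    stop("open_dist must exceed closed_dist")
  if (kind == "loop_open_reassociate" && is.null(loop_open_frame))
    loop_open_frame <- floor(mean(event_frames))
  out <- list(kind = kind, n_frames = as.integer(n_frames),
              event_frames = as.integer(event_frames),
              closed_dist = closed_dist, open_dist = open_dist,
              loop_open_frame = loop_open_frame,
              ramp_frames = as.integer(ramp_frames),
              noise = noise, dt = dt, seed = as.integer(seed))
  class(out) <- "scenario_script"
  out
}

## per-frame bound flags implied by a script
script_bound_states <- function(script) {
  bound <- rep(TRUE, script$n_frames)
  ev <- script$event_frames
  if (script$kind == "dissociate_only") {
    bound[ev[1]:script$n_frames] <- FALSE
  } else if (script$kind %in% c("unbind_rebind", "loop_open_reassociate")) {
    bound[ev[1]:(ev[2] - 1L)] <- FALSE
  }
  bound
}

## per-frame gate distances implied by a script
script_gate_distances <- function(script) {
  nf <- script$n_frames
  if (script$kind == "unbind_rebind")
    return(rep(script$open_dist, nf))
  if (script$kind != "loop_open_reassociate")
    return(rep(script$closed_dist, nf))
  d <- rep(script$closed_dist, nf)
  start <- script$loop_open_frame
  end <- min(nf, start + script$ramp_frames - 1L)
  ramp <- seq(script$closed_dist, script$open_dist,
              length.out = end - start + 1L)
  d[start:end] <- ramp
  if (end < nf) d[(end + 1L):nf] <- script$open_dist
  d
}

#' Generate a scripted trajectory
#'
#' Combines a toy pocket and a ligand into a multi-frame system in which
#' (a) the N615 `N` / Q676 `OE1` gate distance follows the scripted
#' closed/open profile (residue 676 is translated rigidly along the gate
#' axis), (b) the ligand center jumps between its bound (site-centered)
#' position and a remote unbound position at the scripted event frames, and
#' (c) isotropic Gaussian noise of the scripted amplitude is added to every
#' coordinate of every frame. Deterministic per script seed.
#'
#' @param script a [scenario_script()].
#' @param pocket a toy pocket from [make_toy_pocket()] (must contain
#'   residues 615 and 676), or its `structure` element.
#' @param ligand a ligand [structure3d()] in its bound position, or a
#'   [make_ligand()] result.
#' @param unbound_offset displacement applied to the ligand while unbound,
#'   Angstrom (default 25 along +z: far outside both the 3.5 contact and
#'   the 11 nonbonded cutoffs).
#' @return a [trajectory3d()] of pocket + ligand atoms.
#' @export
make_trajectory <- function(script, pocket, ligand,
                            unbound_offset = c(0, 0, 25)) {
  stopifnot(inherits(script, "scenario_script"))
  if (is.list(pocket) && !is.structure3d(pocket)) pocket <- pocket$structure
  if (is.list(ligand) && !is.structure3d(ligand)) ligand <- ligand$structure
  stopifnot(is.structure3d(pocket), is.structure3d(ligand))
  set.seed(script$seed)
  atoms <- rbind(pocket$atoms, ligand$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  n_pocket <- nrow(pocket$atoms)
  n <- nrow(atoms)
  base <- as.matrix(atoms[, c("x", "y", "z")])

  proto <- structure3d(atoms, role = "protein")
  i_gate_a <- resolve_atom(proto, atom_spec(615, "N"))
  i_gate_b <- resolve_atom(proto, atom_spec(676, "OE1"))
  rows_676 <- which(atoms$resno == 676 & seq_len(n) <= n_pocket)
  axis <- base[i_gate_b, ] - base[i_gate_a, ]
  d0 <- sqrt(sum(axis^2))
  axis <- axis / d0

  gate_d <- script_gate_distances(script)
  bound <- script_bound_states(script)
  lig_rows <- (n_pocket + 1L):n

  coords <- array(NA_real_, c(n, 3L, script$n_frames))
  for (f in seq_len(script$n_frames)) {
    xyz <- base
    shift <- (gate_d[f] - d0)
    xyz[rows_676, ] <- sweep(xyz[rows_676, , drop = FALSE], 2,
                             shift * axis, "+")
    if (!bound[f])
      xyz[lig_rows, ] <- sweep(xyz[lig_rows, , drop = FALSE], 2,
                               unbound_offset, "+")
    if (script$noise > 0)
      xyz <- xyz + matrix(stats::rnorm(3 * n, sd = script$noise), n, 3)
    coords[, , f] <- xyz
  }
  trajectory3d(atoms, coords,
               times = (seq_len(script$n_frames) - 1L) * script$dt,
               role = "protein")
}
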