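## Trajectory analytics: per-residue Lennard-Jones interaction profiles,
## loop-gating distance series with open/closed classification, and
## binding/unbinding event detection with dwell-based hysteresis.

#' Per-residue Lennard-Jones interaction profile
#'
#' For each selected target residue and each frame, sums the 12-6 pair
#' energy ([lj_energy()]) over all ligand-atom/residue-atom pairs within the
#' nonbonded cutoff. Interaction profiling is deliberately LJ-only;
#' electrostatics are not part of the profile. A per-frame contact count
#' (number of residues with any heavy-atom pair within `contact_cutoff`)
#' accompanies the energy matrix and drives [detect_binding_events()].
#'
#' @param traj a parameterized [trajectory3d()] containing protein and
#'   ligand atoms.
#' @param ligand residue name identifying the ligand atoms (default
#'   `"LIG"`), or an integer vector of atom row indices.
#' @param residues optional character vector of residue keys
#'   (`"chain/resno/resname"`) to profile; default all non-ligand residues.
#' @param cutoff nonbonded cutoff for the energy sums, Angstrom (default
#'   11).
#' @param contact_cutoff heavy-atom contact distance, Angstrom (default
#'   3.5, the same cutoff that defines binding pockets).
#' @return an object of class `interaction_profile`: list with `energy`
#'   (residues x frames matrix, kcal/mol), `contacts` (per-frame residue
#'   contact count), `times`, `residues`, `cutoff`, `contact_cutoff`.
#' @export
per_residue_lj_profile <- function(traj, ligand = "LIG", residues = NULL,
                                   cutoff = 11, contact_cutoff = 3.5) {
  stopifnot(is.trajectory3d(traj))
  require_parameters(traj, "trajectory")
  a <- traj$atoms
  lig_idx <- if (is.numeric(ligand)) as.integer(ligand)
             else which(a$resname == ligand)
  if (length(lig_idx) == 0L) stop("ligand selection matches no atoms")
  prot_idx <- setdiff(seq_len(nrow(a)), lig_idx)
  keys <- paste(a$chain, a$resno, a$resname, sep = "/")
  if (is.null(residues)) residues <- unique(keys[prot_idx])
  missing_res <- setdiff(residues, keys[prot_idx])
  if (length(missing_res) > 0L)
    stop("residues not present in trajectory: ",
         paste(missing_res, collapse = ", "))
  nf <- n_frames(traj)
  energy <- matrix(0, length(residues), nf,
                   dimnames = list(residues, NULL))
  contacts <- integer(nf)
  lig_heavy <- lig_idx[a$is_heavy[lig_idx]]
  res_rows <- lapply(residues, function(k) prot_idx[keys[prot_idx] == k])
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f]
    lx <- xyz[lig_idx, , drop = FALSE]
    in_contact <- logical(length(residues))
    for (j in seq_along(residues)) {
      rows <- res_rows[[j]]
      rx <- xyz[rows, , drop = FALSE]
      r2 <- pair_dist2(lx, rx)
      r2[r2 < 0] <- 0
      r <- sqrt(r2)
      within <- r <= cutoff
      if (any(within)) {
        e <- lj_kernel(matrix(a$eps[lig_idx], length(lig_idx), length(rows)),
                       matrix(a$eps[rows], length(lig_idx), length(rows),
                              byrow = TRUE),
                       matrix(a$rmin_half[lig_idx], length(lig_idx),
                              length(rows)),
                       matrix(a$rmin_half[rows], length(lig_idx),
                              length(rows), byrow = TRUE),
                       pmax(r, 1e-12))
        energy[j, f] <- sum(e[within])
      }
      heavy_rows <- rows[a$is_heavy[rows]]
      if (length(heavy_rows) > 0L && length(lig_heavy) > 0L) {
        hr <- r[match(lig_heavy, lig_idx), match(heavy_rows, rows),
                drop = FALSE]
        in_contact[j] <- any(hr <= contact_cutoff)
      }
    }
    contacts[f] <- sum(in_contact)
  }
  out <- list(energy = energy, contacts = contacts, times = traj$times,
              residues = residues, cutoff = cutoff,
              contact_cutoff = contact_cutoff)
  class(out) <- "interaction_profile"
  out
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat(sprintf("<interaction_profile> %d residues x %d frames (LJ, cutoff %g A)\n",
              nrow(x$energy), ncol(x$energy), x$cutoff))
  invisible(x)
}

#' Loop-gating distance series (d_LOOPS)
#'
#' Per-frame Euclidean distance between two gate atoms -- by default the
#' N615 backbone nitrogen of the A-loop and the Q676 side-chain oxygen of
#' the opposite loop, a distance that tracks A-loop opening and closing.
#'
#' @param traj a [trajectory3d()].
#' @param atom_a,atom_b [atom_spec()]s for the two gate atoms.
#' @return an object of class `loop_gate_series`: list with `times` (ps),
#'   `d` (Angstrom) and the atom pair.
#' @export
loop_distance_series <- function(traj,
                                 atom_a = atom_spec(615, "N"),
                                 atom_b = atom_spec(676, "OE1")) {
  stopifnot(is.trajectory3d(traj))
  s <- structure3d(traj$atoms, role = traj$role)
  i <- resolve_atom(s, atom_a)
  j <- resolve_atom(s, atom_b)
  ca <- matrix(traj$coords[i, , ], nrow = 3)  # robust to 1-frame drop
  cb <- matrix(traj$coords[j, , ], nrow = 3)
  d <- sqrt(colSums((ca - cb)^2))
  out <- list(times = traj$times, d = as.numeric(d),
              atom_a = atom_a, atom_b = atom_b)
  class(out) <- "loop_gate_series"
  out
}

#' @export
print.loop_gate_series <- function(x, ...) {
  cat(sprintf("<loop_gate_series> %s - %s: %d frames, d = %.2f..%.2f A\n",
              format(x$atom_a), format(x$atom_b), length(x$d),
              min(x$d), max(x$d)))
  invisible(x)
}

#' Classify loop frames as open, closed or intermediate
#'
#' Thresholds are inclusive towards the extreme states: a frame is `open`
#' when `d >= open_threshold`, `closed` when `d <= closed_threshold`, and
#' `intermediate` otherwise. No default thresholds are provided for real
#' data; for synthetic fixtures the midpoints of the scripted plateaus are
#' natural choices.
#'
#' @param series a [loop_distance_series()] result.
#' @param open_threshold,closed_threshold distances in Angstrom with
#'   `open_threshold > closed_threshold`.
#' @return factor of per-frame states with levels
#'   `closed < intermediate < open`.
#' @export
classify_loop_state <- function(series, open_threshold, closed_threshold) {
  stopifnot(inherits(series, "loop_gate_series"))
  if (!(open_threshold > closed_threshold))
    stop("open_threshold must exceed closed_threshold")
  state <- rep("intermediate", length(series$d))
  state[series$d >= open_threshold] <- "open"
  state[series$d <= closed_threshold] <- "closed"
  factor(state, levels = c("closed", "intermediate", "open"), ordered = TRUE)
}

#' Detect binding and unbinding events
#'
#' The ligand is bound in a frame when its residue contact count reaches
#' `min_contacts`. Dwell-based hysteresis suppresses single-frame flicker:
#' contiguous runs of a state shorter than `dwell` frames are merged into
#' the neighboring state before transitions are read off. Each bound ->
#' unbound transition is a dissociation, each unbound -> bound transition an
#' association; events therefore alternate in kind.
#'
#' @param profile an [per_residue_lj_profile()] result (its `contacts`
#'   series is used).
#' @param min_contacts minimum residue contact count for the bound state
#'   (default 1).
#' @param dwell minimum run length, in frames, for a state to count
#'   (default 5).
#' @return data frame with columns `kind` (`"dissociation"` /
#'   `"association"`), `frame` (first frame of the new state) and `time`
#'   (ps); zero rows when no sustained transition occurs.
#' @export
detect_binding_events <- function(profile, min_contacts = 1, dwell = 5) {
  stopifnot(inherits(profile, "interaction_profile"), dwell >= 1,
            min_contacts >= 1)
  bound <- profile$contacts >= min_contacts
  runs <- rle(bound)
  ## merge runs shorter than dwell into their left neighbor (or right for a
  ## short leading run) until every surviving run is sustained
  repeat {
    short <- which(runs$lengths < dwell)
    if (length(short) == 0L || length(runs$lengths) == 1L) break
    k <- short[1]
    into <- if (k > 1L) k - 1L else k + 1L
    runs$lengths[into] <- runs$lengths[into] + runs$lengths[k]
    runs$lengths <- runs$lengths[-k]
    runs$values <- runs$values[-k]
    ## collapse now-adjacent equal states
    if (length(runs$values) > 1L) {
      keep <- c(TRUE, diff(as.integer(runs$values)) != 0)
      if (!all(keep)) {
        lengths2 <- tapply(runs$lengths, cumsum(keep), sum)
        runs$values <- runs$values[keep]
        runs$lengths <- as.integer(lengths2)
      }
    }
  }
  if (length(runs$values) <= 1L)
    return(data.frame(kind = character(), frame = integer(),
                      time = numeric(), stringsAsFactors = FALSE))
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  trans <- seq_along(runs$values)[-1]
  data.frame(
    kind = ifelse(runs$values[trans], "association", "dissociation"),
    frame = starts[trans],
    time = profile$times[starts[trans]],
    stringsAsFactors = FALSE
  )
}
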