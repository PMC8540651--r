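# Fixture builders and independent oracles used across the suite. The
# oracles deliberately re-derive quantities with naive arithmetic so they
# stay independent of the package's code paths.

# coordinate accessor kept local to the tests
coords_of_test <- function(s) unname(as.matrix(s$atoms[, c("x", "y", "z")]))

# minimal atom table builder
atom_df <- function(names, elements, xyz, resno = 1L, resname = "GLY",
                    chain = "A") {
  n <- length(names)
  data.frame(serial = seq_len(n), name = names, element = elements,
             chain = chain, resno = resno, resname = resname,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# two-heavy-atom ligand at given coordinates
two_atom_ligand <- function(xyz, resname = "LIG", resno = 900L) {
  structure3d(atom_df(c("C1", "C2"), c("C", "C"), xyz,
                      resno = resno, resname = resname, chain = "L"),
              role = "ligand")
}

translate_structure <- function(s, v) {
  a <- s$atoms
  a$x <- a$x + v[1]; a$y <- a$y + v[2]; a$z <- a$z + v[3]
  structure3d(a, role = s$role)
}

# heavy-atom rmsd computed naively, assuming identical atom order
naive_rmsd <- function(a, b) {
  ha <- a$atoms[a$atoms$is_heavy, c("x", "y", "z")]
  hb <- b$atoms[b$atoms$is_heavy, c("x", "y", "z")]
  sqrt(mean(rowSums((as.matrix(ha) - as.matrix(hb))^2)))
}

# brute-force implementation of the energy-sorted seed-relative clustering
# protocol: returns a list of sorted member-index vectors, in rank order
oracle_cluster <- function(poses, energies, threshold = 2.0) {
  remaining <- seq_along(poses)
  clusters <- list()
  while (length(remaining) > 0L) {
    seed <- remaining[which.min(energies[remaining])]
    within <- vapply(remaining, function(i)
      naive_rmsd(poses[[seed]], poses[[i]]) <= threshold, logical(1))
    members <- remaining[within]
    clusters[[length(clusters) + 1L]] <- sort(members)
    remaining <- setdiff(remaining, members)
  }
  clusters
}

# direct 12-6 evaluation (combining rules written out long-hand)
oracle_lj <- function(eps_i, eps_j, ri, rj, r) {
  eps_ij <- sqrt(eps_i * eps_j)
  Rij <- ri + rj
  (eps_ij * Rij^12) / r^12 - (2 * eps_ij * Rij^6) / r^6
}

# total ligand-protein LJ energy of one trajectory frame, summed naively
# over all pairs within the cutoff
oracle_frame_lj_total <- function(traj, frame, ligand_resname = "LIG",
                                  cutoff = 11) {
  a <- traj$atoms
  xyz <- traj$coords[, , frame]
  lig <- which(a$resname == ligand_resname)
  prot <- setdiff(seq_len(nrow(a)), lig)
  total <- 0
  for (i in lig) for (j in prot) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r <= cutoff)
      total <- total + oracle_lj(a$eps[i], a$eps[j],
                                 a$rmin_half[i], a$rmin_half[j], r)
  }
  total
}

# a tiny parameter set with one named row and element fallbacks
tiny_param_set <- function() {
  param_set(data.frame(
    res_name = c("CYS", "", ""),
    atom_name = c("SG", "", ""),
    element = c("S", "C", "H"),
    charge = c(-0.3, 0.1, 0.05),
    eps = c(0.25, 0.086, 0.0157),
    rmin_half = c(2.0, 1.908, 0.6),
    solv_S = c(-0.002, -0.001, 0.0005),
    solv_V = c(33.5, 33.5, 0),
    stringsAsFactors = FALSE
  ))
}
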