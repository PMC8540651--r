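# small parameterized scenario trajectory used across this file
scenario_traj <- function(kind, seed = 1, noise = 0.1, n_frames = 100, ...) {
  pk <- make_toy_pocket(seed, n_residues = 5, n_contact = 5)
  lig <- make_bitc_ligand(seed + 1000)
  sc <- scenario_script(kind, n_frames = n_frames, noise = noise,
                        seed = seed, ...)
  tr <- make_trajectory(sc, pk, lig)
  list(traj = assign_parameters(tr, pk$params), script = sc, pocket = pk)
}

test_that("per-residue LJ profile reduces to single-pair energies and zero columns", {
  # single residue, single atom pair: the profile entry is lj_energy
  a1 <- atom_df("CA", "C", rbind(c(0, 0, 0)), resno = 10L, resname = "GLY")
  a2 <- atom_df("C1", "C", rbind(c(3, 0, 0)), resno = 900L, resname = "LIG")
  atoms <- rbind(a1, a2); atoms$serial <- 1:2
  coords <- array(c(0, 3, 0, 0, 0, 0, 0, 4, 0, 0, 0, 0), c(2, 3, 2))
  tr <- trajectory3d(atoms, coords)
  tr <- assign_parameters(tr, tiny_param_set())
  pr <- per_residue_lj_profile(tr, ligand = "LIG")
  expect_equal(dim(pr$energy), c(1, 2))
  expect_equal(unname(pr$energy[1, 1]),
               lj_energy(list(eps = 0.086, rmin_half = 1.908),
                         list(eps = 0.086, rmin_half = 1.908), r = 3))
  expect_equal(unname(pr$energy[1, 2]),
               lj_energy(list(eps = 0.086, rmin_half = 1.908),
                         list(eps = 0.086, rmin_half = 1.908), r = 4))
  # ligand far beyond the cutoff in a frame -> all-zero column
  coords[2, , 2] <- c(40, 0, 0)
  tr2 <- assign_parameters(trajectory3d(atoms, coords), tiny_param_set())
  pr2 <- per_residue_lj_profile(tr2, ligand = "LIG")
  expect_equal(pr2$energy[, 2], c("A/10/GLY" = 0))
  expect_equal(pr2$contacts[2], 0)
})

test_that("profile columns sum to the total LJ energy within the cutoff", {
  st <- scenario_traj("unbind_rebind", seed = 12, n_frames = 20)
  pr <- per_residue_lj_profile(st$traj)
  for (f in c(1, 7, 14, 20)) {
    total <- oracle_frame_lj_total(st$traj, f)
    expect_equal(sum(pr$energy[, f]), total, tolerance = 1e-6)
  }
})

test_that("interaction appears when bound, vanishes when dissociated, deepens on approach", {
  st <- scenario_traj("dissociate_only", seed = 4, n_frames = 60,
                      event_frames = 30)
  pr <- per_residue_lj_profile(st$traj)
  # bound frames interact; after dissociation every column is zero
  expect_gt(abs(sum(pr$energy[, 5])), 0.01)
  expect_equal(sum(pr$energy[, 55]), 0)
  # a scripted approach toward the LJ minimum makes the energy more negative
  a1 <- atom_df("CA", "C", rbind(c(0, 0, 0)), resno = 10L, resname = "GLY")
  a2 <- atom_df("C1", "C", rbind(c(6, 0, 0)), resno = 900L, resname = "LIG")
  atoms <- rbind(a1, a2); atoms$serial <- 1:2
  coords <- array(0, c(2, 3, 2))
  coords[2, 1, 1] <- 6      # start: far apart
  coords[2, 1, 2] <- 3.816  # contact frame: at the pair equilibrium
  tr <- assign_parameters(trajectory3d(atoms, coords), tiny_param_set())
  prof <- per_residue_lj_profile(tr)
  expect_lt(prof$energy[1, 2], prof$energy[1, 1])
  expect_equal(unname(prof$energy[1, 2]), -0.086, tolerance = 1e-6)
})

test_that("loop distance series tracks the scripted gate geometry", {
  st <- scenario_traj("static", seed = 6, noise = 0.05)
  s <- loop_distance_series(st$traj)
  expect_equal(length(s$d), 100)
  # static scenario: constant within a few noise amplitudes
  expect_lt(max(abs(s$d - mean(s$d))), 6 * 0.05 * sqrt(2) + 0.1)
  expect_equal(mean(s$d), st$script$closed_dist, tolerance = 0.2)
  # single frame reduces to one direct distance
  one <- make_trajectory(scenario_script("static", n_frames = 1, noise = 0,
                                         seed = 1),
                         st$pocket, make_bitc_ligand(7))
  s1 <- loop_distance_series(one)
  f <- frame_structure(one, 1)
  i <- which(f$atoms$resno == 615 & f$atoms$name == "N")
  j <- which(f$atoms$resno == 676 & f$atoms$name == "OE1")
  direct <- sqrt(sum((as.numeric(f$atoms[i, c("x", "y", "z")]) -
                      as.numeric(f$atoms[j, c("x", "y", "z")]))^2))
  expect_equal(s1$d, direct, tolerance = 1e-9)
  # scripted opening: final distance exceeds the first
  op <- scenario_traj("loop_open_reassociate", seed = 9)
  so <- loop_distance_series(op$traj)
  expect_gt(so$d[100] - so$d[1], 4)
  expect_error(loop_distance_series(st$traj, atom_b = atom_spec(999, "XX")),
               "not found")
})

test_that("loop-state classification is inclusive at thresholds and partitions frames", {
  st <- scenario_traj("loop_open_reassociate", seed = 10, noise = 0.05)
  s <- loop_distance_series(st$traj)
  mid_lo <- st$script$closed_dist + 1
  mid_hi <- st$script$open_dist - 1
  state <- classify_loop_state(s, open_threshold = mid_hi,
                               closed_threshold = mid_lo)
  expect_equal(length(state), length(s$d))
  expect_equal(as.character(state[1]), "closed")
  expect_equal(as.character(state[length(state)]), "open")
  # the ramp produces one contiguous intermediate run
  runs <- rle(as.character(state))
  expect_equal(sum(runs$values == "intermediate"), 1)
  # widening the gap never creates new extreme-state frames
  wide <- classify_loop_state(s, open_threshold = mid_hi + 1,
                              closed_threshold = mid_lo - 1)
  expect_true(all(which(wide == "open") %in% which(state == "open")))
  expect_true(all(which(wide == "closed") %in% which(state == "closed")))
  # boundary values belong to the extreme state
  fake <- structure(list(times = 0:2, d = c(5, 8, 11),
                         atom_a = atom_spec(615, "N"),
                         atom_b = atom_spec(676, "OE1")),
                    class = "loop_gate_series")
  expect_equal(as.character(classify_loop_state(fake, 11, 5)),
               c("closed", "intermediate", "open"))
  expect_error(classify_loop_state(fake, 5, 11), "exceed")
})

test_that("binding-event detection reports scripted transitions and alternation", {
  # always bound / never in contact -> no events
  st <- scenario_traj("static", seed = 20)
  pr <- per_residue_lj_profile(st$traj)
  expect_equal(nrow(detect_binding_events(pr)), 0)
  far <- st$traj
  far$coords[st$traj$atoms$resname == "LIG", , ] <-
    far$coords[st$traj$atoms$resname == "LIG", , ] + 100
  expect_equal(nrow(detect_binding_events(per_residue_lj_profile(far))), 0)
  # scripted dissociation is recovered within the dwell window
  sd_ <- scenario_traj("dissociate_only", seed = 21)
  ev <- detect_binding_events(per_residue_lj_profile(sd_$traj), dwell = 5)
  expect_equal(ev$kind, "dissociation")
  expect_lte(abs(ev$frame - sd_$script$event_frames[1]), 5)
  # unbind-rebind yields exactly dissociation then association
  ur <- scenario_traj("unbind_rebind", seed = 22)
  ev2 <- detect_binding_events(per_residue_lj_profile(ur$traj), dwell = 5)
  expect_equal(ev2$kind, c("dissociation", "association"))
  expect_true(all(diff(ev2$frame) > 0))
})
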