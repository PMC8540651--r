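test_that("rmsd satisfies identity, translation, and the hand-computed case", {
  ref <- two_atom_ligand(rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(rmsd(ref, ref), 0)
  # rigid translation by a norm-3 vector moves every deviation to 3
  v <- c(2, 2, 1)  # norm 3
  expect_equal(rmsd(ref, translate_structure(ref, v)), 3)
  # deviations 0 and 2 over two heavy atoms -> sqrt(4/2)
  pose <- two_atom_ligand(rbind(c(0, 0, 0), c(1.5, 2, 0)))
  expect_equal(rmsd(ref, pose), sqrt(2), tolerance = 1e-12)
  expect_equal(rmsd(ref, pose), 1.4142135624, tolerance = 1e-9)
})

test_that("rmsd is symmetric, non-negative, and translation-invariant jointly", {
  for (seed in 1:5) {
    lig <- make_bitc_ligand(seed)$structure
    pose <- make_pose_ensemble(lig, 3.1, -5, seed = seed + 100)$poses[[1]]
    expect_equal(rmsd(lig, pose), rmsd(pose, lig))
    expect_gte(rmsd(lig, pose), 0)
    v <- stats::rnorm(3)
    expect_equal(rmsd(translate_structure(lig, v),
                      translate_structure(pose, v)),
                 rmsd(lig, pose), tolerance = 1e-9)
  }
  # pairing is by name; a renamed atom is reported
  a <- two_atom_ligand(rbind(c(0, 0, 0), c(1, 0, 0)))
  b <- a; b$atoms$name[2] <- "C9"
  expect_error(rmsd(a, b), "C9")
})

test_that("warhead distance is the plain Euclidean distance and d_best its minimum", {
  lig <- two_atom_ligand(rbind(c(0, 0, 0), c(3, 0, 0)))
  cys <- structure3d(atom_df("SG", "S", rbind(c(0, 0, 0)),
                             resno = 621L, resname = "CYS"))
  expect_equal(warhead_distance(lig, atom_spec(900, "C1"), cys), 0)
  expect_equal(warhead_distance(lig, atom_spec(900, "C2"), cys), 3)
  expect_error(warhead_distance(lig, atom_spec(900, "C9"), cys), "not found")

  # ensemble minimum agrees with a naive scan (oracle)
  bitc <- make_bitc_ligand(4)
  ens <- make_pose_ensemble(bitc$structure, c(0.5, 4, 2, 7), -(9:6),
                            seed = 9, warhead = bitc$warhead)
  pocket <- make_toy_pocket(4, n_residues = 5)
  naive <- min(vapply(ens$poses, function(p)
    warhead_distance(p, bitc$warhead, pocket$structure), numeric(1)))
  expect_equal(d_best(ens, pocket$structure), naive)
})

test_that("covalent-geometry fixture reproduces the 1.8 A bond distance", {
  cc <- make_covalent_complex(17)
  d <- warhead_distance(cc$ligand, cc$warhead, cc$target, site = cc$site)
  expect_equal(d, 1.8, tolerance = 1e-9)
})

test_that("binding pocket uses inclusive heavy-atom cutoffs and is monotone", {
  # one residue anchor at 3.4 A, the next nearest at 3.6 A
  lig <- structure3d(atom_df("C1", "C", rbind(c(0, 0, 0)),
                             resno = 900L, resname = "LIG", chain = "L"),
                     role = "ligand")
  tgt <- structure3d(atom_df(c("CA", "CA"), c("C", "C"),
                             rbind(c(3.4, 0, 0), c(0, 3.6, 0)),
                             resno = c(10L, 11L), resname = "GLY"))
  p <- binding_pocket(tgt, lig)
  expect_equal(nrow(p), 1)
  expect_equal(p$resno, 10)
  # boundary inclusive at exactly the cutoff
  tgt2 <- structure3d(atom_df("CA", "C", rbind(c(3.5, 0, 0)),
                              resno = 12L, resname = "GLY"))
  expect_equal(nrow(binding_pocket(tgt2, lig)), 1)
  # far ligand -> empty pocket is allowed
  expect_equal(nrow(binding_pocket(tgt, translate_structure(lig, c(50, 0, 0)))), 0)
  # monotone in cutoff
  pk <- make_toy_pocket(8, n_residues = 6, n_contact = 3)
  bl <- make_bitc_ligand(8)$structure
  key <- function(p) paste(p$resno, p$resname)
  for (cuts in list(c(2, 3.5), c(3.5, 5), c(5, 9))) {
    p1 <- binding_pocket(pk$structure, bl, cutoff = cuts[1])
    p2 <- binding_pocket(pk$structure, bl, cutoff = cuts[2])
    expect_true(all(key(p1) %in% key(p2)))
  }
})

test_that("generated pockets are detected exactly as scripted", {
  for (seed in c(3, 14, 25)) {
    pk <- make_toy_pocket(seed, n_residues = 7, n_contact = 4)
    lig <- make_bitc_ligand(seed + 1)$structure
    p <- binding_pocket(pk$structure, lig)
    expect_setequal(paste(p$resno, p$resname),
                    paste(pk$contact_residues$resno,
                          pk$contact_residues$resname))
  }
})

test_that("AA_match is the reference-normalized overlap percentage", {
  pk <- make_toy_pocket(2, n_residues = 5)
  lig <- make_bitc_ligand(2)$structure
  p <- binding_pocket(pk$structure, lig)
  expect_equal(aa_match(p, p), 100)
  # reference of 5 residues, 3 shared -> 60 %
  ref <- structure(data.frame(chain = "A", resno = 1:5,
                              resname = rep("GLY", 5)),
                   class = c("binding_pocket", "data.frame"))
  obs <- structure(data.frame(chain = "A", resno = c(1:3, 8:9),
                              resname = rep("GLY", 5)),
                   class = c("binding_pocket", "data.frame"))
  expect_equal(aa_match(ref, obs), 60)
  expect_equal(aa_match(ref, obs, denominator = "union"), 100 * 3 / 7)
  # disjoint -> 0; empty reference undefined
  far <- structure(data.frame(chain = "A", resno = 20:22,
                              resname = rep("ALA", 3)),
                   class = c("binding_pocket", "data.frame"))
  expect_equal(aa_match(ref, far), 0)
  empty <- structure(ref[0, ], class = c("binding_pocket", "data.frame"))
  expect_error(aa_match(empty, obs), "undefined")
})

test_that("efficiency index has the published sign convention and rounding", {
  expect_equal(efficiency_index(-77.7, 10, digits = 2), 7.77)
  expect_equal(efficiency_index(-84.1, 23, digits = 2), 3.66)
  expect_equal(efficiency_index(0, 5), 0)
  expect_error(efficiency_index(-10, 0), "nha")
  # linear in dG at fixed NHA
  dg <- seq(-90, -10, by = 7)
  expect_equal(efficiency_index(2 * dg, 10), 2 * efficiency_index(dg, 10))
  # rounding is half away from zero
  expect_equal(efficiency_index(-0.125 * 10, 10, digits = 2), 0.13)
})
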