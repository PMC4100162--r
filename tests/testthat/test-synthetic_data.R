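test_that("planted complexes are recovered exactly by the detector", {
  pc <- make_planted_complex(all_class_spec(seed = 13))
  m <- detect_interactions(pc$complex)
  expect_setequal(m$residues, pc$truth$residues)
  i <- match(pc$truth$residues, m$residues)
  expect_identical(unname(m$bits[i, , drop = FALSE]), unname(pc$truth$bits))
  # empty interaction list: spectators only, all-zero matrix
  pc0 <- make_planted_complex(plant_spec(seed = 2))
  expect_equal(nrow(detect_interactions(pc0$complex)$bits), 0)
})

test_that("detector recovery is exact 0.3 A inside and outside the cutoffs", {
  # hydrogen bond at cutoff - 0.3 is detected; at cutoff + 0.3 the H-bond
  # bit is off while the polar/contact bits follow their own cutoffs
  near <- make_planted_complex(plant_spec(list(
    list(residue = "GLN", class = "hbond_donor", distance = 3.2)), seed = 1))
  expect_true(detect_interactions(near$complex)$bits[1, "hbond_donor"])
  far <- make_planted_complex(plant_spec(list(
    list(residue = "GLN", class = "hbond_donor", distance = 3.8)), seed = 1))
  mf <- detect_interactions(far$complex)
  expect_false(mf$bits[1, "hbond_donor"])
  expect_true(mf$bits[1, "polar"])        # 3.8 < 4.0 polar cutoff... still polar
  expect_identical(unname(mf$bits), unname(far$truth$bits))
  # hydrophobic beyond contact + 0.3 disappears entirely
  off <- make_planted_complex(plant_spec(list(
    list(residue = "LEU", class = "hydrophobic", distance = 4.8)), seed = 1))
  expect_equal(nrow(detect_interactions(off$complex)$bits), 0)
  expect_false(any(off$truth$bits))
})

test_that("generators are pure functions of spec and seed", {
  sp <- all_class_spec(seed = 33)
  expect_identical(make_planted_complex(sp)$pdb, make_planted_complex(sp)$pdb)
  pc <- make_planted_complex(sp)
  es <- ensemble_spec(n_poses = 10, p = 0.5, rmsd_targets = 2, seed = 5)
  e1 <- make_pose_ensemble(pc, es)
  e2 <- make_pose_ensemble(pc, es)
  expect_identical(e1$occurrence, e2$occurrence)
  expect_identical(e1$ensemble$poses[[3]]$atoms, e2$ensemble$poses[[3]]$atoms)
  expect_identical(make_energy_series(table5_components()[["D-AMC"]],
                                      sigma = 1, n = 20, seed = 9),
                   make_energy_series(table5_components()[["D-AMC"]],
                                      sigma = 1, n = 20, seed = 9))
  expect_identical(make_score_table(seed = 4), make_score_table(seed = 4))
})

test_that("ensembles hit planted occurrence frequencies and RMSD targets", {
  pc <- make_planted_complex(all_class_spec(seed = 3))
  # p = 1: every pose reproduces the base truth
  pe1 <- make_pose_ensemble(pc, ensemble_spec(n_poses = 5, p = 1, seed = 1))
  for (pose in pe1$ensemble$poses) {
    m <- detect_interactions(pose)
    i <- match(pc$truth$residues, m$residues)
    expect_identical(unname(m$bits[i, , drop = FALSE]),
                     unname(pc$truth$bits))
  }
  # p = 0.5 with n = 200: binomial 4-sigma recovery of the frequency,
  # and the detector's observed frequency equals the planted occurrence
  pe <- make_pose_ensemble(pc, ensemble_spec(n_poses = 200, p = 0.5, seed = 17))
  prof <- average_fingerprint(lapply(pe$ensemble$poses, detect_interactions))
  i <- match(pc$truth$residues, prof$residues)
  obs <- prof$freq[i, "any"]
  expect_equal(unname(obs), unname(pe$expected_freq))
  expect_true(all(abs(obs - 0.5) <= 4 * sqrt(0.25 / 200)))
  # rmsd targets respected to construction accuracy
  pe2 <- make_pose_ensemble(pc, ensemble_spec(n_poses = 1, p = 1,
                                              rmsd_targets = c(3, 0.8),
                                              seed = 2))
  for (k in seq_len(nrow(pe2$rmsd_poses))) {
    r <- heavy_atom_rmsd(pe2$ensemble$poses[[pe2$rmsd_poses$pose_index[k]]],
                         pc$complex)
    expect_equal(r$rmsd, pe2$rmsd_poses$target[k], tolerance = 0.01)
  }
})

test_that("frequency recovery holds across seeds (4-sigma binomial band)", {
  pc <- make_planted_complex(plant_spec(list(
    list(residue = "GLN", class = "hbond_donor"),
    list(residue = "LEU", class = "hydrophobic")), seed = 1))
  p <- 0.7; n <- 100
  hits <- vapply(1:5, function(s) {
    pe <- make_pose_ensemble(pc, ensemble_spec(n_poses = n, p = p, seed = s))
    prof <- average_fingerprint(lapply(pe$ensemble$poses,
                                       detect_interactions))
    i <- match(pc$truth$residues, prof$residues)
    all(abs(prof$freq[i, "any"] - p) <= 4 * sqrt(p * (1 - p) / n))
  }, logical(1))
  expect_true(all(hits))
})

test_that("energy series and score tables encode their planted ground truth", {
  means <- table5_components()[["R-AMC"]]
  s0 <- make_energy_series(means, sigma = 0, n = 5, seed = 1)
  avg <- average_binding(s0)
  expect_equal(avg$dG_bind, -40.91, tolerance = 1e-9)
  expect_equal(avg$components$nonpolar, -38.94, tolerance = 1e-9)
  tbl <- make_score_table(best_label = "R-AMC", gap = 2.1, n_entries = 20,
                          seed = 7)
  expect_equal(nrow(tbl), 20)
  expect_equal(sort(tbl$score)[2] - sort(tbl$score)[1], 2.1)
  two <- make_score_table(best_label = "A-AMC", gap = 1, n_entries = 2,
                          seed = 1)
  expect_equal(nrow(two), 2)
})

test_that("unsatisfiable planted geometry is rejected", {
  expect_error(plant_spec(list(list(residue = "GLN", class = "hbond_donor",
                                    distance = 1.0))), "unsatisfiable")
  expect_error(plant_spec(list(list(residue = "TRP", class = "polar"))),
               "supports residues")
})
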