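test_that("heavy-atom RMSD satisfies identity, translation and symmetry laws", {
  pk <- zmcp1_mini_pocket()
  ref <- make_triage_pose(pk)
  expect_equal(heavy_atom_rmsd(ref, ref)$rmsd, 0)
  # rigid translation of every ligand atom by (3,0,0) gives exactly 3
  tr <- ref
  idx <- tr$atoms$record == "ligand"
  tr$atoms[idx, "x"] <- tr$atoms[idx, "x"] + 3
  expect_equal(heavy_atom_rmsd(tr, ref)$rmsd, 3)
  expect_equal(heavy_atom_rmsd(ref, tr)$rmsd,
               heavy_atom_rmsd(tr, ref)$rmsd)
  # symmetry correction can never increase the RMSD
  expect_lte(heavy_atom_rmsd(tr, ref, symmetry = TRUE)$rmsd,
             heavy_atom_rmsd(tr, ref)$rmsd)
  # inventory mismatch names the offending atoms
  other <- tiny_complex(c("C1", "ZZ1"), rbind(c(0, 0, 0), c(1.4, 0, 0)))
  expect_error(heavy_atom_rmsd(other, ref), "mismatch")
})

test_that("symmetry-corrected RMSD matches a brute-force permutation oracle", {
  # two-fold symmetric toy: carboxylate-like Y-shape, equivalent O1/O2
  mk <- function(o1, o2) tiny_complex(
    c("C1", "C2", "O1", "O2"),
    rbind(c(0, 0, 0), c(0, 1.4, 0), o1, o2))
  ref <- mk(c(1.1, -0.6, 0), c(-1.1, -0.6, 0))
  swapped <- mk(c(-1.1, -0.6, 0), c(1.1, -0.6, 0))
  expect_gt(heavy_atom_rmsd(swapped, ref)$rmsd, 1)
  expect_equal(heavy_atom_rmsd(swapped, ref, symmetry = TRUE)$rmsd, 0)
  # randomly displaced variants against the brute-force oracle
  set.seed(42)
  for (k in 1:5) {
    jit <- matrix(rnorm(12, sd = 0.7), 4, 3)
    pose <- mk(c(-1.1, -0.6, 0) + jit[3, ], c(1.1, -0.6, 0) + jit[4, ])
    pose$atoms[pose$atoms$name == "C1", c("x", "y", "z")] <-
      rbind(c(0, 0, 0) + jit[1, ])
    pose$atoms[pose$atoms$name == "C2", c("x", "y", "z")] <-
      rbind(c(0, 1.4, 0) + jit[2, ])
    expect_equal(heavy_atom_rmsd(pose, ref, symmetry = TRUE)$rmsd,
                 brute_force_sym_rmsd(pose, ref), tolerance = 1e-10)
  }
})

test_that("docking classification applies the 2.5 A success rule inclusively", {
  expect_identical(classify_docking(2.41), "success")
  expect_identical(classify_docking(2.5), "success")
  expect_identical(classify_docking(7.0), "scoring_failure")
  expect_identical(classify_docking(0), "success")
  expect_error(classify_docking(-0.1), "non-negative")
})

test_that("binding-mode selection applies the three rules, not the score", {
  pk <- zmcp1_mini_pocket()
  ann <- zmcp1_annotation()
  good <- make_triage_pose(pk, d_catalytic = 4.0, d_oxyanion = 2.9)
  far_cat <- make_triage_pose(pk, d_catalytic = 6.2, d_oxyanion = 2.9,
                              model_id = 2)
  no_hb <- make_triage_pose(pk, d_catalytic = 4.0, d_oxyanion = 4.6,
                            model_id = 3)
  out_s1 <- make_triage_pose(pk, d_catalytic = 4.0, p1_in_s1 = FALSE,
                             model_id = 4)
  # the only conforming pose wins despite having the WORST score
  ens <- pose_ensemble(list(far_cat, no_hb, out_s1, good),
                       scores = c(-12, -11.5, -11, -9))
  tr <- select_binding_mode(ens, ann)
  expect_equal(tr$selected, 4L)
  expect_identical(tr$verdicts$passed, c(FALSE, FALSE, FALSE, TRUE))
  expect_false(tr$verdicts$r2_catalytic[1])
  expect_false(tr$verdicts$r3_oxyanion[2])
  expect_false(tr$verdicts$r1_subsite[3])
  # no conforming pose: verdicts still returned, nothing selected
  ens2 <- pose_ensemble(list(far_cat, no_hb), scores = c(-12, -11))
  tr2 <- select_binding_mode(ens2, ann)
  expect_true(is.na(tr2$selected))
  expect_equal(nrow(tr2$verdicts), 2)
  expect_error(select_binding_mode(ens, ann, p_groups = list(P1 = "QQ9")),
               "absent from ligand")
})

test_that("a pose with the reported catalytic geometry passes R2 and R3", {
  # scissile carbon 4.33 A from the nucleophile sulfur and a 2.08 A
  # oxyanion contact: the accepted R-AMC binding mode
  pk <- zmcp1_mini_pocket()
  pose <- make_triage_pose(pk, d_catalytic = 4.33, d_oxyanion = 2.08)
  tr <- select_binding_mode(pose_ensemble(list(pose)), zmcp1_annotation())
  v <- tr$verdicts
  expect_true(v$r2_catalytic)
  expect_true(v$r3_oxyanion)
  expect_equal(v$d_catalytic, 4.33, tolerance = 1e-6)
  expect_equal(v$d_oxyanion, 2.08, tolerance = 1e-6)
  # a later dipeptide complex shows 3.29 A, also within the gate
  expect_true(select_binding_mode(
    pose_ensemble(list(make_triage_pose(pk, d_catalytic = 3.29))),
    zmcp1_annotation())$verdicts$r2_catalytic)
})

test_that("selection is deterministic and monotone in the rule set", {
  pk <- zmcp1_mini_pocket()
  ann <- zmcp1_annotation()
  poses <- list(
    make_triage_pose(pk, d_catalytic = 4.0, p2_in_s2 = TRUE, model_id = 1),
    make_triage_pose(pk, d_catalytic = 4.0, p2_in_s2 = FALSE, model_id = 2))
  ens <- pose_ensemble(poses, scores = c(-8, -8))
  # equal scores: lowest index wins
  tr1 <- select_binding_mode(ens, ann)
  expect_equal(tr1$selected, 1L)
  # adding the P2/S2 rule can only reject poses, never rescue one
  tr2 <- select_binding_mode(ens, ann,
                             p_groups = list(P1 = c("CB1", "N2", "N3"),
                                             P2 = c("CB2", "CG2")))
  expect_true(all(which(tr2$verdicts$passed) %in% which(tr1$verdicts$passed)))
  expect_equal(tr2$selected, 1L)
  expect_false(tr2$verdicts$passed[2])
  # rerun is identical
  expect_identical(select_binding_mode(ens, ann)$verdicts, tr1$verdicts)
})
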