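test_that("a far-away ligand yields an all-zero fingerprint", {
  cx <- tiny_complex("C1", c(500, 0, 0))
  m <- detect_interactions(cx)
  expect_equal(nrow(m$bits), 0)
  md <- detect_interactions(cx, dense = TRUE)
  expect_false(any(md$bits))
})

test_that("a planted hydrogen bond sets donor, polar and any bits", {
  # residue backbone N at 2.9 A from a ligand carbonyl O, N-H...O 165 deg
  h <- specsift:::donor_h_local(2.9, 165)
  cx <- tiny_complex(
    lig_names = "O1", lig_xyz = c(0, 0, -2.9),
    res_names = c("N", "CA", "C", "O", "H"),
    res_xyz = rbind(c(0, 0, 0), c(0.95, 0, 1.05), c(0.4, 0, 2.45),
                    c(1.1, 0.95, 2.95), h))
  b <- detect_interactions(cx)$bits[1, ]
  expect_true(all(b[c("hbond_donor", "polar", "any", "backbone")]))
  expect_false(b["sidechain"])
  # a bent geometry (60 deg) fails the angle test when the H is present
  h2 <- specsift:::donor_h_local(2.9, 60)
  cx2 <- tiny_complex(
    lig_names = "O1", lig_xyz = c(0, 0, -2.9),
    res_names = c("N", "CA", "C", "O", "H"),
    res_xyz = rbind(c(0, 0, 0), c(0.95, 0, 1.05), c(0.4, 0, 2.45),
                    c(1.1, 0.95, 2.95), h2))
  expect_false(detect_interactions(cx2)$bits[1, "hbond_donor"])
})

test_that("a planted salt bridge sets charged, polar, sidechain and any", {
  tmpl <- specsift:::template_for("ARG", "NH1")
  cx <- tiny_complex(
    lig_names = c("O1", "C1", "O2"),
    lig_xyz = rbind(c(0, 0, -3.5), c(0, 0, -4.75), c(0, 0, -6.0)),
    res = "ARG", res_names = tmpl$names, res_xyz = tmpl$xyz)
  b <- detect_interactions(cx)$bits[1, ]
  expect_true(all(b[c("charged", "polar", "sidechain", "any")]))
  expect_false(b["aromatic"])
})

test_that("glycine contacts register as backbone, never side chain", {
  tmpl <- specsift:::template_for("GLY", "CA")
  cx <- tiny_complex(lig_names = "C1", lig_xyz = c(0, 0, -4.0),
                     res = "GLY", res_names = tmpl$names,
                     res_xyz = tmpl$xyz)
  b <- detect_interactions(cx)$bits[1, ]
  expect_true(b["backbone"])
  expect_false(b["sidechain"])
})

test_that("averaging counts occurrences and behaves linearly", {
  pc <- make_planted_complex(all_class_spec())
  m1 <- detect_interactions(pc$complex)
  # single matrix: profile equals the 0/1 cast
  p1 <- average_fingerprint(list(m1))
  expect_equal(unname(p1$freq[match(m1$residues, p1$residues), ]),
               unname(m1$bits * 1))
  # a bit set in one of two matrices averages to 0.5
  off <- make_pose_ensemble(pc, ensemble_spec(n_poses = 1, p = 0,
                                              seed = 2))$ensemble$poses[[1]]
  m0 <- detect_interactions(off)
  p2 <- average_fingerprint(list(m1, m0))
  expect_true(all(p2$freq[match(m1$residues, p2$residues), "any"] == 0.5))
  # 22 of 31 -> 22/31
  mats <- c(rep(list(m1), 22), rep(list(m0), 9))
  p31 <- average_fingerprint(mats)
  expect_equal(max(p31$freq), 22 / 31)
  expect_equal(p31$n_complexes, 31)
  # weighted-mean linearity over concatenated populations (residues
  # absent from a sub-population contribute frequency 0)
  a <- rep(list(m1), 3); b <- rep(list(m0), 5)
  pa <- average_fingerprint(a); pb <- average_fingerprint(b)
  pab <- average_fingerprint(c(a, b))
  lift <- function(p) {
    f <- p$freq[match(pab$residues, p$residues), , drop = FALSE]
    f[is.na(f)] <- 0
    unname(f)
  }
  expect_equal(unname(pab$freq), (3 * lift(pa) + 5 * lift(pb)) / 8)
  expect_error(average_fingerprint(list()), "no matrices")
})

test_that("profile frequencies are bounded and integer multiples of 1/n", {
  pc <- make_planted_complex(all_class_spec(seed = 9))
  pe <- make_pose_ensemble(pc, ensemble_spec(n_poses = 40, p = 0.6, seed = 4))
  prof <- average_fingerprint(lapply(pe$ensemble$poses, detect_interactions))
  expect_true(all(prof$freq >= 0 & prof$freq <= 1))
  expect_true(all(abs(prof$freq * prof$n_complexes -
                        round(prof$freq * prof$n_complexes)) < 1e-9))
  # computed "any" dominates every specific bit
  expect_true(all(prof$freq[, "any"] >= prof$freq[, -1]))
})

test_that("consensus is cutoff-monotone and respects the bit selector", {
  prof <- read_profile(extdata("zmcp1_sift_profile.tsv"))
  cuts <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0)
  sizes <- vapply(cuts, function(ct) nrow(consensus_residues(prof, ct)), 0L)
  expect_true(all(diff(sizes) <= 0))
  for (k in seq_along(cuts)[-1]) {
    hi <- consensus_residues(prof, cuts[k])
    lo <- consensus_residues(prof, cuts[k - 1])
    expect_true(all(hi$key %in% lo$key))
  }
  expect_equal(nrow(consensus_residues(prof, 1.0, bit = "charged")), 0)
  expect_error(consensus_residues(prof, 0.5, bit = "banana"), "unknown bit")
})

test_that("profile report round-trips frequencies at two decimals", {
  pc <- make_planted_complex(all_class_spec(seed = 2))
  pe <- make_pose_ensemble(pc, ensemble_spec(n_poses = 17, p = 0.7, seed = 8))
  prof <- average_fingerprint(lapply(pe$ensemble$poses, detect_interactions))
  f <- withr::local_tempfile(fileext = ".tsv")
  profile_report(prof, f)
  back <- read_profile(f)
  # rows are sorted by descending "any"; compare on labels
  i <- match(back$labels, prof$labels)
  expect_equal(unname(back$freq), unname(round(prof$freq[i, , drop = FALSE], 2)))
  # header order is the canonical nine-bit order
  hdr <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(hdr, c("residue", "any", "backbone", "sidechain", "polar",
                          "hydrophobic", "hbond_acceptor", "hbond_donor",
                          "aromatic", "charged"))
})
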