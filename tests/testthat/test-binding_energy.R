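test_that("species free energy follows G = E_gas + G_solv - TS", {
  expect_equal(species_free_energy(energy_components()), 0)
  c1 <- energy_components(E_int = 1, E_vdW = 2, E_ele = 3, G_PB = 4,
                          G_np = 5, TS = 0)
  expect_equal(species_free_energy(c1), 15)
  c2 <- energy_components(E_int = 1, E_vdW = 2, E_ele = 3, G_PB = 4,
                          G_np = 5, TS = 10)
  expect_equal(species_free_energy(c2), 5)
  expect_error(energy_components(E_ele = Inf), "finite")
})

test_that("binding free energy vanishes in the non-interacting limit", {
  expect_equal(binding_free_energy(10, 7, 3), 0)
  expect_equal(binding_free_energy(-50, -30, -10), -10)
})

test_that("decomposition sums are exact and order-free", {
  d <- decompose(-172.62, -33.5, 170.65, -5.44)
  expect_equal(d$nonpolar, d$dE_vdW + d$dG_np, tolerance = 1e-12)
  expect_equal(d$polar, d$dE_ele + d$dG_PB, tolerance = 1e-12)
  expect_equal(d$dG_bind, d$nonpolar + d$polar, tolerance = 1e-12)
})

test_that("snapshot averaging recovers constants exactly and ignores order", {
  s <- data.frame(dE_ele = rep(-10, 5), dE_vdW = -2, dG_PB = 8, dG_np = -1)
  avg <- average_binding(s)
  expect_equal(avg$dG_bind, -5)
  expect_equal(avg$se, 0)
  set.seed(1)
  s2 <- data.frame(dE_ele = rnorm(50, -10), dE_vdW = rnorm(50, -2),
                   dG_PB = rnorm(50, 8), dG_np = rnorm(50, -1))
  a1 <- average_binding(s2)
  a2 <- average_binding(s2[sample(50), ])
  expect_equal(a1$dG_bind, a2$dG_bind)
  expect_error(average_binding(s2[0, ]), "empty")
})

test_that("enabling an entropy column shifts dG_bind by exactly -dTS", {
  s <- data.frame(dE_ele = rep(-10, 4), dE_vdW = -2, dG_PB = 8, dG_np = -1)
  base <- average_binding(s)$dG_bind
  s$TS <- 3
  expect_equal(average_binding(s)$dG_bind, base - 3)
})

test_that("seeded Gaussian series recover the planted mean within 4 sigma/sqrt(n)", {
  means <- table5_components()[["R-AMC"]]
  truth <- with(means, (dE_vdW + dG_np) + (dE_ele + dG_PB))
  ser <- make_energy_series(means, sigma = 2, n = 1000, seed = 99)
  avg <- average_binding(ser)
  # per-snapshot dG has sd 2*sigma (four independent components)
  expect_lt(abs(avg$dG_bind - truth), 4 * (2 * 2) / sqrt(1000))
  expect_equal(avg$n, 1000)
})

test_that("Coulomb, Lennard-Jones and SASA match closed forms", {
  # two unit charges 1 A apart in vacuum
  expect_equal(coulomb_energy(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, 1)),
               332.0636)
  # LJ zero at r = sigma, -eps at the minimum
  p <- ff_params()
  s <- unname(p$lj$sigma["C"]); e <- unname(p$lj$eps["C"])
  expect_equal(lennard_jones_energy(rbind(c(0, 0, 0), c(s, 0, 0)),
                                    c("C", "C")), 0, tolerance = 1e-12)
  expect_equal(lennard_jones_energy(rbind(c(0, 0, 0), c(2^(1/6) * s, 0, 0)),
                                    c("C", "C")), -e, tolerance = 1e-12)
  # Lorentz-Berthelot minimum for a mixed pair
  sij <- (p$lj$sigma[["C"]] + p$lj$sigma[["O"]]) / 2
  eij <- sqrt(p$lj$eps[["C"]] * p$lj$eps[["O"]])
  expect_equal(lennard_jones_energy(rbind(c(0, 0, 0), c(2^(1/6) * sij, 0, 0)),
                                    c("C", "O")), -eij, tolerance = 1e-12)
  # isolated-sphere SASA (sampled within 2% of 4 pi (r + probe)^2)
  got <- as.numeric(shrake_rupley_sasa(rbind(c(0, 0, 0)), "C"))
  expect_equal(got, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.02)
  # a deeply buried atom contributes nothing
  shell <- rbind(c(0, 0, 0),
                 3 * specsift:::pocket_directions())
  per <- attr(shrake_rupley_sasa(shell, rep("C", 13)), "per_atom")
  expect_equal(per[1], 0)
})

test_that("component evaluation cancels pairwise terms for distant ligands", {
  tmpl <- specsift:::template_for("GLY", "CA")
  cx <- tiny_complex(lig_names = c("C1", "C2"),
                     lig_xyz = rbind(c(200, 0, 0), c(201.5, 0, 0)),
                     res = "GLY", res_names = tmpl$names,
                     res_xyz = tmpl$xyz, charge = 0.1)
  ev <- evaluate_components(cx)
  expect_equal(ev$delta$dE_vdW, 0, tolerance = 1e-6)
  expect_equal(ev$delta$dE_ele, 0, tolerance = 1e-4)
  # solvation of non-overlapping species is additive: deltas ~ 0 too,
  # so the single-trajectory dG_bind reduces to the solvation deltas
  d <- decompose(ev$delta$dE_ele, ev$delta$dE_vdW, ev$delta$dG_PB,
                 ev$delta$dG_np)
  expect_equal(d$dG_bind, ev$delta$dG_PB + ev$delta$dG_np, tolerance = 1e-4)
})

test_that("energy report prints the seven-row table at two decimals", {
  cols <- table5_components()
  decs <- lapply(cols, function(cc)
    decompose(cc$dE_ele, cc$dE_vdW, cc$dG_PB, cc$dG_np))
  lines <- energy_report(decs)
  expect_length(lines, 8)
  expect_match(lines[1], "^component\tR-AMC\tD-AMC$")
  expect_match(lines[8], "^dG_bind\t-40.91\t-13.85$")
  expect_match(lines[6], "^Non-polar\t-38.94\t-36.86$")
})
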