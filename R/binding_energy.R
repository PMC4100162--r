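# MM-PBSA end-state bookkeeping: per-species free energies, binding free
# energy, the polar/non-polar decomposition, snapshot averaging, and a
# lightweight component evaluator (Coulomb, Lennard-Jones, Shrake-Rupley
# SASA, Born-style polar-solvation surrogate).

.COULOMB_K <- 332.0636   # kcal mol^-1 A e^-2

#' Energy components of one species
#'
#' @param E_int Internal (bond + angle + torsion) energy, kcal/mol.
#' @param E_vdW Van der Waals energy.
#' @param E_ele Electrostatic energy.
#' @param G_PB Polar solvation free energy.
#' @param G_np Nonpolar solvation free energy.
#' @param TS Entropy term (0 under the entropy-neglect protocol).
#' @return Named list of class `energy_components`.
#' @export
energy_components <- function(E_int = 0, E_vdW = 0, E_ele = 0,
                              G_PB = 0, G_np = 0, TS = 0) {
  x <- list(E_int = E_int, E_vdW = E_vdW, E_ele = E_ele,
            G_PB = G_PB, G_np = G_np, TS = TS)
  if (!all(is.finite(unlist(x)))) stop("energy components must be finite")
  structure(x, class = "energy_components")
}

#' Free energy of one species
#'
#' G = E_gas + G_solvation - TS, with E_gas = E_int + E_vdW + E_ele and
#' G_solvation = G_PB + G_np.
#'
#' @param c An [energy_components()] object.
#' @return Free energy in kcal/mol.
#' @export
species_free_energy <- function(c) {
  stopifnot(inherits(c, "energy_components"))
  (c$E_int + c$E_vdW + c$E_ele) + (c$G_PB + c$G_np) - c$TS
}

#' Binding free energy from species free energies
#'
#' dG_bind = G_complex - (G_protein + G_ligand).
#'
#' @param complex_G,protein_G,ligand_G Species free energies, kcal/mol.
#' @return Binding free energy, kcal/mol.
#' @export
binding_free_energy <- function(complex_G, protein_G, ligand_G) {
  complex_G - (protein_G + ligand_G)
}

#' Polar/non-polar decomposition of a binding free energy
#'
#' Groups the four component differences into the two summary rows of a
#' standard MM-PBSA report: nonpolar = dE_vdW + dG_np, polar = dE_ele +
#' dG_PB, and dG_bind = nonpolar + polar.  The internal-energy difference
#' is identically zero under the single-trajectory protocol (complex,
#' protein and ligand snapshots all come from the complex trajectory), so
#' it carries no row.
#'
#' @param dE_ele,dE_vdW,dG_PB,dG_np Component differences, kcal/mol.
#' @return List of class `binding_decomposition` with fields `dE_ele`,
#'   `dE_vdW`, `dG_PB`, `dG_np`, `nonpolar`, `polar`, `dG_bind`.
#' @export
decompose <- function(dE_ele, dE_vdW, dG_PB, dG_np) {
  nonpolar <- dE_vdW + dG_np
  polar <- dE_ele + dG_PB
  structure(list(dE_ele = dE_ele, dE_vdW = dE_vdW, dG_PB = dG_PB,
                 dG_np = dG_np, nonpolar = nonpolar, polar = polar,
                 dG_bind = nonpolar + polar),
            class = "binding_decomposition")
}

#' @export
print.binding_decomposition <- function(x, ...) {
  cat(sprintf(paste0("<binding_decomposition> (kcal/mol)\n",
                     "  dE_ele %8.2f   dE_vdW %8.2f\n",
                     "  dG_PB  %8.2f   dG_np  %8.2f\n",
                     "  Non-polar %8.2f  Polar %8.2f  dG_bind %8.2f\n"),
              x$dE_ele, x$dE_vdW, x$dG_PB, x$dG_np,
              x$nonpolar, x$polar, x$dG_bind))
  invisible(x)
}

#' Read a per-snapshot energy-component series
#'
#' Tab-separated table with one row per snapshot and columns `dE_ele`,
#' `dE_vdW`, `dG_PB`, `dG_np` (optionally `TS` and `snapshot`).
#'
#' @param file Path to the table.
#' @return data.frame of per-snapshot component differences.
#' @export
read_energy_series <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("dE_ele", "dE_vdW", "dG_PB", "dG_np")
  if (!all(need %in% names(df)))
    stop("energy series must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) < 1) stop("energy series is empty")
  df
}

#' Average binding free energy over a snapshot series
#'
#' Computes the per-snapshot dG_bind (via [decompose()], minus any TS
#' column) and averages arithmetically, the standard snapshot-averaging
#' protocol.  Component means and the standard error of the mean dG_bind
#' are reported alongside.
#'
#' @param series data.frame as from [read_energy_series()], or a path.
#' @return List of class `binding_average`: `dG_bind` (mean), `se`,
#'   `n`, `components` (mean [decompose()] of the component means) and
#'   `per_snapshot` (numeric vector).
#' @export
average_binding <- function(series) {
  if (is.character(series)) series <- read_energy_series(series)
  if (nrow(series) < 1) stop("energy series is empty")
  ts <- if ("TS" %in% names(series)) series$TS else 0
  per <- (series$dE_vdW + series$dG_np) + (series$dE_ele + series$dG_PB) - ts
  comp <- decompose(mean(series$dE_ele), mean(series$dE_vdW),
                    mean(series$dG_PB), mean(series$dG_np))
  structure(list(
    dG_bind = mean(per) ,
    se = if (length(per) > 1) sd(per) / sqrt(length(per)) else 0,
    n = length(per), components = comp, per_snapshot = per
  ), class = "binding_average")
}

#' @export
print.binding_average <- function(x, ...) {
  cat(sprintf("<binding_average> dG_bind = %.2f +/- %.2f kcal/mol over %d snapshots\n",
              x$dG_bind, x$se, x$n))
  invisible(x)
}

#' MM-PBSA report table
#'
#' Formats one or more decompositions as the standard seven-row report
#' (dE_ele, dE_vdW, dG_PB, dG_np, Non-polar, Polar, dG_bind), energies
#' rounded to two decimals, one column per complex.
#'
#' @param decomps Named list of `binding_decomposition` (or
#'   `binding_average`) objects; names become column headers.
#' @param file Optional output path.
#' @return Character vector of table lines.
#' @export
energy_report <- function(decomps, file = NULL) {
  decomps <- lapply(decomps, function(d)
    if (inherits(d, "binding_average")) d$components else d)
  rows <- c("dE_ele", "dE_vdW", "dG_PB", "dG_np",
            "Non-polar", "Polar", "dG_bind")
  fields <- c("dE_ele", "dE_vdW", "dG_PB", "dG_np",
              "nonpolar", "polar", "dG_bind")
  lines <- paste(c("component", names(decomps)), collapse = "\t")
  for (i in seq_along(rows)) {
    vals <- vapply(decomps, function(d) sprintf("%.2f", d[[fields[i]]]), "")
    lines <- c(lines, paste(c(rows[i], vals), collapse = "\t"))
  }
  if (!is.null(file)) writeLines(lines, file)
  lines
}

# ---------------------------------------------------------------------------
# Component evaluators (force-field-lite)

#' Force-field-lite parameters
#'
#' Element-based Lennard-Jones parameters (sigma in Angstrom, epsilon in
#' kcal/mol, Lorentz-Berthelot combination), surface-tension coefficients
#' for the nonpolar term (G_np = gamma * SASA + beta), Born radii for the
#' polar-solvation surrogate, and the dielectric model for the gas-phase
#' Coulomb sum (`"constant"` with eps = 1, or `"distance"` for eps(r) = r).
#'
#' @param gamma,beta Nonpolar surface coefficients (kcal/mol/A^2, kcal/mol).
#' @param probe Solvent probe radius (A) for SASA.
#' @param n_sphere_points Sphere sampling density for Shrake-Rupley.
#' @param dielectric `"constant"` or `"distance"`.
#' @param epsilon Dielectric constant used when `dielectric = "constant"`.
#' @param solvent_dielectric Solvent dielectric for the polar surrogate.
#' @param nonbonded_cutoff Pair-distance cutoff (A) for the Coulomb and
#'   Lennard-Jones sums in [evaluate_components()].
#' @param template_charges Fallback per-element partial charges used when
#'   the atom table carries none.
#' @return List of parameters.
#' @export
ff_params <- function(gamma = 0.00542, beta = 0.92, probe = 1.4,
                      n_sphere_points = 960, dielectric = "constant",
                      epsilon = 1, solvent_dielectric = 80,
                      nonbonded_cutoff = 12,
                      template_charges = c(C = 0.10, N = -0.40, O = -0.45,
                                           S = -0.15, H = 0.15)) {
  list(gamma = gamma, beta = beta, probe = probe,
       n_sphere_points = n_sphere_points, dielectric = dielectric,
       epsilon = epsilon, solvent_dielectric = solvent_dielectric,
       nonbonded_cutoff = nonbonded_cutoff,
       template_charges = template_charges,
       lj = list(sigma = c(C = 3.40, N = 3.25, O = 3.00, S = 3.56,
                           H = 2.50, P = 3.74),
                 eps = c(C = 0.086, N = 0.170, O = 0.210, S = 0.250,
                         H = 0.015, P = 0.200)),
       vdw_radius = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                      P = 1.80),
       born_radius = c(C = 1.70, N = 1.55, O = 1.50, S = 1.80, H = 1.20,
                       P = 1.85))
}

#' Pairwise Coulomb energy
#'
#' E_ele = sum over pairs of 332.0636 q_i q_j / (eps(r) r_ij).
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param q Partial charges (e).
#' @param pairs Two-column index matrix of pairs to sum (default: all i<j).
#' @param dielectric,epsilon Dielectric model, see [ff_params()].
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(xyz, q, pairs = NULL, dielectric = "constant",
                           epsilon = 1) {
  if (is.null(pairs)) pairs <- t(utils::combn(nrow(xyz), 2))
  if (nrow(pairs) == 0) return(0)
  r <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                       xyz[pairs[, 2], , drop = FALSE])^2))
  eps <- if (dielectric == "distance") r * epsilon else epsilon
  sum(.COULOMB_K * q[pairs[, 1]] * q[pairs[, 2]] / (eps * r))
}

#' Pairwise Lennard-Jones energy
#'
#' 4 eps_ij ((sigma_ij/r)^12 - (sigma_ij/r)^6) with Lorentz-Berthelot
#' combination (arithmetic sigma, geometric epsilon).
#'
#' @param xyz n x 3 coordinates.
#' @param elem Element symbols.
#' @param pairs Pair index matrix (default all i<j).
#' @param params [ff_params()].
#' @return Energy in kcal/mol.
#' @export
lennard_jones_energy <- function(xyz, elem, pairs = NULL,
                                 params = ff_params()) {
  if (is.null(pairs)) pairs <- t(utils::combn(nrow(xyz), 2))
  if (nrow(pairs) == 0) return(0)
  sg <- params$lj$sigma[elem]; ep <- params$lj$eps[elem]
  sg[is.na(sg)] <- 3.3; ep[is.na(ep)] <- 0.1
  r <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                       xyz[pairs[, 2], , drop = FALSE])^2))
  sij <- (sg[pairs[, 1]] + sg[pairs[, 2]]) / 2
  eij <- sqrt(ep[pairs[, 1]] * ep[pairs[, 2]])
  sr6 <- (sij / r)^6
  sum(4 * eij * (sr6^2 - sr6))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by sampling quasi-uniform points (golden-spiral lattice)
#' on each atom's solvent-expanded sphere and counting points not buried
#' in any neighbour.
#'
#' @param xyz n x 3 coordinates (Angstrom).
#' @param elem Element symbols (sets vdW radii).
#' @param probe Probe radius (A).
#' @param n_points Sample points per atom.
#' @param params [ff_params()] supplying the radii.
#' @return Total SASA in A^2 (attribute `per_atom` carries the breakdown).
#' @export
shrake_rupley_sasa <- function(xyz, elem, probe = 1.4, n_points = 960,
                               params = ff_params()) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  rad <- params$vdw_radius[elem]
  rad[is.na(rad)] <- 1.7
  rad <- unname(rad) + probe
  # golden-spiral unit sphere
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  sph <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  area <- numeric(n)
  d <- cross_dist(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rad[i] + rad & seq_len(n) != i)
    pts <- sweep(sph * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sqrt(colSums((t(pts) - xyz[j, ])^2))
      free <- free & dj >= rad[j]
      if (!any(free)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  structure(sum(area), per_atom = area)
}

# Born-style pairwise screening surrogate for the polar solvation term.
# Generalized-Born with element-based (non-perturbed) Born radii:
#   G_pol = -0.5 (1 - 1/eps_w) sum_ij k q_i q_j / f_GB(r_ij)
#   f_GB = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj)))
# This is a declared surrogate for a finite-difference PB solver; it
# reproduces the sign and rough magnitude of polar-solvation effects, not
# solver-grade values.
born_polar_energy <- function(xyz, q, elem, params = ff_params()) {
  R <- params$born_radius[elem]
  R[is.na(R)] <- 1.6
  n <- nrow(xyz)
  pre <- -0.5 * (1 - 1 / params$solvent_dielectric) * .COULOMB_K
  d <- cross_dist(xyz, xyz)
  RR <- outer(R, R)
  fgb <- sqrt(d^2 + RR * exp(-d^2 / (4 * RR)))
  qq <- outer(q, q)
  pre * sum(qq / fgb)
}

#' Evaluate MM-PBSA components for a complex and its isolated species
#'
#' Single-trajectory evaluation: protein and ligand coordinates are taken
#' from the complex itself, so internal terms cancel and `E_int = 0` for
#' the differences.  Gas-phase terms are a pairwise Coulomb sum (constant
#' dielectric 1 by default) and Lennard-Jones with Lorentz-Berthelot
#' mixing; the nonpolar solvation term is `gamma * SASA + beta` with
#' Shrake-Rupley SASA (1.4 A probe); the polar term uses a Born-style
#' pairwise screening surrogate (a stand-in for a Poisson-Boltzmann
#' solver; bookkeeping, not solver-grade energetics).
#'
#' Partial charges come from the atom table's `charge` column; atoms with
#' missing charges fall back to the element-template set, or raise an
#' error in strict mode.
#'
#' @param cx A [sift_complex()].
#' @param params [ff_params()].
#' @param strict Error on missing charges instead of using the template.
#' @return List with `complex`, `protein`, `ligand` ([energy_components()])
#'   and `delta` (their [decompose()]-ready differences).
#' @export
evaluate_components <- function(cx, params = ff_params(), strict = FALSE) {
  at <- cx$atoms
  q <- at$charge
  if (anyNA(q)) {
    if (strict)
      stop("atoms without partial charges: ",
           paste(head(at$name[is.na(q)], 10), collapse = ", "))
    tq <- params$template_charges[at$elem[is.na(q)]]
    tq[is.na(tq)] <- 0
    q[is.na(q)] <- tq
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  is_lig <- at$record == "ligand"

  species <- function(idx) {
    sxyz <- xyz[idx, , drop = FALSE]
    sq <- q[idx]; sel <- at$elem[idx]
    sasa <- shrake_rupley_sasa(sxyz, sel, probe = params$probe,
                               n_points = params$n_sphere_points,
                               params = params)
    pairs <- if (sum(idx) > 1) {
      d <- cross_dist(sxyz, sxyz)
      which(d <= params$nonbonded_cutoff & upper.tri(d), arr.ind = TRUE)
    } else matrix(integer(0), ncol = 2)
    energy_components(
      E_int = 0,
      E_vdW = lennard_jones_energy(sxyz, sel, pairs = pairs,
                                   params = params),
      E_ele = coulomb_energy(sxyz, sq, pairs = pairs,
                             dielectric = params$dielectric,
                             epsilon = params$epsilon),
      G_PB = born_polar_energy(sxyz, sq, sel, params),
      G_np = params$gamma * as.numeric(sasa) + params$beta
    )
  }
  comp <- species(rep(TRUE, nrow(at)))
  prot <- species(!is_lig)
  lig <- species(is_lig)
  delta <- list(dE_ele = comp$E_ele - prot$E_ele - lig$E_ele,
                dE_vdW = comp$E_vdW - prot$E_vdW - lig$E_vdW,
                dG_PB = comp$G_PB - prot$G_PB - lig$G_PB,
                dG_np = comp$G_np - prot$G_np - lig$G_np)
  list(complex = comp, protein = prot, ligand = lig, delta = delta)
}
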