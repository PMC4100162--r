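# Shared fixture builders.  Everything is generated in code; no binary
# fixtures.

# Tiny protein+ligand complex: one residue and a handful of ligand atoms
# at caller-controlled positions.
tiny_complex <- function(lig_names, lig_xyz, res = "GLY",
                         res_names = c("N", "CA", "C", "O"),
                         res_xyz = rbind(c(50, 0, 0), c(51, 0, 0),
                                         c(52, 0, 0), c(52, 1, 0)),
                         charge = NA_real_) {
  prot <- atom_table(name = res_names, x = res_xyz[, 1], y = res_xyz[, 2],
                     z = res_xyz[, 3], resno = 1L, resname = res,
                     record = "protein")
  lig_xyz <- rbind(lig_xyz)
  lig <- atom_table(name = lig_names, x = lig_xyz[, 1], y = lig_xyz[, 2],
                    z = lig_xyz[, 3], chain = "L", resno = 9L,
                    resname = "TOY", record = "ligand", charge = charge)
  sift_complex(rbind(prot, lig))
}

# The two MM-PBSA component columns as printed in the source study's
# decomposition table (kcal/mol).
table5_components <- function() {
  list(
    "R-AMC" = list(dE_ele = -172.62, dE_vdW = -33.5,
                   dG_PB = 170.65, dG_np = -5.44),
    "D-AMC" = list(dE_ele = -106.88, dE_vdW = -31.4,
                   dG_PB = 129.89, dG_np = -5.46)
  )
}

extdata <- function(...) system.file("extdata", ..., package = "specsift")

# All permutations of 1..n (recursive; used only for small n).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- list()
  for (p in sub) for (k in seq_len(n)) {
    out[[length(out) + 1]] <- append(p, n, after = k - 1)
  }
  out
}

# Brute-force symmetry-corrected RMSD oracle: minimum RMSD over all
# element-preserving atom permutations that preserve the inferred bond
# graph.  Independent of heavy_atom_rmsd()'s VF2 route.
brute_force_sym_rmsd <- function(pose, reference) {
  lp <- pose$atoms[pose$atoms$record == "ligand", ]
  lr <- reference$atoms[reference$atoms$record == "ligand", ]
  lp <- lp[order(match(lp$name, lr$name)), ]
  a <- as.matrix(lp[, c("x", "y", "z")])
  b <- as.matrix(lr[, c("x", "y", "z")])
  n <- nrow(b)
  adj <- matrix(FALSE, n, n)
  bd <- specsift:::infer_bonds(b, lr$elem)
  for (i in seq_len(nrow(bd))) adj[bd[i, 1], bd[i, 2]] <- adj[bd[i, 2], bd[i, 1]] <- TRUE
  best <- Inf
  for (p in all_permutations(n)) {
    if (!all(lr$elem[p] == lr$elem)) next
    if (!identical(adj[p, p], adj)) next
    r <- sqrt(mean(rowSums((a[p, , drop = FALSE] - b)^2)))
    if (r < best) best <- r
  }
  best
}

# Standard planted-complex spec exercising all interaction classes at
# default (guard-banded) geometry.
all_class_spec <- function(seed = 1) {
  plant_spec(list(
    list(residue = "GLN", class = "hbond_donor", distance = 2.9, angle = 165),
    list(residue = "GLY", class = "hbond_acceptor"),
    list(residue = "CYS", class = "polar"),
    list(residue = "LEU", class = "hydrophobic"),
    list(residue = "PHE", class = "aromatic"),
    list(residue = "ARG", class = "charged"),
    list(residue = "GLY", class = "contact")
  ), seed = seed)
}
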