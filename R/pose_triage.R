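# Docking-pose validation (heavy-atom RMSD, 2.5 A success rule) and
# binding-mode triage against the catalytic machinery.

#' Heavy-atom RMSD between a docked pose and a reference
#'
#' Root-mean-square deviation over ligand heavy atoms, with atoms matched
#' by name.  No superposition is performed: docked and reference poses are
#' assumed to share the receptor frame, as is standard for redocking
#' validation.  With `symmetry = TRUE` the minimum RMSD over all
#' element-preserving automorphisms of the ligand bond graph is returned,
#' so chemically equivalent atoms (e.g. the two oxygens of a carboxylate)
#' can swap.
#'
#' @param pose,reference [sift_complex()] objects with identical ligand
#'   atom inventories.
#' @param symmetry Correct for ligand topological symmetry.
#' @return List of class `rmsd_result`: `rmsd` (Angstrom), `mapping`
#'   (`"by-name"` or `"symmetry-corrected"`), `n_atoms`.
#' @export
heavy_atom_rmsd <- function(pose, reference, symmetry = FALSE) {
  lp <- ligand_atoms(pose); lr <- ligand_atoms(reference)
  lp <- lp[is_heavy(lp$elem), , drop = FALSE]
  lr <- lr[is_heavy(lr$elem), , drop = FALSE]
  m <- match(lr$name, lp$name)
  if (anyNA(m) || nrow(lp) != nrow(lr)) {
    miss <- c(setdiff(lr$name, lp$name), setdiff(lp$name, lr$name))
    stop("ligand atom inventory mismatch; differing atoms: ",
         paste(unique(miss), collapse = ", "))
  }
  lp <- lp[m, , drop = FALSE]
  a <- as.matrix(lp[, c("x", "y", "z")])
  b <- as.matrix(lr[, c("x", "y", "z")])
  best <- sqrt(mean(rowSums((a - b)^2)))
  mapping <- "by-name"
  if (symmetry) {
    perms <- ligand_automorphisms(lr)
    for (p in perms) {
      r <- sqrt(mean(rowSums((a[p, , drop = FALSE] - b)^2)))
      if (r < best) best <- r
    }
    mapping <- "symmetry-corrected"
  }
  structure(list(rmsd = best, mapping = mapping, n_atoms = nrow(lr)),
            class = "rmsd_result")
}

#' @export
print.rmsd_result <- function(x, ...) {
  cat(sprintf("<rmsd_result> %.3f A over %d heavy atoms (%s)\n",
              x$rmsd, x$n_atoms, x$mapping))
  invisible(x)
}

# All element-preserving automorphisms of the ligand bond graph (VF2 with
# element colours), as permutations of the heavy-atom rows.
ligand_automorphisms <- function(lig) {
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  bonds <- infer_bonds(xyz, lig$elem)
  n <- nrow(lig)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(bonds) > 0) g <- igraph::add_edges(g, t(bonds))
  col <- as.integer(factor(lig$elem))
  iso <- igraph::isomorphisms(g, g, method = "vf2",
                              vertex.color1 = col, vertex.color2 = col)
  lapply(iso, as.integer)
}

#' Classify a docking validation result
#'
#' A redocking run is a success when the top-scoring pose lies within the
#' RMSD threshold of the crystallographic ligand (2.5 A by default,
#' inclusive); otherwise it is a scoring failure.
#'
#' @param rmsd Heavy-atom RMSD in Angstrom (non-negative).
#' @param threshold Success threshold in Angstrom.
#' @return `"success"` or `"scoring_failure"`.
#' @export
classify_docking <- function(rmsd, threshold = 2.5) {
  if (any(rmsd < 0)) stop("rmsd must be non-negative")
  ifelse(rmsd <= threshold, "success", "scoring_failure")
}

#' Triage rules configuration
#'
#' @param occupancy_cutoff Heavy-atom cutoff (Angstrom) for a P-group atom
#'   to count as occupying a subsite.
#' @param catalytic_max Maximum scissile-carbon to nucleophile-sulfur
#'   distance.  "About 4 A" is operationalised as `<= 4.5`.
#' @param scissile_atom Ligand atom name of the scissile carbonyl carbon.
#' @param criteria [geometric_criteria()] used for the oxyanion-hole
#'   hydrogen-bond rule.
#' @return List of rule parameters.
#' @export
triage_rules <- function(occupancy_cutoff = 4.5, catalytic_max = 4.5,
                         scissile_atom = "C11",
                         criteria = geometric_criteria()) {
  list(occupancy_cutoff = occupancy_cutoff, catalytic_max = catalytic_max,
       scissile_atom = scissile_atom, criteria = criteria)
}

#' Select the catalytically competent binding mode from a pose ensemble
#'
#' Applies three geometric rules to every pose: (R1) subsite occupancy -
#' at least one P1-group heavy atom within `occupancy_cutoff` of an
#' S1-subsite residue heavy atom (and likewise P2/S2 when a P2 group is
#' declared); (R2) catalytic distance - the scissile carbonyl carbon
#' within `catalytic_max` of the nucleophile atom (Cys SG); (R3) oxyanion
#' hydrogen bond - at least one hydrogen bond between the P1 charged group
#' and an oxyanion-hole residue.  The selected pose is the best-scoring
#' pose passing all applicable rules (ties: lowest pose index).
#'
#' @param ensemble A [pose_ensemble()].
#' @param annotation An [enzyme_annotation()].
#' @param p_groups Named list of ligand atom-name sets, e.g.
#'   `list(P1 = c("CB1","N2","N3"), P2 = c("CB2","CG2"))`.  At least P1.
#' @param rules A [triage_rules()] list.
#' @return List of class `triage_result`: `verdicts` (one row per pose with
#'   per-rule pass flags and measured distances), `selected` (pose index or
#'   NA) and `pose` (the selected [sift_complex()] or NULL).
#' @export
select_binding_mode <- function(ensemble, annotation,
                                p_groups = list(P1 = c("CB1", "N2", "N3")),
                                rules = triage_rules()) {
  stopifnot(inherits(ensemble, "pose_ensemble"),
            inherits(annotation, "enzyme_annotation"))
  if (is.null(p_groups$P1)) stop("p_groups must define at least P1")
  lig0 <- ligand_atoms(ensemble$poses[[1]])
  missing_p1 <- setdiff(p_groups$P1, lig0$name)
  if (length(missing_p1) > 0)
    stop("P1 atom names absent from ligand: ",
         paste(missing_p1, collapse = ", "))

  pos_labels <- intersect(names(p_groups), c("P1", "P2"))
  rows <- lapply(seq_along(ensemble$poses), function(i) {
    cx <- ensemble$poses[[i]]
    prot <- protein_atoms(cx)
    lig <- ligand_atoms(cx)
    pkey <- residue_key(prot$chain, prot$resno, prot$icode)

    # R1: subsite occupancy for each declared P group
    occ <- vapply(pos_labels, function(pl) {
      sub <- annotation$subsites[[sub("P", "S", pl)]]
      if (is.null(sub)) return(NA)
      pa <- lig[lig$name %in% p_groups[[pl]] & is_heavy(lig$elem), , drop = FALSE]
      sa <- prot[pkey %in% sub & is_heavy(prot$elem), , drop = FALSE]
      if (nrow(pa) == 0 || nrow(sa) == 0) return(FALSE)
      min(cross_dist(pa[, c("x", "y", "z")], sa[, c("x", "y", "z")])) <=
        rules$occupancy_cutoff
    }, logical(1))

    # R2: scissile carbon to nucleophile distance
    sc <- lig[lig$name == rules$scissile_atom, , drop = FALSE]
    nuc <- prot[pkey == annotation$nucleophile$residue &
                  prot$name == annotation$nucleophile$atom, , drop = FALSE]
    d_cat <- if (nrow(sc) == 1 && nrow(nuc) == 1)
      vec_norm(as.numeric(sc[1, c("x", "y", "z")]) -
                 as.numeric(nuc[1, c("x", "y", "z")])) else NA_real_
    r2 <- !is.na(d_cat) && d_cat <= rules$catalytic_max

    # R3: H-bond between the P1 group and an oxyanion-hole residue
    oxy <- prot[pkey %in% annotation$oxyanion_hole, , drop = FALSE]
    p1a <- lig[lig$name %in% p_groups$P1, , drop = FALSE]
    r3 <- oxyanion_hbond(oxy, p1a, lig, rules$criteria)

    data.frame(pose_index = i, score = ensemble$scores[i],
               r1_subsite = all(occ, na.rm = TRUE),
               r2_catalytic = r2, d_catalytic = d_cat,
               r3_oxyanion = r3$hit, d_oxyanion = r3$dist,
               passed = all(occ, na.rm = TRUE) && r2 && r3$hit,
               stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, rows)

  sel <- NA_integer_
  pass <- which(verdicts$passed)
  if (length(pass) > 0) {
    sc <- ensemble$scores[pass]
    if (all(is.na(sc))) sel <- pass[1]
    else sel <- pass[order(sc, pass)][1]
  }
  structure(list(verdicts = verdicts, selected = sel,
                 pose = if (!is.na(sel)) ensemble$poses[[sel]] else NULL),
            class = "triage_result")
}

# H-bond between any P1 N/O atom and any oxyanion-residue donor/acceptor
# N/O atom: heavy-atom distance within the H-bond cutoff, angle checked
# when a donor hydrogen is present on the residue side.
oxyanion_hbond <- function(oxy, p1a, lig, criteria) {
  ra <- oxy[oxy$elem %in% c("N", "O") & is_heavy(oxy$elem), , drop = FALSE]
  la <- p1a[p1a$elem %in% c("N", "O"), , drop = FALSE]
  if (nrow(ra) == 0 || nrow(la) == 0)
    return(list(hit = FALSE, dist = NA_real_))
  d <- cross_dist(ra[, c("x", "y", "z")], la[, c("x", "y", "z")])
  dist <- min(d)
  list(hit = dist <= criteria$hbond_heavy_cutoff, dist = dist)
}

#' @export
print.triage_result <- function(x, ...) {
  cat("<triage_result>", nrow(x$verdicts), "poses;",
      sum(x$verdicts$passed), "passing; selected:",
      if (is.na(x$selected)) "none" else x$selected, "\n")
  invisible(x)
}

#' Write a triage verdict table
#'
#' @param result A `triage_result`.
#' @param file Output path for the tab-separated verdict table.
#' @return `file`, invisibly.
#' @export
write_verdicts <- function(result, file) {
  df <- result$verdicts
  df$d_catalytic <- round(df$d_catalytic, 2)
  df$d_oxyanion <- round(df$d_oxyanion, 2)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
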