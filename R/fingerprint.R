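# Nine-bit structural interaction fingerprints (SIFt).
#
# Bit order, fixed throughout the package and in all reports:
#   any, backbone, sidechain, polar, hydrophobic,
#   hbond_acceptor, hbond_donor, aromatic, charged
#
# "H-bond donor" means the *protein residue* donates the hydrogen; the
# direction convention is documented and the two bits can be swapped by the
# caller if the opposite convention is needed.

.SIFT_BITS <- c("any", "backbone", "sidechain", "polar", "hydrophobic",
                "hbond_acceptor", "hbond_donor", "aromatic", "charged")

#' Geometric criteria for interaction detection
#'
#' Distance/angle cutoffs used by [detect_interactions()].  Defaults follow
#' common structural-biology practice: 4.5 A heavy-atom contact, 4.0 A
#' polar contact, 3.5 A hydrogen-bond donor-acceptor distance with a
#' 120 degree donor-H...acceptor angle when the hydrogen is present,
#' 5.0 A aromatic ring-centroid distance, 4.0 A salt bridge.
#'
#' @param contact_cutoff Heavy-atom contact cutoff (Angstrom).
#' @param polar_cutoff N/O/S-N/O/S polar contact cutoff.
#' @param hbond_heavy_cutoff Donor-acceptor heavy-atom cutoff; must not
#'   exceed `contact_cutoff`.
#' @param hbond_angle_min Minimum donor-H...acceptor angle (degrees),
#'   applied only when the donor hydrogen is present.
#' @param aromatic_centroid_cutoff Ring centroid-centroid cutoff.
#' @param salt_bridge_cutoff Cutoff for oppositely charged N/O pairs.
#' @return Object of class `geometric_criteria`.
#' @export
geometric_criteria <- function(contact_cutoff = 4.5, polar_cutoff = 4.0,
                               hbond_heavy_cutoff = 3.5,
                               hbond_angle_min = 120,
                               aromatic_centroid_cutoff = 5.0,
                               salt_bridge_cutoff = 4.0) {
  crit <- list(contact_cutoff = contact_cutoff, polar_cutoff = polar_cutoff,
               hbond_heavy_cutoff = hbond_heavy_cutoff,
               hbond_angle_min = hbond_angle_min,
               aromatic_centroid_cutoff = aromatic_centroid_cutoff,
               salt_bridge_cutoff = salt_bridge_cutoff)
  if (any(unlist(crit) <= 0)) stop("all criteria must be positive")
  if (hbond_heavy_cutoff > contact_cutoff)
    stop("hbond_heavy_cutoff must not exceed contact_cutoff")
  structure(crit, class = "geometric_criteria")
}

# --- residue-template typing ------------------------------------------------

# Side-chain H-bond donor / acceptor heavy atoms by residue name.  Backbone
# N is a donor (except proline), backbone O/OXT acceptors, for all residues.
.SC_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1",
  TYR = "OH", CYS = "SG"
)
.SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH",
  MET = "SD", CYS = "SG"
)

# Charged side-chain groups: sign and member atoms.
.CHARGED_GROUPS <- list(
  ARG = list(sign = +1, atoms = c("NE", "NH1", "NH2")),
  LYS = list(sign = +1, atoms = "NZ"),
  HIS = list(sign = +1, atoms = c("ND1", "NE2")),
  ASP = list(sign = -1, atoms = c("OD1", "OD2")),
  GLU = list(sign = -1, atoms = c("OE1", "OE2"))
)

# Aromatic ring atom sets by residue name (all atoms must be present).
.RING_ATOMS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

# Apolar carbons: carbons with no N/O/S neighbour within covalent range in
# the same molecule (intra-residue for protein, whole ligand for ligands).
apolar_carbons <- function(atoms) {
  out <- logical(nrow(atoms))
  isC <- atoms$elem == "C"
  if (!any(isC)) return(out)
  pol <- atoms$elem %in% c("N", "O", "S")
  if (!any(pol)) { out[isC] <- TRUE; return(out) }
  d <- cross_dist(atoms[isC, c("x", "y", "z")], atoms[pol, c("x", "y", "z")])
  lim <- outer(covalent_radius(atoms$elem[isC]),
               covalent_radius(atoms$elem[pol]), "+") + .BOND_TOLERANCE
  out[isC] <- rowSums(d <= lim) == 0
  out
}

# Perceive ligand aromatic rings: smallest cycles of size 5-6 over the
# inferred bond graph, all C/N, planar within 0.1 A RMS.  Returns a list of
# atom-index vectors.
ligand_rings <- function(atoms) {
  heavy <- which(is_heavy(atoms$elem))
  if (length(heavy) < 5) return(list())
  xyz <- as.matrix(atoms[heavy, c("x", "y", "z")])
  bonds <- infer_bonds(xyz, atoms$elem[heavy])
  if (nrow(bonds) < 5) return(list())
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  if (igraph::vcount(g) < length(heavy))
    g <- igraph::add_vertices(g, length(heavy) - igraph::vcount(g))
  rings <- list()
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, i, j)$vpath[[1]])
    if (length(sp) < 2) next              # bond not in a cycle
    ring <- as.integer(sp)
    if (length(ring) < 5 || length(ring) > 6) next
    if (!all(atoms$elem[heavy][ring] %in% c("C", "N"))) next
    pts <- xyz[ring, , drop = FALSE]
    if (ring_planarity_rms(pts) > 0.1) next
    key <- paste(sort(ring), collapse = "-")
    rings[[key]] <- heavy[ring]
  }
  unname(rings)
}

# RMS distance of points from their best-fit plane.
ring_planarity_rms <- function(pts) {
  ctr <- colMeans(pts)
  s <- svd(sweep(pts, 2, ctr))
  sqrt(mean((s$u[, 3] * s$d[3])^2))
}

# Hydrogens covalently attached to heavy atom `i` (indices into atoms).
attached_hydrogens <- function(atoms, i) {
  h <- which(atoms$elem == "H")
  if (length(h) == 0) return(integer(0))
  d <- cross_dist(atoms[i, c("x", "y", "z"), drop = FALSE],
                  atoms[h, c("x", "y", "z"), drop = FALSE])
  h[d[1, ] <= 1.3]
}

# Ligand charged groups inferred when formal/partial charges are absent:
# nitrogens are positive candidates; oxygens on a carbon bearing >= 2
# oxygens (carboxylate-like) are negative candidates.  When the atom table
# carries non-zero charges, their sign is used directly.
ligand_charged_atoms <- function(lig) {
  chg <- lig$charge
  if (any(!is.na(chg) & chg != 0)) {
    return(list(pos = which(!is.na(chg) & chg > 0.25 & lig$elem %in% c("N", "O")),
                neg = which(!is.na(chg) & chg < -0.25 & lig$elem %in% c("N", "O"))))
  }
  pos <- which(lig$elem == "N")
  neg <- integer(0)
  oi <- which(lig$elem == "O"); ci <- which(lig$elem == "C")
  if (length(oi) >= 2 && length(ci) >= 1) {
    d <- cross_dist(lig[ci, c("x", "y", "z"), drop = FALSE],
                    lig[oi, c("x", "y", "z"), drop = FALSE])
    lim <- outer(covalent_radius(lig$elem[ci]),
                 covalent_radius(lig$elem[oi]), "+") + .BOND_TOLERANCE
    n_ox <- rowSums(d <= lim)
    for (k in which(n_ox >= 2)) neg <- c(neg, oi[d[k, ] <= lim[k, ]])
    neg <- unique(neg)
  }
  list(pos = pos, neg = neg)
}

# --- detection --------------------------------------------------------------

#' Detect protein-ligand interactions for one complex
#'
#' Computes the nine-bit interaction fingerprint for every protein residue
#' of a complex.  Bits: `any` (at least one heavy-atom pair within the
#' contact cutoff, or any specific bit), `backbone`/`sidechain` (contact
#' through an atom of that partition), `polar` (residue N/O/S near ligand
#' N/O/S), `hydrophobic` (apolar carbon pair in contact), `hbond_donor`
#' (residue donates an H-bond to the ligand), `hbond_acceptor` (residue
#' accepts), `aromatic` (ring-centroid contact between a residue ring and a
#' perceived ligand ring), `charged` (salt bridge between oppositely
#' charged groups).  Hydrogen-bond detection is distance-only when the
#' donor hydrogen is absent, as in most docked poses.
#'
#' The `any` bit is recomputed as the OR of plain contact and all specific
#' bits, so `any` dominates every other bit by construction.
#'
#' @param cx A [sift_complex()].
#' @param criteria A [geometric_criteria()].
#' @param dense Keep rows for residues with no bit set.
#' @return Object of class `sift_matrix`: residue keys/labels plus a
#'   logical residues x 9 bit matrix.
#' @export
detect_interactions <- function(cx, criteria = geometric_criteria(),
                                dense = FALSE) {
  stopifnot(inherits(cx, "sift_complex"))
  prot <- protein_atoms(cx)
  lig <- ligand_atoms(cx)
  if (sum(is_heavy(lig$elem)) == 0) stop("ligand has no heavy atoms")

  key <- residue_key(prot$chain, prot$resno, prot$icode)
  ukey <- unique(key)
  bits <- matrix(FALSE, length(ukey), length(.SIFT_BITS),
                 dimnames = list(ukey, .SIFT_BITS))
  labels <- vapply(ukey, function(k) {
    i <- which(key == k)[1]; residue_label(prot$resname[i], prot$resno[i])
  }, "")

  lig_heavy <- which(is_heavy(lig$elem))
  lxyz <- as.matrix(lig[lig_heavy, c("x", "y", "z")])
  lig_apolar <- apolar_carbons(lig)[lig_heavy]
  lig_nos <- lig$elem[lig_heavy] %in% c("N", "O", "S")
  lig_no <- lig$elem[lig_heavy] %in% c("N", "O")
  lrings <- ligand_rings(lig)
  lring_centroids <- lapply(lrings, function(idx)
    colMeans(as.matrix(lig[idx, c("x", "y", "z")])))
  lchg <- ligand_charged_atoms(lig)
  lig_hdon_h <- lapply(seq_along(lig_heavy), function(k)
    attached_hydrogens(lig, lig_heavy[k]))

  for (k in seq_along(ukey)) {
    res <- prot[key == ukey[k], , drop = FALSE]
    rname <- toupper(res$resname[1])
    rheavy <- which(is_heavy(res$elem))
    if (length(rheavy) == 0) next
    rxyz <- as.matrix(res[rheavy, c("x", "y", "z")])
    d <- cross_dist(rxyz, lxyz)
    if (min(d) > max(criteria$contact_cutoff,
                     criteria$aromatic_centroid_cutoff) + 3) next

    part <- partition_backbone(res$name)
    in_bb <- res$name[rheavy] %in% part$backbone
    contact <- d <= criteria$contact_cutoff
    plain_contact <- any(contact)
    b <- setNames(logical(length(.SIFT_BITS)), .SIFT_BITS)
    b["backbone"] <- any(contact[in_bb, , drop = FALSE])
    b["sidechain"] <- any(contact[!in_bb, , drop = FALSE])

    res_nos <- res$elem[rheavy] %in% c("N", "O", "S")
    b["polar"] <- any(d[res_nos, lig_nos, drop = FALSE] <= criteria$polar_cutoff)

    res_apolar <- apolar_carbons(res)[rheavy]
    b["hydrophobic"] <- any(d[res_apolar, lig_apolar, drop = FALSE] <=
                              criteria$contact_cutoff)

    # hydrogen bonds: residue donor -> ligand acceptor sets hbond_donor
    don <- res$name[rheavy] %in% c(if (rname != "PRO") "N",
                                   .SC_DONORS[[rname]])
    b["hbond_donor"] <- hbond_hit(res, rheavy[don], lig, lig_heavy[lig_no],
                                  d[don, lig_no, drop = FALSE],
                                  donor_side = "protein", criteria)
    acc <- res$name[rheavy] %in% c("O", "OXT", .SC_ACCEPTORS[[rname]])
    b["hbond_acceptor"] <- hbond_hit(res, rheavy[acc], lig, lig_heavy[lig_no],
                                     d[acc, lig_no, drop = FALSE],
                                     donor_side = "ligand", criteria,
                                     lig_hydrogens = lig_hdon_h[lig_no])

    # aromatic: residue template ring vs perceived ligand ring
    if (length(lrings) > 0 && !is.null(.RING_ATOMS[[rname]])) {
      for (ring_def in .RING_ATOMS[[rname]]) {
        ri <- match(ring_def, res$name)
        if (anyNA(ri)) next
        ctr <- colMeans(as.matrix(res[ri, c("x", "y", "z")]))
        for (lc in lring_centroids) {
          if (vec_norm(ctr - lc) <= criteria$aromatic_centroid_cutoff) {
            b["aromatic"] <- TRUE; break
          }
        }
        if (b["aromatic"]) break
      }
    }

    # charged: oppositely signed groups with an N/O pair in range
    grp <- .CHARGED_GROUPS[[rname]]
    if (!is.null(grp)) {
      gi <- which(res$name[rheavy] %in% grp$atoms)
      opp <- if (grp$sign > 0) lchg$neg else lchg$pos
      opp <- match(opp, lig_heavy)
      opp <- opp[!is.na(opp)]
      if (length(gi) && length(opp))
        b["charged"] <- any(d[gi, opp, drop = FALSE] <=
                              criteria$salt_bridge_cutoff)
    }

    b["any"] <- plain_contact || any(b[-1])
    bits[k, ] <- b
  }

  keep <- if (dense) rep(TRUE, length(ukey)) else rowSums(bits) > 0
  structure(list(residues = ukey[keep], labels = unname(labels[keep]),
                 bits = bits[keep, , drop = FALSE],
                 dense = dense, complex_ref = cx$model_id),
            class = "sift_matrix")
}

# Shared H-bond test.  `d` is the donor x acceptor (or acceptor x donor)
# distance submatrix.  Angle is checked only when the donor carries an
# explicit hydrogen.
hbond_hit <- function(res, res_idx, lig, lig_idx, d, donor_side, criteria,
                      lig_hydrogens = NULL) {
  if (length(res_idx) == 0 || length(lig_idx) == 0 || length(d) == 0)
    return(FALSE)
  hits <- which(d <= criteria$hbond_heavy_cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0) return(FALSE)
  for (h in seq_len(nrow(hits))) {
    ri <- res_idx[hits[h, 1]]; li <- lig_idx[hits[h, 2]]
    rpos <- as.numeric(res[ri, c("x", "y", "z")])
    lpos <- as.numeric(lig[li, c("x", "y", "z")])
    if (donor_side == "protein") {
      hs <- attached_hydrogens(res, ri)
      hxyz <- res[hs, c("x", "y", "z"), drop = FALSE]
      dpos <- rpos; apos <- lpos
    } else {
      hs <- lig_hydrogens[[hits[h, 2]]]
      hxyz <- lig[hs, c("x", "y", "z"), drop = FALSE]
      dpos <- lpos; apos <- rpos
    }
    if (length(hs) == 0) return(TRUE)      # distance-only when no H
    ang <- apply(hxyz, 1, function(hp)
      angle_deg(dpos, as.numeric(hp), apos))
    if (any(ang >= criteria$hbond_angle_min)) return(TRUE)
  }
  FALSE
}

#' @export
print.sift_matrix <- function(x, ...) {
  cat("<sift_matrix>", nrow(x$bits), "interacting residues (model",
      x$complex_ref, ")\n")
  invisible(x)
}

# --- averaging and consensus ------------------------------------------------

#' Average fingerprints over a population of complexes
#'
#' The per-residue, per-bit frequency is the fraction of complexes in which
#' that bit is set; residues absent from a complex's matrix contribute 0.
#' This is the ensemble-averaged SIFt used to profile a population of
#' ligands and/or receptor conformations.
#'
#' @param matrices List of `sift_matrix` objects on a common residue
#'   numbering.
#' @return Object of class `sift_profile` with a residues x 9 frequency
#'   matrix and `n_complexes`.
#' @export
average_fingerprint <- function(matrices) {
  if (length(matrices) == 0) stop("no matrices to average")
  stopifnot(all(vapply(matrices, inherits, TRUE, "sift_matrix")))
  keys <- unique(unlist(lapply(matrices, `[[`, "residues")))
  keys <- keys[order_residue_keys(keys)]
  acc <- matrix(0, length(keys), length(.SIFT_BITS),
                dimnames = list(keys, .SIFT_BITS))
  labels <- setNames(rep(NA_character_, length(keys)), keys)
  for (m in matrices) {
    i <- match(m$residues, keys)
    acc[i, ] <- acc[i, ] + m$bits
    labels[i] <- m$labels
  }
  new_sift_profile(keys, unname(labels), acc / length(matrices),
                   length(matrices))
}

order_residue_keys <- function(keys) {
  parts <- regmatches(keys, regexec("^([^:]*):(-?[0-9]+)(.*)$", keys))
  chain <- vapply(parts, `[`, "", 2)
  resno <- as.integer(vapply(parts, `[`, "", 3))
  icode <- vapply(parts, `[`, "", 4)
  order(chain, resno, icode)
}

new_sift_profile <- function(residues, labels, freq, n_complexes) {
  freq <- as.matrix(freq)
  colnames(freq) <- .SIFT_BITS
  if (any(freq < -1e-12 | freq > 1 + 1e-12))
    stop("fingerprint frequencies must lie in [0, 1]")
  if (is.finite(n_complexes) &&
      any(abs(freq * n_complexes - round(freq * n_complexes)) > 1e-9))
    stop("frequencies are not multiples of 1/n_complexes")
  structure(list(residues = residues, labels = labels, freq = freq,
                 n_complexes = n_complexes),
            class = "sift_profile")
}

#' @export
print.sift_profile <- function(x, ...) {
  cat("<sift_profile>", nrow(x$freq), "residues averaged over",
      x$n_complexes, "complexes\n")
  invisible(x)
}

#' Consensus binding-site residues
#'
#' Residues whose selected-bit frequency reaches `cutoff`, the default
#' being the "any contact" bit at 50%.  Ordered by descending frequency,
#' then residue number.
#'
#' @param profile A `sift_profile`.
#' @param cutoff Frequency cutoff in (0, 1].
#' @param bit Bit selector (one of the nine bit names).
#' @return data.frame with columns `residue` (label), `key`, `frequency`.
#' @export
consensus_residues <- function(profile, cutoff = 0.5, bit = "any") {
  stopifnot(inherits(profile, "sift_profile"))
  if (!bit %in% .SIFT_BITS)
    stop("unknown bit selector: ", bit, " (expected one of: ",
         paste(.SIFT_BITS, collapse = ", "), ")")
  if (!(cutoff > 0 && cutoff <= 1)) stop("cutoff must be in (0, 1]")
  f <- profile$freq[, bit]
  sel <- which(f >= cutoff)
  resno <- as.integer(sub("^[A-Za-z]*", "",
                          gsub("[^0-9]*$", "", profile$labels[sel])))
  ord <- order(-f[sel], resno)
  data.frame(residue = profile$labels[sel][ord],
             key = profile$residues[sel][ord],
             frequency = unname(f[sel][ord]),
             stringsAsFactors = FALSE)
}

#' Write a fingerprint profile as a delimited table
#'
#' Emits (and optionally writes) a tab-separated table with one row per
#' residue and the nine frequency columns in canonical order, frequencies
#' rounded to two decimals, rows sorted by descending "any" frequency.
#'
#' @param profile A `sift_profile`.
#' @param file Optional output path.
#' @return Character vector of table lines, invisibly when `file` is given.
#' @export
profile_report <- function(profile, file = NULL) {
  stopifnot(inherits(profile, "sift_profile"))
  ord <- order(-profile$freq[, "any"])
  df <- data.frame(residue = profile$labels[ord],
                   round(profile$freq[ord, , drop = FALSE], 2),
                   check.names = FALSE, stringsAsFactors = FALSE)
  lines <- c(paste(c("residue", .SIFT_BITS), collapse = "\t"),
             apply(df, 1, function(r) paste(trimws(r), collapse = "\t")))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Read a fingerprint profile table
#'
#' Inverse of [profile_report()].  Also used to load externally reported
#' averaged-SIFt tables; those typically omit the underlying complex count,
#' in which case `n_complexes = NA` disables the frequency-granularity
#' check (reported tables may be rounded or internally inconsistent).
#'
#' @param file Path to a profile table.
#' @param n_complexes Number of complexes behind the table (NA if unknown).
#' @return A `sift_profile`.
#' @export
read_profile <- function(file, n_complexes = NA) {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("residue", .SIFT_BITS)
  if (!all(need %in% names(df)))
    stop("profile table must have columns: ", paste(need, collapse = ", "))
  keys <- paste0("?:", sub("^[A-Za-z]*", "", df$residue), "#", seq_len(nrow(df)))
  new_sift_profile(keys, df$residue, as.matrix(df[, .SIFT_BITS]),
                   n_complexes)
}
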