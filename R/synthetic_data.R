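# Synthetic fixtures with known ground truth: planted-interaction pocket
# complexes, pose ensembles with controlled occurrence frequencies and
# RMSD, snapshot energy series, and score tables.  Every generator is a
# pure function of its spec and seed.  Ground truth is derived from the
# construction (planted roles and geometry), never by running the
# detectors under test.

# --- residue geometry templates --------------------------------------------
# Local frames: the planting anchor sits at the origin, +z points OUTWARD
# (away from the pocket centre), and the ligand partner atom is placed at
# (0, 0, -d).  Layouts are geometric stand-ins, not force-field geometry:
# they guarantee that only the anchor atom can enter any interaction
# cutoff, with every other polar atom kept >= 4.3 A and every other carbon
# >= 4.8 A from the partner at default planting distances.

.TEMPLATES <- list(
  "GLY:N" = list(
    names = c("N", "CA", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(0.95, 0, 1.05), c(0.4, 0, 2.45),
                c(1.1, 0.95, 2.95))),
  "GLY:O" = list(
    names = c("O", "C", "CA", "N"),
    xyz = rbind(c(0, 0, 0), c(0, 0.45, 1.14), c(0, 1.65, 1.85),
                c(0, 1.65, 3.25))),
  "GLY:CA" = list(
    names = c("CA", "N", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(0, 1.2, 0.75), c(1.25, 0, 0.85),
                c(1.25, 0.9, 1.95))),
  "ALA:CB" = list(
    names = c("CB", "CA", "N", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(0, 0, 1.52), c(0, 1.2, 2.2),
                c(1.25, 0, 2.3), c(1.3, 0.95, 3.3))),
  "CYS:SG" = list(
    names = c("SG", "CB", "CA", "N", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(0, 0.9, 1.4), c(0, 0.3, 2.7),
                c(0, 1.35, 3.4), c(1.25, 0, 3.3), c(1.3, 0.9, 4.3))),
  "SER:OG" = list(
    names = c("OG", "CB", "CA", "N", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(0, 0.9, 1.1), c(0, 0.3, 2.4),
                c(0, 1.35, 3.1), c(1.25, 0, 3.0), c(1.3, 0.9, 4.0))),
  "GLN:NE2" = list(
    names = c("NE2", "CD", "OE1", "CG", "CB", "CA", "N", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(0, 1.0, 0.8), c(0, 1.9, 1.65),
                c(0, 0.95, 2.3), c(0, 0.3, 3.5), c(0, 1.05, 4.75),
                c(0, 2.2, 5.3), c(1.25, 0.45, 5.4), c(1.3, 1.35, 6.4))),
  "ASN:ND2" = list(
    names = c("ND2", "CG", "OD1", "CB", "CA", "N", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(0, 1.0, 0.8), c(0, 1.9, 1.65),
                c(0, 0.95, 2.3), c(0, 0.25, 3.5), c(0, 1.3, 4.2),
                c(1.25, 0, 4.15), c(1.3, 0.9, 5.15))),
  "LEU:CD1" = list(
    names = c("CD1", "CG", "CD2", "CB", "CA", "N", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(0, 0.8, 1.2), c(0, 2.2, 1.15),
                c(0, 0.75, 2.7), c(0, 0, 3.9), c(0, 1.1, 4.6),
                c(1.25, 0, 4.5), c(1.3, 0.9, 5.5))),
  "MET:SD" = list(
    names = c("SD", "CE", "CG", "CB", "CA", "N", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(0, 1.3, 0.95), c(0, 0.85, 1.75),
                c(0, 0.8, 3.25), c(0, 0, 4.4), c(0, 1.1, 5.1),
                c(1.25, 0, 5.0), c(1.3, 0.9, 6.0))),
  "ASP:OD1" = list(
    names = c("OD1", "CG", "OD2", "CB", "CA", "N", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(0, 1.0, 0.75), c(0, 2.2, 0.55),
                c(0, 0.95, 2.25), c(0, 0.25, 3.45), c(0, 1.3, 4.15),
                c(1.25, 0, 4.1), c(1.3, 0.9, 5.1))),
  "ARG:NH1" = list(
    names = c("NH1", "CZ", "NH2", "NE", "CD", "CG", "CB", "CA", "N", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(0, 1.15, 0.55), c(0, 2.3, 0.5),
                c(0, 1.2, 1.9), c(0, 2.3, 2.6), c(0, 1.75, 3.9),
                c(0, 2.5, 5.0), c(0, 1.8, 6.2), c(0, 2.9, 6.8),
                c(1.25, 1.3, 6.8), c(1.3, 1.9, 7.8))),
  "HIS:NE2" = list(
    names = c("NE2", "CD2", "CG", "ND1", "CE1", "CB", "CA", "N", "C", "O"),
    xyz = rbind(c(0, 0, 0), c(1.15, 0, 0.6), c(1.0, 0, 1.95),
                c(-0.35, 0, 2.2), c(-0.95, 0, 0.95), c(1.75, 0, 3.0),
                c(1.75, 0, 4.5), c(0.75, 0.6, 5.1), c(2.95, 0.4, 5.1),
                c(3.0, 0.6, 6.3)))
)

# Phe template built programmatically: ring centroid is the anchor.
phe_template <- function() {
  ang <- (0:5) * pi / 3
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  list(names = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2",
                 "CB", "CA", "N", "C", "O"),
       xyz = rbind(ring, c(2.3, 0, 0.9), c(2.3, 0, 2.4), c(1.3, 0.6, 3.0),
                   c(3.5, 0.4, 3.0), c(3.6, 0.6, 4.2)))
}

template_for <- function(residue, anchor) {
  if (residue == "PHE" && anchor == "RING") return(phe_template())
  t <- .TEMPLATES[[paste0(residue, ":", anchor)]]
  if (is.null(t)) stop("no template for ", residue, " anchored at ", anchor)
  t
}

# Planting anchors and ligand partner chemistry per interaction class.
.PLANT_ANCHORS <- list(
  hbond_donor    = c(GLN = "NE2", GLY = "N"),
  hbond_acceptor = c(GLY = "O"),
  polar          = c(CYS = "SG"),
  hydrophobic    = c(LEU = "CD1", ALA = "CB"),
  aromatic       = c(PHE = "RING"),
  charged        = c(ARG = "NH1", ASP = "OD1"),
  contact        = c(GLY = "CA", ALA = "CB")
)

# Default planting distances, chosen >= 0.3 A clear of every default
# cutoff boundary so detection is robust to floating-point detail.
.PLANT_DEFAULTS <- c(hbond_donor = 2.9, hbond_acceptor = 2.9, polar = 3.6,
                     hydrophobic = 3.8, aromatic = 4.0, charged = 3.2,
                     contact = 4.0)

# Truth bits implied by the construction for one planted interaction.
# Derived from the planted roles and distances (construction knowledge),
# independent of the detector implementation.
class_truth <- function(class, residue, anchor, d, angle,
                        criteria = geometric_criteria()) {
  b <- setNames(logical(length(.SIFT_BITS)), .SIFT_BITS)
  part <- if (anchor %in% .BACKBONE_NAMES && anchor != "RING")
    "backbone" else "sidechain"
  b[part] <- d <= criteria$contact_cutoff || class == "aromatic"
  hb_ok <- d <= criteria$hbond_heavy_cutoff &&
    (is.na(angle) || angle >= criteria$hbond_angle_min)
  polar_pair <- class %in% c("hbond_donor", "hbond_acceptor", "polar",
                             "charged")
  b["polar"] <- polar_pair && d <= criteria$polar_cutoff
  if (class == "hbond_donor") b["hbond_donor"] <- hb_ok
  if (class == "hbond_acceptor") b["hbond_acceptor"] <- hb_ok
  if (class == "hydrophobic") b["hydrophobic"] <- d <= criteria$contact_cutoff
  if (class == "aromatic") {
    b["aromatic"] <- d <= criteria$aromatic_centroid_cutoff
    # stacked parallel rings: closest carbon pair sits at the centroid
    # distance, so a hydrophobic contact rides along at short range
    b["hydrophobic"] <- d <= criteria$contact_cutoff
  }
  if (class == "charged") {
    b["charged"] <- d <= criteria$salt_bridge_cutoff
    # the charged-group nitrogen/oxygen pair is also a donor/acceptor pair;
    # with no explicit hydrogens the distance-only H-bond rule fires too
    hb <- d <= criteria$hbond_heavy_cutoff
    if (residue == "ARG") b["hbond_donor"] <- hb
    if (residue == "ASP") b["hbond_acceptor"] <- hb
  }
  b["any"] <- d <= criteria$contact_cutoff || any(b)
  b
}

# Icosahedron vertex directions: 12 well-separated pocket directions.
pocket_directions <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, p), c(0, -1, p), c(0, 1, -p), c(0, -1, -p),
             c(1, p, 0), c(-1, p, 0), c(1, -p, 0), c(-1, -p, 0),
             c(p, 0, 1), c(-p, 0, 1), c(p, 0, -1), c(-p, 0, -1))
  v / sqrt(1 + p^2)
}

#' Specification for a planted-interaction complex
#'
#' @param interactions List of plants, each
#'   `list(residue = "GLN", class = "hbond_donor", distance = 2.9,
#'   angle = 165)`.  `distance` and `angle` default to class-specific
#'   values at least 0.3 A clear of every detection cutoff.  Supported
#'   (class, residue) pairs: hbond_donor (GLN, GLY), hbond_acceptor (GLY),
#'   polar (CYS), hydrophobic (LEU, ALA), aromatic (PHE), charged
#'   (ARG, ASP), contact (GLY, ALA).
#' @param pocket_radius Shell radius (A) at which residue anchors sit.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `plant_spec`.
#' @export
plant_spec <- function(interactions = list(), pocket_radius = 8, seed = 1) {
  if (length(interactions) > 10)
    stop("at most 10 planted interactions are supported")
  interactions <- lapply(interactions, function(it) {
    it$class <- match.arg(it$class, names(.PLANT_ANCHORS))
    anchors <- .PLANT_ANCHORS[[it$class]]
    it$residue <- toupper(it$residue %||% names(anchors)[1])
    if (!it$residue %in% names(anchors))
      stop("class ", it$class, " supports residues: ",
           paste(names(anchors), collapse = ", "))
    it$anchor <- anchors[[it$residue]]
    it$distance <- it$distance %||% unname(.PLANT_DEFAULTS[it$class])
    if (it$distance < 1.7)
      stop("unsatisfiable geometry: planted distance below covalent range")
    it$angle <- it$angle %||%
      (if (it$class %in% c("hbond_donor", "hbond_acceptor")) 165 else NA_real_)
    it
  })
  structure(list(interactions = interactions,
                 pocket_radius = pocket_radius, seed = as.integer(seed)),
            class = "plant_spec")
}

# Donor H local position: donor at origin, acceptor at (0,0,-d),
# |DH| = 1.0, requested donor-H...acceptor angle theta at the hydrogen.
donor_h_local <- function(d, theta) {
  th <- theta * pi / 180
  sinA <- sin(th) / d                    # law of sines, |DH| = 1
  A <- asin(min(1, sinA))
  alpha <- pi - th - A                   # angle at the donor
  c(sin(alpha), 0, -cos(alpha))
}

#' Generate a pocket complex with planted interactions
#'
#' Residues are placed on a shell around the origin along well-separated
#' (icosahedral) directions, one per planted interaction, with the ligand
#' partner atoms placed to realise exactly the requested geometry.  Two
#' spectator residues with no ligand contact are always included, along
#' with a three-carbon ligand core at the origin.  The ground-truth bit
#' matrix is recorded from the construction.
#'
#' @param spec A [plant_spec()].
#' @return List: `complex` ([sift_complex()]), `truth` (a `sift_matrix`),
#'   `units` (ligand atom names per plant, used by [make_pose_ensemble()]),
#'   `pdb` (PDB text lines).
#' @export
make_planted_complex <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  dirs <- pocket_directions()
  a_lig <- spec$pocket_radius / 2        # ligand partner shell
  rows <- list(); lig_rows <- list(); units <- list()
  truth <- list()

  for (i in seq_along(spec$interactions)) {
    it <- spec$interactions[[i]]
    u <- dirs[i, ]
    R <- rotation_onto(c(0, 0, 1), u)
    tmpl <- template_for(it$residue, it$anchor)
    anchor_pos <- (a_lig + it$distance) * u
    res_xyz <- sweep(tmpl$xyz %*% t(R), 2, anchor_pos, "+")
    res_names <- tmpl$names
    lig_names <- character(0); lig_local <- NULL

    to_local <- function(v) anchor_pos + R %*% v  # local -> global helper
    d <- it$distance
    if (it$class == "hbond_donor") {
      h <- donor_h_local(d, it$angle)
      res_xyz <- rbind(res_xyz, t(to_local(h)))
      hname <- if (it$anchor == "N") "H" else "HE21"
      res_names <- c(res_names, hname)
      lig_names <- sprintf("O%d", i); lig_local <- rbind(c(0, 0, -d))
    } else if (it$class == "hbond_acceptor") {
      hl <- c(0, 0, -d) + donor_h_local(d, it$angle) * c(1, 1, -1)
      lig_names <- c(sprintf("N%d", i), sprintf("H%d", i))
      lig_local <- rbind(c(0, 0, -d), hl)
    } else if (it$class == "polar") {
      lig_names <- sprintf("O%d", i); lig_local <- rbind(c(0, 0, -d))
    } else if (it$class %in% c("hydrophobic", "contact")) {
      lig_names <- sprintf("C%d", i); lig_local <- rbind(c(0, 0, -d))
    } else if (it$class == "aromatic") {
      ang <- (0:5) * pi / 3
      ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), -d)
      lig_names <- sprintf("C%d%s", i, LETTERS[1:6])
      lig_local <- ring
    } else if (it$class == "charged") {
      if (it$residue == "ARG") {
        # linear carboxylate stand-in pointing away from the guanidinium
        lig_names <- c(sprintf("O%d", i), sprintf("C%d", i),
                       sprintf("O%dB", i))
        lig_local <- rbind(c(0, 0, -d), c(0, 0, -d - 1.25),
                           c(0, 0, -d - 2.5))
      } else {
        lig_names <- sprintf("N%d", i); lig_local <- rbind(c(0, 0, -d))
      }
    }
    lig_xyz <- sweep(lig_local %*% t(R), 2, anchor_pos, "+")

    rows[[i]] <- data.frame(name = res_names, x = res_xyz[, 1],
                            y = res_xyz[, 2], z = res_xyz[, 3],
                            resno = 100L + i, resname = it$residue,
                            stringsAsFactors = FALSE)
    lig_rows[[i]] <- data.frame(name = lig_names, x = lig_xyz[, 1],
                                y = lig_xyz[, 2], z = lig_xyz[, 3],
                                stringsAsFactors = FALSE)
    units[[i]] <- list(atoms = lig_names, residue_key = paste0("A:", 100 + i),
                       label = residue_label(it$residue, 100 + i),
                       class = it$class,
                       bits = class_truth(it$class, it$residue, it$anchor,
                                          d, it$angle))
    truth[[i]] <- units[[i]]$bits
  }

  # spectators: no ligand partner, anchors on unused directions
  n_int <- length(spec$interactions)
  spect <- list()
  for (k in 1:2) {
    u <- dirs[10 + k, ]
    R <- rotation_onto(c(0, 0, 1), u)
    tmpl <- template_for(c("GLY", "ALA")[k], c("CA", "CB")[k])
    xyz <- sweep(tmpl$xyz %*% t(R), 2, spec$pocket_radius * u, "+")
    spect[[k]] <- data.frame(name = tmpl$names, x = xyz[, 1], y = xyz[, 2],
                             z = xyz[, 3], resno = 200L + k,
                             resname = c("GLY", "ALA")[k],
                             stringsAsFactors = FALSE)
  }

  core <- data.frame(name = c("C97", "C98", "C99"),
                     x = c(0.75, -0.75, 0), y = c(0, 0, 1.0), z = 0,
                     stringsAsFactors = FALSE)
  prot <- do.call(rbind, c(rows, spect))
  lig <- rbind(do.call(rbind, c(list(core[, c("name", "x", "y", "z")]),
                                lig_rows)))
  atoms <- rbind(
    atom_table(name = prot$name, x = prot$x, y = prot$y, z = prot$z,
               chain = "A", resno = prot$resno, resname = prot$resname,
               record = "protein"),
    atom_table(name = lig$name, x = lig$x, y = lig$y, z = lig$z,
               chain = "L", resno = 900L, resname = "LIG",
               record = "ligand")
  )
  atoms$serial <- seq_len(nrow(atoms))
  cx <- sift_complex(atoms, model_id = 1L,
                     metadata = list(generator = "make_planted_complex",
                                     seed = spec$seed))
  validate_separation(cx, units)

  bits <- if (n_int > 0) do.call(rbind, truth) else
    matrix(FALSE, 0, length(.SIFT_BITS))
  colnames(bits) <- .SIFT_BITS
  keys <- vapply(units, `[[`, "", "residue_key")
  rownames(bits) <- keys
  truth_m <- structure(list(residues = keys,
                            labels = vapply(units, `[[`, "", "label"),
                            bits = bits, dense = FALSE, complex_ref = 1L),
                       class = "sift_matrix")
  f <- tempfile(fileext = ".pdb")
  write_pdb_complexes(cx, f)
  pdb <- readLines(f); unlink(f)
  list(complex = cx, truth = truth_m, units = units, spec = spec, pdb = pdb)
}

# Construction-time check that no non-partner residue/ligand atom pair
# comes near any detection cutoff (plain distance arithmetic).
validate_separation <- function(cx, units, guard = 4.8) {
  prot <- protein_atoms(cx); lig <- ligand_atoms(cx)
  pkey <- residue_key(prot$chain, prot$resno, prot$icode)
  partner <- setNames(lapply(units, `[[`, "atoms"),
                      vapply(units, `[[`, "", "residue_key"))
  d <- cross_dist(prot[, c("x", "y", "z")], lig[, c("x", "y", "z")])
  for (i in seq_len(nrow(prot))) {
    own <- partner[[pkey[i]]]
    near <- which(d[i, ] < guard)
    bad <- near[!(lig$name[near] %in% own)]
    # the planted hydrogen of an H-bond donor may approach its own acceptor
    if (length(bad) > 0 && !prot$elem[i] == "H")
      stop("unsatisfiable geometry: ", pkey[i], " atom ", prot$name[i],
           " within ", guard, " A of non-partner ligand atom(s) ",
           paste(lig$name[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Specification for a synthetic pose ensemble
#'
#' @param n_poses Number of stochastic poses.
#' @param p Per-interaction occurrence probability in `[0, 1]` (scalar or
#'   one value per planted interaction).
#' @param rmsd_targets Heavy-atom RMSD targets (A); one extra rigidly
#'   displaced pose is appended per target.
#' @param seed Integer seed.
#' @return List of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_poses = 20, p = 1, rmsd_targets = numeric(0),
                          seed = 1) {
  stopifnot(n_poses >= 1, all(p >= 0 & p <= 1), all(rmsd_targets >= 0))
  structure(list(n_poses = as.integer(n_poses), p = p,
                 rmsd_targets = rmsd_targets, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate a pose ensemble with planted occurrence frequencies
#'
#' Starting from a planted complex, each stochastic pose keeps each
#' planted interaction with probability `p`; switched-off interactions
#' have their ligand unit translated radially inward, far out of range of
#' every cutoff.  One additional pose per `rmsd_target` displaces the
#' entire ligand rigidly by that distance, which fixes its heavy-atom
#' RMSD to the base pose exactly.
#'
#' @param base Result of [make_planted_complex()].
#' @param spec An [ensemble_spec()].
#' @return List: `ensemble` ([pose_ensemble()]), `occurrence` (pose x
#'   interaction logical matrix for the stochastic poses), `expected_freq`
#'   (per-interaction observed frequency), `rmsd_poses` (data.frame of
#'   pose index and target).
#' @export
make_pose_ensemble <- function(base, spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  units <- base$units
  p <- rep(spec$p, length.out = length(units))
  set.seed(spec$seed)
  dirs <- pocket_directions()
  a_lig <- base$spec$pocket_radius / 2

  occ <- matrix(TRUE, spec$n_poses, length(units))
  poses <- vector("list", spec$n_poses)
  for (j in seq_len(spec$n_poses)) {
    cx <- base$complex
    for (i in seq_along(units)) {
      on <- runif(1) < p[i]
      occ[j, i] <- on
      if (!on) {
        idx <- cx$atoms$name %in% units[[i]]$atoms &
          cx$atoms$record == "ligand"
        shift <- (1.2 - a_lig) * dirs[i, ]
        cx$atoms[idx, c("x", "y", "z")] <-
          sweep(cx$atoms[idx, c("x", "y", "z")], 2, shift, "+")
      }
    }
    cx$model_id <- j
    poses[[j]] <- cx
  }

  rmsd_df <- data.frame(pose_index = integer(0), target = numeric(0))
  for (k in seq_along(spec$rmsd_targets)) {
    t <- spec$rmsd_targets[k]
    w <- rnorm(3); w <- w / vec_norm(w)
    cx <- base$complex
    idx <- cx$atoms$record == "ligand"
    cx$atoms[idx, c("x", "y", "z")] <-
      sweep(cx$atoms[idx, c("x", "y", "z")], 2, t * w, "+")
    cx$model_id <- spec$n_poses + k
    poses[[spec$n_poses + k]] <- cx
    rmsd_df <- rbind(rmsd_df,
                     data.frame(pose_index = spec$n_poses + k, target = t))
  }

  list(ensemble = pose_ensemble(poses, source = "make_pose_ensemble"),
       occurrence = occ,
       expected_freq = if (length(units)) colMeans(occ) else numeric(0),
       rmsd_poses = rmsd_df)
}

#' Generate a synthetic per-snapshot energy series
#'
#' Independent Gaussian draws around stated component means, emulating the
#' fluctuation of MM-PBSA component differences along an equilibrated
#' trajectory.
#'
#' @param means Named numeric vector or list with `dE_ele`, `dE_vdW`,
#'   `dG_PB`, `dG_np`.
#' @param sigma Per-component standard deviation (kcal/mol).
#' @param n Number of snapshots.
#' @param seed Integer seed.
#' @param file Optional path; when given the table is written as TSV.
#' @return data.frame with `snapshot` and the four component columns.
#' @export
make_energy_series <- function(means, sigma = 2, n = 1000, seed = 1,
                               file = NULL) {
  stopifnot(n >= 1, sigma >= 0)
  means <- unlist(means)
  need <- c("dE_ele", "dE_vdW", "dG_PB", "dG_np")
  if (!all(need %in% names(means)))
    stop("means must name: ", paste(need, collapse = ", "))
  set.seed(seed)
  df <- data.frame(snapshot = seq_len(n))
  for (k in need) df[[k]] <- rnorm(n, means[[k]], sigma)
  if (!is.null(file))
    write.table(format(df, digits = 10, trim = TRUE), file, sep = "\t",
                quote = FALSE, row.names = FALSE)
  df
}

#' Generate a docking score table with a planted best substrate
#'
#' The best entry beats the second-best by exactly `gap`; the remaining
#' scores are drawn uniformly above the second-best.
#'
#' @param best_label Label of the planted best substrate.
#' @param gap Score gap (kcal/mol) between best and second-best.
#' @param n_entries Number of rows (>= 2).
#' @param seed Integer seed.
#' @param labels Optional labels for the other entries.
#' @param best_score Score of the planted best entry.
#' @param file Optional TSV output path.
#' @return data.frame with columns `ligand`, `score`.
#' @export
make_score_table <- function(best_label = "R-AMC", gap = 2.1,
                             n_entries = 20, seed = 1, labels = NULL,
                             best_score = -10.4, file = NULL) {
  stopifnot(n_entries >= 2, gap >= 0)
  if (is.null(labels)) {
    aa <- setdiff(names(.AA3), sub("-.*", "", best_label))
    labels <- paste0(aa, "-AMC")
  }
  labels <- setdiff(labels, best_label)[seq_len(n_entries - 1)]
  set.seed(seed)
  second <- best_score + gap
  others <- if (n_entries > 2)
    round(second + sort(runif(n_entries - 2, 0.1, 5)), 1) else numeric(0)
  df <- data.frame(ligand = c(best_label, labels),
                   score = c(best_score, second, others),
                   stringsAsFactors = FALSE)
  if (!is.null(file))
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

# --- zmCP1-mini triage pocket ----------------------------------------------

.MINI_DIRECTIONS <- local({
  n <- function(v) v / sqrt(sum(v^2))
  list(
    `149` = c(1, 0, 0),              # Cys, nucleophile SG
    `147` = n(c(0.866, 0.5, 0)),     # Gly, S1 (adjacent to the oxyanion side)
    `143` = n(c(0.5, 0.866, 0)),     # Gln, oxyanion hole
    `148` = n(c(0.7, 0.35, -0.62)),  # Cys (non-conserved oxyanion candidate)
    `189` = n(c(0.866, -0.5, 0)),    # Cys, S1
    `190` = n(c(0.64, -0.766, 0)),   # Asp, S1
    `191` = n(c(0.34, -0.94, 0)),    # Gly, S1
    `285` = c(0, 1, 0),              # His, triad
    `306` = n(c(-0.5, 0.866, 0)),    # Asn, triad
    `193` = n(c(0.57, 0.57, 0.59)),  # Leu, S2
    `194` = n(c(0, 0.71, 0.71)),     # Met, S2
    `259` = n(c(-0.5, 0.5, 0.707)),  # Ala, S2
    `283` = c(0, 0, 1),              # Leu, S2
    `286` = n(c(0.71, 0, 0.71))      # Ala, S2
  )
})

.MINI_RESIDUES <- c(`143` = "GLN", `147` = "GLY", `148` = "CYS",
                    `149` = "CYS", `189` = "CYS", `190` = "ASP",
                    `191` = "GLY", `193` = "LEU", `194` = "MET",
                    `259` = "ALA", `283` = "LEU", `285` = "HIS",
                    `286` = "ALA", `306` = "ASN")

.MINI_ANCHORS <- c(GLN = "NE2", GLY = "CA", CYS = "SG", ASP = "OD1",
                   LEU = "CD1", MET = "SD", ALA = "CB", HIS = "NE2",
                   ASN = "ND2")

#' Toy zmCP1 active-site pocket
#'
#' A minimal geometric pocket carrying the annotated zmCP1 active-site
#' residues (Gln143, Gly147, Cys148, Cys149, Cys189, Asp190, Gly191,
#' Leu193, Met194, Ala259, Leu283, His285, Ala286, Asn306) on a shell
#' around the origin, with functional-atom tips pointing inward.  The
#' catalytic sulfur, oxyanion-hole donors and S1/S2 subsites sit in
#' mutually reachable positions so the three binding-mode rules can all be
#' satisfied by a single toy-substrate pose.
#'
#' @param tip_radius Radius (A) at which functional tips sit.
#' @return data.frame of protein atoms (see [atom_table()]).
#' @export
zmcp1_mini_pocket <- function(tip_radius = 5.2) {
  rows <- lapply(names(.MINI_DIRECTIONS), function(rn) {
    res <- .MINI_RESIDUES[[rn]]
    anchor <- .MINI_ANCHORS[[res]]
    tmpl <- template_for(res, anchor)
    u <- .MINI_DIRECTIONS[[rn]]
    R <- rotation_onto(c(0, 0, 1), u)
    xyz <- sweep(tmpl$xyz %*% t(R), 2, tip_radius * u, "+")
    data.frame(name = tmpl$names, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               resno = as.integer(rn), resname = res,
               stringsAsFactors = FALSE)
  })
  prot <- do.call(rbind, rows)
  prot <- prot[order(prot$resno), , drop = FALSE]
  atom_table(name = prot$name, x = prot$x, y = prot$y, z = prot$z,
             chain = "A", resno = prot$resno, resname = prot$resname,
             record = "protein")
}

#' Pose a toy AMC-like substrate in the zmCP1-mini pocket
#'
#' Builds a rigid planar bicyclic stand-in for an R-AMC-like substrate
#' (naphthalene-like ring system C1-C10, amide nitrogen N1, scissile
#' carbonyl carbon C11 with oxygen O11, and a guanidinium-like P1 group
#' CB1/CZ1/N2/N3; optionally a P2 group CB2/CG2) and places it so that the
#' scissile carbon sits `d_catalytic` from Cys149 SG and the P1 nitrogen
#' `d_oxyanion` from Gln143 NE2.  With `p1_in_s1 = FALSE` the P1 group is
#' pushed out of reach of the S1 residues; with `p2_in_s2 = TRUE` the P2
#' carbons are placed in contact with the S2 cluster.
#'
#' @param pocket Atom table from [zmcp1_mini_pocket()].
#' @param d_catalytic Scissile-carbon to nucleophile-sulfur distance (A).
#' @param d_oxyanion P1-nitrogen to Gln143 NE2 distance (A).
#' @param p1_in_s1 Keep the P1 group within contact of the S1 subsite.
#' @param p2_in_s2 Place the P2 group within contact of the S2 subsite.
#' @param model_id Model number for the returned complex.
#' @return A [sift_complex()] combining the pocket and the posed ligand.
#' @export
make_triage_pose <- function(pocket, d_catalytic = 4.0, d_oxyanion = 2.9,
                             p1_in_s1 = TRUE, p2_in_s2 = FALSE,
                             model_id = 1L) {
  tipr <- 5.2
  u149 <- .MINI_DIRECTIONS[["149"]]
  u143 <- .MINI_DIRECTIONS[["143"]]
  u147 <- .MINI_DIRECTIONS[["147"]]
  u193 <- .MINI_DIRECTIONS[["193"]]
  sg <- tipr * u149
  ne2 <- tipr * u143

  c11 <- sg - d_catalytic * u149
  o11 <- c11 + c(0, 0, 1.23)
  n1 <- c11 - 1.33 * u149
  # ring system: two fused hexagons in the xy-plane, tucked toward -x
  ang <- pi / 6 + (0:5) * pi / 3
  hex1 <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  hex2 <- sweep(hex1, 2, c(2 * 1.39 * cos(pi / 6), 0, 0), "+")
  ring <- unique(round(rbind(hex1, hex2), 6))
  ring <- sweep(ring, 2, n1 - c(4.8, 0, 0), "+")

  p1_dir <- if (p1_in_s1) u143 else unit_vec(c(-0.5, -0.3, -0.8))
  n2 <- if (p1_in_s1) ne2 - d_oxyanion * u143 else
    c(0, 0, -6) + d_oxyanion * p1_dir
  cz1 <- n2 - 1.33 * p1_dir
  n3 <- cz1 - 1.33 * p1_dir
  cb1 <- n3 - 1.5 * p1_dir

  if (p2_in_s2) {
    tip193 <- tipr * u193
    cb2 <- tip193 - 3.8 * u193
    cg2 <- cb2 - 1.5 * u193
  } else {
    cb2 <- c(-1.5, -1.5, -4.5); cg2 <- cb2 - c(0, 0, 1.5)
  }

  lig_xyz <- rbind(ring, n1, c11, o11, cb1, cz1, n2, n3, cb2, cg2)
  lig_names <- c(paste0("C", 1:10), "N1", "C11", "O11",
                 "CB1", "CZ1", "N2", "N3", "CB2", "CG2")
  lig <- atom_table(name = lig_names, x = lig_xyz[, 1], y = lig_xyz[, 2],
                    z = lig_xyz[, 3], chain = "L", resno = 901L,
                    resname = "RMC", record = "ligand")
  sift_complex(rbind(pocket, lig), model_id = model_id)
}
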