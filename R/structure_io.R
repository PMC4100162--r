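#' @section Atom tables:
#' Atoms are kept in a plain data.frame with one row per atom and columns
#' `serial`, `name`, `elem`, `x`, `y`, `z`, `chain`, `resno`, `icode`,
#' `resname`, `record` (`"protein"` or `"ligand"`) and `charge` (partial
#' charge, NA when unknown).  All coordinates are Angstrom.
#' @name atom-tables
#' @keywords internal
NULL

#' Build an atom table
#'
#' Low-level constructor for the per-atom data.frame used throughout the
#' package.  Vectors are recycled by `data.frame()` rules; `serial` defaults
#' to the row index.
#'
#' @param name Atom names (PDB convention, e.g. `"CA"`, `"SG"`).
#' @param elem Element symbols; inferred from the first letter(s) of `name`
#'   when missing.
#' @param x,y,z Coordinates in Angstrom.
#' @param chain Chain identifier.
#' @param resno Residue number.
#' @param icode Insertion code (`""` when none).
#' @param resname Three-letter residue name.
#' @param record `"protein"` or `"ligand"`.
#' @param charge Optional partial charge (elementary-charge units).
#' @param serial Optional atom serial numbers.
#' @return A data.frame of atoms.
#' @export
atom_table <- function(name, elem = NULL, x, y, z, chain = "A", resno = 1L,
                       icode = "", resname = "UNK", record = "protein",
                       charge = NA_real_, serial = NULL) {
  if (is.null(elem)) elem <- guess_element(name)
  df <- data.frame(
    serial = if (is.null(serial)) seq_along(name) else serial,
    name = as.character(name), elem = toupper(as.character(elem)),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    chain = as.character(chain), resno = as.integer(resno),
    icode = as.character(icode), resname = as.character(resname),
    record = as.character(record), charge = as.numeric(charge),
    stringsAsFactors = FALSE
  )
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)), all(is.finite(df$z)),
            all(nzchar(df$elem)))
  if (anyDuplicated(df$serial)) stop("atom serial numbers must be unique")
  df
}

# Element from a PDB atom name: strip digits/primes, take leading letters;
# two-letter elements only when unambiguous (CL, BR).
guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", as.character(name)))
  el <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  el[two %in% c("CL", "BR")] <- two[two %in% c("CL", "BR")]
  el[el == ""] <- "X"
  el
}

#' Residue keys and labels
#'
#' A residue key is the string `"<chain>:<resno><icode>"` (e.g. `"A:149"`),
#' unique within a model.  A residue label is the one-letter code followed
#' by the number (e.g. `"C149"`), the form used in fingerprint reports.
#'
#' @param chain,resno,icode Residue identifiers.
#' @return Character vector of keys.
#' @export
residue_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resno, icode)
}


#' @rdname residue_key
#' @param resname Three-letter residue names.
#' @export
residue_label <- function(resname, resno) {
  one <- .AA1[toupper(resname)]
  one[is.na(one)] <- "X"
  paste0(one, resno)
}

# ---------------------------------------------------------------------------
# Residue classification

#' Default residue class table
#'
#' Maps each canonical amino acid to a subset of the four interaction
#' classes used by the fingerprint: polar, hydrophobic, aromatic, charged.
#' Classes overlap (His is aromatic, polar and charged).  Users may supply
#' their own table to [classify_residue()].
#'
#' @return Named list: residue name -> character vector of classes.
#' @export
residue_class_table <- function() {
  tab <- list(
    hydrophobic = c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "PRO", "GLY"),
    aromatic    = c("PHE", "TYR", "TRP", "HIS"),
    polar       = c("SER", "THR", "ASN", "GLN", "CYS", "TYR", "HIS", "TRP"),
    charged     = c("ASP", "GLU", "LYS", "ARG", "HIS")
  )
  res <- unique(unlist(tab))
  out <- lapply(res, function(r) names(tab)[vapply(tab, function(v) r %in% v, logical(1))])
  names(out) <- res
  out
}

#' Classify a residue by name
#'
#' @param name Three-letter residue code.
#' @param class_table Table as returned by [residue_class_table()].
#' @param strict Error on unknown residues (default) or return an empty
#'   class set with a warning.
#' @return Character vector of classes (possibly empty).
#' @export
classify_residue <- function(name, class_table = residue_class_table(),
                             strict = TRUE) {
  name <- toupper(name)
  if (!name %in% names(class_table)) {
    if (strict) stop("unknown residue name: ", name)
    warning("unknown residue name: ", name, "; returning empty class set")
    return(character(0))
  }
  class_table[[name]]
}

.BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3")

#' Partition a residue's atoms into backbone and side chain
#'
#' Backbone atoms are N, CA, C, O (plus OXT and backbone hydrogens); all
#' other atoms are side chain.  Glycine has an empty side chain.
#'
#' @param atom_names Character vector of atom names for one residue.
#' @return List with components `backbone` and `sidechain` (disjoint,
#'   covering all input names).
#' @export
partition_backbone <- function(atom_names) {
  bb <- atom_names %in% .BACKBONE_NAMES
  if (!any(atom_names %in% c("N", "CA", "C", "O")))
    warning("residue lacks standard backbone atoms; partitioning over present atoms")
  list(backbone = atom_names[bb], sidechain = atom_names[!bb])
}

# ---------------------------------------------------------------------------
# Complexes and ensembles

#' Construct a protein-ligand complex
#'
#' @param atoms Atom table (see [atom_table()]) containing protein and
#'   ligand rows (column `record`).
#' @param model_id Integer model identifier.
#' @param metadata Optional named list.
#' @return An object of class `sift_complex`.
#' @export
sift_complex <- function(atoms, model_id = 1L, metadata = list()) {
  stopifnot(is.data.frame(atoms))
  lig <- atoms[atoms$record == "ligand", , drop = FALSE]
  if (nrow(lig) == 0) stop("complex has no ligand atoms")
  if (length(unique(lig$resname)) > 1)
    stop("complex must contain exactly one ligand species, got: ",
         paste(unique(lig$resname), collapse = ", "))
  prot <- atoms[atoms$record == "protein", , drop = FALSE]
  ord <- order(prot$chain, prot$resno, prot$icode, prot$serial)
  atoms <- rbind(prot[ord, , drop = FALSE], lig)
  atoms$serial <- seq_len(nrow(atoms))
  structure(list(model_id = as.integer(model_id), atoms = atoms,
                 ligand_resname = lig$resname[1], metadata = metadata),
            class = "sift_complex")
}

#' @export
print.sift_complex <- function(x, ...) {
  p <- x$atoms$record == "protein"
  cat("<sift_complex> model", x$model_id, "-",
      length(unique(residue_key(x$atoms$chain[p], x$atoms$resno[p], x$atoms$icode[p]))),
      "protein residues,", sum(!p), "ligand atoms (", x$ligand_resname, ")\n")
  invisible(x)
}

protein_atoms <- function(cx) cx$atoms[cx$atoms$record == "protein", , drop = FALSE]
ligand_atoms  <- function(cx) cx$atoms[cx$atoms$record == "ligand", , drop = FALSE]

#' Construct a pose ensemble
#'
#' @param poses List of [sift_complex()] objects sharing one protein atom
#'   inventory and one ligand atom inventory.
#' @param scores Optional numeric docking scores (kcal/mol), NA allowed.
#' @param source Free-text provenance.
#' @return An object of class `pose_ensemble`.
#' @export
pose_ensemble <- function(poses, scores = NULL, source = "") {
  if (length(poses) < 1) stop("ensemble must contain at least one pose")
  inv <- lapply(poses, function(p) {
    la <- ligand_atoms(p)
    paste(sort(paste(la$name, la$elem)), collapse = "|")
  })
  if (length(unique(unlist(inv))) != 1)
    stop("inconsistent ensemble: ligand atom inventory differs across models")
  np <- vapply(poses, function(p) nrow(protein_atoms(p)), integer(1))
  if (length(unique(np)) != 1)
    stop("inconsistent ensemble: protein atom count differs across models")
  if (is.null(scores)) scores <- rep(NA_real_, length(poses))
  stopifnot(length(scores) == length(poses))
  structure(list(poses = poses, scores = as.numeric(scores), source = source),
            class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat("<pose_ensemble>", length(x$poses), "poses of",
      x$poses[[1]]$ligand_resname,
      if (any(!is.na(x$scores))) "(scored)" else "", "\n")
  invisible(x)
}

#' @export
length.pose_ensemble <- function(x) length(x$poses)

# ---------------------------------------------------------------------------
# PDB input/output (bio3d-backed)

#' Parse PDB text into a pose ensemble
#'
#' Reads a (possibly multi-MODEL) PDB file or character vector of PDB lines.
#' HETATM groups matching `ligand_selector` become the ligand; each MODEL
#' becomes one pose.  Waters are discarded by default; of alternate
#' locations only altloc A is kept.
#'
#' @param pdb File path or character vector of PDB lines.
#' @param ligand_selector Residue name(s) identifying the ligand, or a list
#'   `list(chain = ...)` selecting by chain.
#' @param keep_waters Keep HOH/WAT residues as protein-side spectators.
#' @return A [pose_ensemble()].
#' @export
parse_complexes <- function(pdb, ligand_selector, keep_waters = FALSE) {
  path <- pdb
  if (length(pdb) > 1 || grepl("\n", pdb[1], fixed = TRUE) ||
      !file.exists(pdb[1])) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(pdb, collapse = "\n"), "\n")), path)
  }
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- p$atom
  nmod <- nrow(p$xyz)

  keep <- rep(TRUE, nrow(at))
  alt <- at$alt
  if (!is.null(alt)) keep <- keep & (is.na(alt) | alt %in% c("", " ", "A"))
  if (!keep_waters) keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))

  if (is.list(ligand_selector)) {
    is_lig <- at$chain %in% ligand_selector$chain
  } else {
    is_lig <- at$resid %in% ligand_selector
  }
  if (!any(is_lig & keep)) stop("ligand not found: selector matched no residue")

  icode <- at$insert
  icode[is.na(icode)] <- ""
  poses <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    xyz <- matrix(p$xyz[m, ], ncol = 3, byrow = TRUE)
    atoms <- atom_table(
      name = at$elety[keep], elem = element_from_bio3d(at$elesy[keep], at$elety[keep]),
      x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
      chain = ifelse(is.na(at$chain[keep]), "A", at$chain[keep]),
      resno = at$resno[keep], icode = icode[keep], resname = at$resid[keep],
      record = ifelse(is_lig[keep], "ligand", "protein")
    )
    poses[[m]] <- sift_complex(atoms, model_id = m)
  }
  pose_ensemble(poses, source = if (is.character(pdb) && length(pdb) == 1 &&
                                    file.exists(pdb)) pdb else "text")
}

element_from_bio3d <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- el == ""
  el[miss] <- guess_element(elety[miss])
  el
}

#' Write a complex or ensemble as PDB text
#'
#' Multi-pose ensembles are written as multi-MODEL files.  Coordinates are
#' written at standard PDB precision (3 decimals).  With
#' `charges_in_occupancy = TRUE` partial charges are stored in the
#' occupancy column (a PQR-like convention for round-tripping charges
#' through the format, which has no charge field).
#'
#' @param x A [sift_complex()] or [pose_ensemble()].
#' @param file Output path.
#' @param charges_in_occupancy Stash partial charges in the occupancy
#'   column.
#' @return `file`, invisibly.
#' @export
write_pdb_complexes <- function(x, file, charges_in_occupancy = FALSE) {
  if (inherits(x, "sift_complex")) x <- pose_ensemble(list(x))
  stopifnot(inherits(x, "pose_ensemble"))
  at0 <- x$poses[[1]]$atoms
  xyz <- do.call(rbind, lapply(x$poses, function(p)
    as.vector(t(as.matrix(p$atoms[, c("x", "y", "z")])))))
  o <- rep(1, nrow(at0))
  if (charges_in_occupancy) {
    o <- at0$charge
    o[is.na(o)] <- 0
  }
  bio3d::write.pdb(
    file = file, xyz = xyz,
    type = ifelse(at0$record == "ligand", "HETATM", "ATOM"),
    resno = at0$resno, resid = at0$resname, eleno = at0$serial,
    elety = at0$name, chain = at0$chain,
    insert = ifelse(at0$icode == "", NA, at0$icode),
    o = o, b = rep(0, nrow(at0)), elesy = at0$elem
  )
  invisible(file)
}

# ---------------------------------------------------------------------------
# Enzyme annotation

#' Construct an enzyme active-site annotation
#'
#' @param catalytic_triad Character vector of residue keys.
#' @param oxyanion_hole Character vector of residue keys (may overlap the
#'   triad).
#' @param subsites Named list, subsite label (S1, S2, ...) -> residue keys.
#' @param nucleophile List `list(residue = key, atom = name)` locating the
#'   catalytic nucleophile atom.
#' @return Object of class `enzyme_annotation`.
#' @export
enzyme_annotation <- function(catalytic_triad, oxyanion_hole, subsites,
                              nucleophile) {
  all_sub <- unlist(subsites, use.names = FALSE)
  if (anyDuplicated(all_sub))
    stop("subsite residue sets must be pairwise disjoint")
  stopifnot(is.list(nucleophile), !is.null(nucleophile$residue),
            !is.null(nucleophile$atom))
  structure(list(catalytic_triad = catalytic_triad,
                 oxyanion_hole = oxyanion_hole,
                 subsites = subsites, nucleophile = nucleophile),
            class = "enzyme_annotation")
}

#' Read an annotation file
#'
#' Plain-text `key: values` format; `#` starts a comment.  Recognised keys:
#' `catalytic_triad`, `oxyanion_hole`, `subsite <LABEL>`, `nucleophile`
#' (residue key followed by atom name).
#'
#' @param file Path to the annotation file.
#' @return An [enzyme_annotation()].
#' @export
read_annotation <- function(file) {
  ln <- readLines(file)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln[nzchar(trimws(ln))])
  kv <- strsplit(ln, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  toks <- strsplit(vals, "[[:space:]]+")
  names(toks) <- keys
  sub_i <- grep("^subsite ", keys)
  subsites <- toks[sub_i]
  names(subsites) <- sub("^subsite ", "", keys[sub_i])
  nuc <- toks[["nucleophile"]]
  enzyme_annotation(
    catalytic_triad = toks[["catalytic_triad"]],
    oxyanion_hole = toks[["oxyanion_hole"]],
    subsites = subsites,
    nucleophile = list(residue = nuc[1], atom = nuc[2])
  )
}

#' Default zmCP1 active-site annotation
#'
#' Loads the shipped annotation for maize cysteine protease 1 (mature-chain
#' numbering): catalytic triad Cys149/His285/Asn306, oxyanion hole
#' Gln143/Cys149, S1 = \{Gly147, Cys189, Asp190, Gly191\}, S2 = \{Leu193,
#' Met194, Ala259, Leu283, Ala286\} (Ala259 is retained from the in-text S2
#' list; a four-residue variant without it also circulates) and nucleophile
#' Cys149 SG.
#'
#' @param chain Chain identifier the residue numbers live on.
#' @return An [enzyme_annotation()].
#' @export
zmcp1_annotation <- function(chain = "A") {
  f <- system.file("extdata", "zmcp1_annotation.txt", package = "specsift")
  ann <- read_annotation(f)
  if (chain != "A") {
    swap <- function(k) sub("^A:", paste0(chain, ":"), k)
    ann$catalytic_triad <- swap(ann$catalytic_triad)
    ann$oxyanion_hole <- swap(ann$oxyanion_hole)
    ann$subsites <- lapply(ann$subsites, swap)
    ann$nucleophile$residue <- swap(ann$nucleophile$residue)
  }
  ann
}
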