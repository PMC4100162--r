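# Substrate ranking from docking score tables and pipeline orchestration.

#' Read a docking score table
#'
#' Two-column delimited text (ligand label, docking score in kcal/mol,
#' lower = better binding).  Labels must be unique and scores numeric.
#'
#' @param file Path to the table (tab- or comma-separated, with header).
#' @param position Optional position label (`"P1"`, `"P2"`, ...).
#' @return Object of class `score_table`: data.frame `entries` with
#'   columns `ligand`, `score`, plus `position`.
#' @export
read_score_table <- function(file, position = NA_character_) {
  sep <- if (grepl("\\.csv$", file)) "," else "\t"
  df <- read.delim(file, sep = sep, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("score table needs two columns (label, score)")
  names(df)[1:2] <- c("ligand", "score")
  df$ligand <- trimws(df$ligand)
  bad <- which(is.na(suppressWarnings(as.numeric(df$score))))
  if (length(bad) > 0)
    stop("non-numeric score in row(s): ", paste(bad, collapse = ", "))
  df$score <- as.numeric(df$score)
  dup <- df$ligand[duplicated(df$ligand)]
  if (length(dup) > 0)
    stop("duplicate ligand label(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(df$score))) stop("scores must be finite")
  structure(list(entries = df[, c("ligand", "score")], position = position),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("<score_table>", nrow(x$entries), "ligands",
      if (!is.na(x$position)) paste0("(", x$position, ")"), "\n")
  invisible(x)
}


#' Amino-acid identity behind a substrate label
#'
#' @param label Substrate labels such as `"R-AMC"` or `"F-R-AMC"`.
#' @return Three-letter amino-acid codes of the varied (first) residue.
#' @export
ligand_residue <- function(label) {
  first <- toupper(sub("-.*$", "", label))
  unname(.AA3[first])
}

#' Rank substrates by docking score
#'
#' Ascending sort (lower score = better binder), ties broken
#' alphabetically by label for determinism.  Reports the best and worst
#' substrates and the top-2 gap.
#'
#' @param table A [read_score_table()] result.
#' @param lower_is_better Docking-score convention flag.
#' @return List of class `preference_call`: `position`, `best`, `worst`
#'   (each list(ligand, score, residue)), `gap_top2`, `ranked`
#'   (data.frame).
#' @export
rank_substrates <- function(table, lower_is_better = TRUE) {
  stopifnot(inherits(table, "score_table"))
  df <- table$entries
  if (nrow(df) < 2) stop("ranking needs at least two entries")
  s <- if (lower_is_better) df$score else -df$score
  ord <- order(s, df$ligand)
  ranked <- df[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  ranked$rank <- seq_len(nrow(ranked))
  ranked$residue <- ligand_residue(ranked$ligand)
  as_entry <- function(i) list(ligand = ranked$ligand[i],
                               score = ranked$score[i],
                               residue = ranked$residue[i])
  structure(list(position = table$position,
                 best = as_entry(1), worst = as_entry(nrow(ranked)),
                 gap_top2 = abs(ranked$score[2] - ranked$score[1]),
                 ranked = ranked),
            class = "preference_call")
}

#' @export
print.preference_call <- function(x, ...) {
  cat(sprintf("<preference_call>%s best %s (%.1f), worst %s (%.1f), top-2 gap %.1f kcal/mol\n",
              if (!is.na(x$position)) paste0(" ", x$position, ":") else "",
              x$best$ligand, x$best$score, x$worst$ligand, x$worst$score,
              x$gap_top2))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Orchestration

#' Run the full specificity analysis
#'
#' Executes the enabled stages in order - binding-mode triage, interaction
#' fingerprinting over poses, consensus extraction, substrate ranking and
#' MM-PBSA averaging - and writes a report directory of delimited tables.
#' Stages are independent: a stage whose inputs are missing from `config`
#' is skipped with a logged warning (or an error in strict mode).  Outputs
#' carry no timestamps, so reruns with identical inputs are byte-identical.
#'
#' @param config Named list.  Recognised elements: `ensemble` (path to a
#'   multi-MODEL PDB), `ligand_selector`, `scores` (numeric docking scores
#'   for the ensemble), `annotation` (path or [enzyme_annotation()]),
#'   `p_groups`, `rules` ([triage_rules()]), `criteria`
#'   ([geometric_criteria()]), `consensus_cutoff`, `score_tables` (named
#'   list of paths), `energy_series` (named list of paths).
#' @param out_dir Report directory (created if absent).
#' @param strict Error instead of skipping stages with missing inputs.
#' @return Invisible list with the stage results and the paths written.
#' @export
run_analysis <- function(config, out_dir, strict = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  skip <- function(stage, why) {
    if (strict) stop(stage, ": ", why)
    note("skip ", stage, ": ", why)
    NULL
  }
  out <- list(paths = character(0))

  criteria <- config$criteria %||% geometric_criteria()
  ens <- NULL
  if (!is.null(config$ensemble)) {
    ens <- parse_complexes(config$ensemble,
                           config$ligand_selector %||% "AMC")
    if (!is.null(config$scores)) ens$scores <- config$scores
    note("parsed ensemble: ", length(ens$poses), " poses")
  }

  # --- triage
  if (!is.null(ens) && !is.null(config$annotation)) {
    ann <- config$annotation
    if (is.character(ann)) ann <- read_annotation(ann)
    rules <- config$rules %||% triage_rules(criteria = criteria)
    tri <- select_binding_mode(ens, ann,
                               p_groups = config$p_groups %||%
                                 list(P1 = c("CB1", "N2", "N3")),
                               rules = rules)
    f <- file.path(out_dir, "triage_verdicts.tsv")
    write_verdicts(tri, f)
    out$paths <- c(out$paths, f)
    if (!is.na(tri$selected)) {
      fp <- file.path(out_dir, "selected_pose.pdb")
      write_pdb_complexes(tri$pose, fp)
      out$paths <- c(out$paths, fp)
      note("triage: selected pose ", tri$selected)
    } else note("triage: no pose passed all rules")
    out$triage <- tri
  } else if (!is.null(ens) || !is.null(config$annotation)) {
    skip("triage", "needs both ensemble and annotation")
  }

  # --- fingerprint + consensus
  if (!is.null(ens)) {
    mats <- lapply(ens$poses, detect_interactions, criteria = criteria)
    prof <- average_fingerprint(mats)
    f <- file.path(out_dir, "fingerprint.tsv")
    profile_report(prof, f)
    cons <- consensus_residues(prof, config$consensus_cutoff %||% 0.5)
    fc <- file.path(out_dir, "consensus_residues.tsv")
    write.table(cons, fc, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- c(out$paths, f, fc)
    out$profile <- prof
    out$consensus <- cons
    note("fingerprint: ", nrow(prof$freq), " residues, ",
         nrow(cons), " consensus")
  }

  # --- ranking
  if (!is.null(config$score_tables)) {
    prefs <- list()
    for (nm in names(config$score_tables)) {
      st <- read_score_table(config$score_tables[[nm]], position = nm)
      pc <- rank_substrates(st)
      prefs[[nm]] <- pc
      f <- file.path(out_dir, paste0("ranking_", nm, ".tsv"))
      rk <- pc$ranked
      rk$score <- sprintf("%.1f", rk$score)
      write.table(rk, f, sep = "\t", quote = FALSE, row.names = FALSE)
      out$paths <- c(out$paths, f)
      note("ranking ", nm, ": best ", pc$best$ligand,
           sprintf(" (%.1f)", pc$best$score))
    }
    f <- file.path(out_dir, "preferences.tsv")
    pdf <- do.call(rbind, lapply(prefs, function(p) data.frame(
      position = p$position, best = p$best$ligand,
      best_residue = p$best$residue,
      best_score = sprintf("%.1f", p$best$score),
      worst = p$worst$ligand,
      worst_score = sprintf("%.1f", p$worst$score),
      gap_top2 = sprintf("%.1f", p$gap_top2),
      stringsAsFactors = FALSE)))
    write.table(pdf, f, sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- c(out$paths, f)
    out$preferences <- prefs
  }

  # --- MM-PBSA averaging
  if (!is.null(config$energy_series)) {
    avgs <- lapply(config$energy_series, average_binding)
    f <- file.path(out_dir, "mmpbsa.tsv")
    energy_report(avgs, f)
    out$paths <- c(out$paths, f)
    out$mmpbsa <- avgs
    for (nm in names(avgs))
      note("mmpbsa ", nm, sprintf(": dG_bind %.2f kcal/mol", avgs[[nm]]$dG_bind))
  }

  if (length(out$paths) == 0 && !strict)
    note("no stage had usable inputs; empty report")
  writeLines(log, file.path(out_dir, "run.log"))
  out$paths <- c(out$paths, file.path(out_dir, "run.log"))
  invisible(out)
}
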