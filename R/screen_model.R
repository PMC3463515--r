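# Domain model for an arrayed RNAi ciliation screen: reagent layout,
# per-experiment ciliated/total cell counts, qRT-PCR knockdown measurements,
# and cilium-length samples, all carried as validated data.frames inside a
# single S3 container built by build_screen()/read_screen().

#' Reagent classes recognized in a screen layout
#'
#' `SIRNA` duplexes and `MIRNA_MIMIC` reagents target candidate genes;
#' `SCRAMBLED_CONTROL` is the non-silencing negative control used for
#' normalization; `POSITIVE_CONTROL` reagents (e.g. targeting IFT88 or PCM1)
#' have a known ciliary effect and anchor threshold calibration.
#' @export
REAGENT_CLASSES <- c("SIRNA", "MIRNA_MIMIC", "SCRAMBLED_CONTROL", "POSITIVE_CONTROL")

#' Canonical gene categories
#'
#' Candidate genes fall into three provenance groups (interactors of a known
#' risk gene, rare-variant associations, common-variant/GWAS associations);
#' control reagents carry `CONTROL`. The column is an open label set: the
#' synthetic-screen generator records its gene classes here so downstream
#' tallies stratify by simulated class.
#' @export
GENE_CATEGORIES <- c("DISC1_INTERACTOR", "RARE_VARIANT", "COMMON_VARIANT", "CONTROL")

#' @export
QPCR_MODES <- c("CT", "PERCENT_REMAINING", "ACTIVITY")

# internal: gene keys are matched case-insensitively, display form preserved
gene_key <- function(gene) toupper(trimws(as.character(gene)))

fail_row <- function(file, row, msg) {
  stop(sprintf("%s row %s: %s", file, paste(row, collapse = ","), msg), call. = FALSE)
}

check_columns <- function(df, required, file) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing required column(s) %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

#' Assemble and validate a screen from in-memory tables
#'
#' Cross-validates the four component tables and returns a `cilia_screen`
#' object. Every malformed row raises a located error; conditions counted on
#' fewer than `min_cells` cells are recorded as QC warnings, not errors,
#' because the cell-count floor is a protocol target rather than a data
#' guarantee.
#'
#' @param layout data.frame with columns `reagent_id`, `gene`,
#'   `reagent_class`, `round` and optionally `category`. Scrambled controls
#'   must have an empty/missing `gene`.
#' @param counts data.frame with columns `experiment_id`, `reagent_id`,
#'   `ciliated_count`, `total_count`; one row per experiment x reagent.
#' @param qpcr optional data.frame with columns `reagent_id`, `mode`,
#'   `replicate`, `value` and, for `CT` mode, `reference_value` and
#'   `control_link`. `PERCENT_REMAINING` values are on the percent scale.
#' @param lengths optional data.frame with columns `reagent_id`, `length_um`.
#' @param min_cells QC floor on `total_count` (default 150).
#' @return A `cilia_screen`: list with elements `layout`, `counts`, `qpcr`,
#'   `lengths`, `genes` (one row per gene with its category), `qc`
#'   (character vector of warnings) and `min_cells`.
#' @seealso [read_screen()] for the file-based entry point.
#' @export
build_screen <- function(layout, counts, qpcr = NULL, lengths = NULL, min_cells = 150) {
  layout <- check_columns(as.data.frame(layout), c("reagent_id", "gene", "reagent_class", "round"), "layout")
  counts <- check_columns(as.data.frame(counts), c("experiment_id", "reagent_id", "ciliated_count", "total_count"), "counts")
  qc <- character(0)

  layout$reagent_id <- trimws(as.character(layout$reagent_id))
  layout$gene <- trimws(as.character(layout$gene))
  layout$gene[!nzchar(layout$gene) | is.na(layout$gene)] <- NA_character_
  layout$reagent_class <- trimws(as.character(layout$reagent_class))
  layout$round <- as.integer(layout$round)
  if (!"category" %in% names(layout)) layout$category <- NA_character_
  layout$category <- trimws(as.character(layout$category))

  dup <- duplicated(layout$reagent_id)
  if (any(dup))
    fail_row("layout", which(dup), sprintf("duplicate reagent_id '%s'", layout$reagent_id[dup][1]))
  bad <- !layout$reagent_class %in% REAGENT_CLASSES
  if (any(bad))
    fail_row("layout", which(bad)[1], sprintf("unknown reagent_class '%s'", layout$reagent_class[which(bad)[1]]))
  bad <- is.na(layout$round) | !layout$round %in% c(1L, 2L)
  if (any(bad)) fail_row("layout", which(bad)[1], "round must be 1 or 2")
  scr <- layout$reagent_class == "SCRAMBLED_CONTROL"
  if (any(scr & !is.na(layout$gene)))
    fail_row("layout", which(scr & !is.na(layout$gene))[1], "scrambled control must not carry a gene")
  if (any(!scr & is.na(layout$gene)))
    fail_row("layout", which(!scr & is.na(layout$gene))[1], "non-scrambled reagent lacks a gene")
  ctrl_class <- layout$reagent_class %in% c("SCRAMBLED_CONTROL", "POSITIVE_CONTROL")
  layout$category[ctrl_class & (is.na(layout$category) | !nzchar(layout$category))] <- "CONTROL"
  if (any(is.na(layout$category) | !nzchar(layout$category)))
    fail_row("layout", which(is.na(layout$category) | !nzchar(layout$category))[1],
             "candidate reagent lacks a gene category")

  # candidate genes need >= 2 round-1 reagents; round-2 reagents only extend
  # genes that were screened in round 1
  cand <- layout[!ctrl_class, , drop = FALSE]
  if (nrow(cand) > 0L) {
    key <- gene_key(cand$gene)
    r1 <- table(key[cand$round == 1L])
    no_r1 <- setdiff(unique(key), names(r1))
    if (length(no_r1) > 0L)
      stop(sprintf("layout: gene %s has round-2 reagents but no round-1 reagents",
                   cand$gene[match(no_r1[1], key)]), call. = FALSE)
    few <- names(r1)[r1 < 2L]
    if (length(few) > 0L)
      stop(sprintf("layout: gene %s has fewer than 2 round-1 reagents",
                   cand$gene[match(few[1], key)]), call. = FALSE)
    mixed <- tapply(cand$category, key, function(x) length(unique(x)) > 1L)
    if (any(mixed))
      stop(sprintf("layout: gene %s listed under more than one category",
                   cand$gene[match(names(mixed)[mixed][1], key)]), call. = FALSE)
  }

  counts$experiment_id <- trimws(as.character(counts$experiment_id))
  counts$reagent_id <- trimws(as.character(counts$reagent_id))
  counts$ciliated_count <- as.integer(counts$ciliated_count)
  counts$total_count <- as.integer(counts$total_count)
  bad <- is.na(counts$ciliated_count) | counts$ciliated_count < 0L
  if (any(bad)) fail_row("counts", which(bad)[1], "ciliated_count must be a non-negative integer")
  bad <- is.na(counts$total_count) | counts$total_count <= 0L
  if (any(bad)) fail_row("counts", which(bad)[1], "total_count must be a positive integer")
  bad <- counts$ciliated_count > counts$total_count
  if (any(bad)) {
    i <- which(bad)[1]
    fail_row("counts", i, sprintf("ciliated_count (%d) exceeds total_count (%d) for reagent '%s'",
                                  counts$ciliated_count[i], counts$total_count[i], counts$reagent_id[i]))
  }
  unknown <- !counts$reagent_id %in% layout$reagent_id
  if (any(unknown)) {
    i <- which(unknown)[1]
    fail_row("counts", i, sprintf("reagent_id '%s' not present in layout", counts$reagent_id[i]))
  }
  dup <- duplicated(counts[c("experiment_id", "reagent_id")])
  if (any(dup)) fail_row("counts", which(dup)[1], "duplicate experiment_id x reagent_id")
  low <- counts$total_count < min_cells
  if (any(low))
    qc <- c(qc, sprintf("QC: experiment %s reagent %s counted %d cells (< minimum %d)",
                        counts$experiment_id[low], counts$reagent_id[low],
                        counts$total_count[low], min_cells))

  if (!is.null(qpcr)) {
    qpcr <- check_columns(as.data.frame(qpcr), c("reagent_id", "mode", "replicate", "value"), "qpcr")
    qpcr$reagent_id <- trimws(as.character(qpcr$reagent_id))
    qpcr$mode <- trimws(as.character(qpcr$mode))
    qpcr$value <- as.numeric(qpcr$value)
    if (!"reference_value" %in% names(qpcr)) qpcr$reference_value <- NA_real_
    if (!"control_link" %in% names(qpcr)) qpcr$control_link <- NA_character_
    qpcr$reference_value <- as.numeric(qpcr$reference_value)
    qpcr$control_link <- trimws(as.character(qpcr$control_link))
    qpcr$control_link[!nzchar(qpcr$control_link) | is.na(qpcr$control_link)] <- NA_character_
    bad <- !qpcr$mode %in% QPCR_MODES
    if (any(bad)) fail_row("qpcr", which(bad)[1], sprintf("unknown mode '%s'", qpcr$mode[which(bad)[1]]))
    unknown <- !qpcr$reagent_id %in% layout$reagent_id
    if (any(unknown))
      fail_row("qpcr", which(unknown)[1], sprintf("reagent_id '%s' not present in layout", qpcr$reagent_id[which(unknown)[1]]))
    bad <- is.na(qpcr$value)
    if (any(bad)) fail_row("qpcr", which(bad)[1], "value is missing or non-numeric")
    bad <- qpcr$mode == "PERCENT_REMAINING" & qpcr$value < 0
    if (any(bad)) fail_row("qpcr", which(bad)[1], "PERCENT_REMAINING value must be non-negative")
    ct <- qpcr$mode == "CT"
    bad <- ct & (is.na(qpcr$reference_value) | is.na(qpcr$control_link))
    if (any(bad)) fail_row("qpcr", which(bad)[1], "CT mode requires reference_value and control_link")
    bad <- ct & !is.na(qpcr$control_link) & !qpcr$control_link %in% layout$reagent_id
    if (any(bad)) fail_row("qpcr", which(bad)[1], sprintf("control_link '%s' not present in layout",
                                                          qpcr$control_link[which(bad)[1]]))
  }

  if (!is.null(lengths)) {
    lengths <- check_columns(as.data.frame(lengths), c("reagent_id", "length_um"), "lengths")
    lengths$reagent_id <- trimws(as.character(lengths$reagent_id))
    lengths$length_um <- as.numeric(lengths$length_um)
    unknown <- !lengths$reagent_id %in% layout$reagent_id
    if (any(unknown))
      fail_row("lengths", which(unknown)[1], sprintf("reagent_id '%s' not present in layout", lengths$reagent_id[which(unknown)[1]]))
    bad <- is.na(lengths$length_um) | lengths$length_um <= 0
    if (any(bad)) fail_row("lengths", which(bad)[1], "length_um must be a positive number")
  }

  cand <- layout[!ctrl_class, , drop = FALSE]
  genes <- unique(data.frame(gene = cand$gene, category = cand$category,
                             key = gene_key(cand$gene), stringsAsFactors = FALSE))
  genes <- genes[!duplicated(genes$key), c("gene", "category")]
  rownames(genes) <- NULL

  scr <- structure(list(layout = layout, counts = counts, qpcr = qpcr,
                        lengths = lengths, genes = genes, qc = qc,
                        min_cells = min_cells),
                   class = "cilia_screen")
  if (length(qc) > 0L)
    warning(sprintf("%d QC warning(s) recorded; see screen$qc", length(qc)), call. = FALSE)
  scr
}

#' Read a screen from delimited text files
#'
#' File schemas (UTF-8, comma-delimited, with header):
#' \describe{
#'   \item{counts.csv}{`experiment_id,reagent_id,ciliated_count,total_count`}
#'   \item{layout.csv}{`reagent_id,gene,reagent_class,round,category`}
#'   \item{qpcr.csv}{`reagent_id,mode,replicate,value,reference_value,control_link`}
#'   \item{lengths.csv}{`reagent_id,length_um`}
#' }
#'
#' @param counts,layout,qpcr,lengths file paths; `qpcr` and `lengths` are
#'   optional (`NULL` to omit).
#' @inheritParams build_screen
#' @return A `cilia_screen` object, fully cross-validated.
#' @export
read_screen <- function(counts, layout, qpcr = NULL, lengths = NULL, min_cells = 150) {
  read1 <- function(path, what) {
    if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  build_screen(layout = read1(layout, "layout"),
               counts = read1(counts, "counts"),
               qpcr = if (!is.null(qpcr)) read1(qpcr, "qpcr"),
               lengths = if (!is.null(lengths)) read1(lengths, "lengths"),
               min_cells = min_cells)
}

#' Write a screen back to its four delimited text files
#'
#' Inverse of [read_screen()]; used by the simulator to materialize synthetic
#' screens. Writes `counts.csv`, `layout.csv`, and `qpcr.csv`/`lengths.csv`
#' when present.
#'
#' @param screen a `cilia_screen`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "cilia_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.csv"), layout = file.path(dir, "layout.csv"))
  utils::write.csv(screen$counts, paths[["counts"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(screen$layout, paths[["layout"]], row.names = FALSE, quote = FALSE)
  if (!is.null(screen$qpcr)) {
    paths <- c(paths, qpcr = file.path(dir, "qpcr.csv"))
    utils::write.csv(screen$qpcr, paths[["qpcr"]], row.names = FALSE, quote = FALSE)
  }
  if (!is.null(screen$lengths)) {
    paths <- c(paths, lengths = file.path(dir, "lengths.csv"))
    utils::write.csv(screen$lengths, paths[["lengths"]], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' @export
print.cilia_screen <- function(x, ...) {
  ctrl <- x$layout$reagent_class %in% c("SCRAMBLED_CONTROL", "POSITIVE_CONTROL")
  cat(sprintf("<cilia_screen> %d genes, %d reagents (%d control), %d experiments\n",
              nrow(x$genes), nrow(x$layout), sum(ctrl),
              length(unique(x$counts$experiment_id))))
  if (!is.null(x$qpcr)) cat(sprintf("  qPCR: %d rows\n", nrow(x$qpcr)))
  if (!is.null(x$lengths)) cat(sprintf("  lengths: %d cilia measured\n", nrow(x$lengths)))
  if (length(x$qc) > 0L) cat(sprintf("  QC warnings: %d\n", length(x$qc)))
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Emits a machine-readable `results.json` (thresholds, per-reagent effects,
#' knockdown table, per-gene decisions, QC log) plus human-readable
#' `summary.tsv` (one row per gene) and `tallies.tsv` (category x status
#' counts). [read_results()] reproduces the decision set exactly.
#'
#' @param calls a `screen_calls` object from [call_screen()]
#' @param dir output directory
#' @param lengths_report optional data.frame from [lengths_report()]
#' @return invisibly, the output directory
#' @export
write_results <- function(calls, dir, lengths_report = NULL) {
  stopifnot(inherits(calls, "screen_calls"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree <- list(
    thresholds = unclass(calls$thresholds),
    effects = calls$effects$summary,
    per_experiment = calls$effects$per_experiment,
    knockdown = calls$knockdown,
    duplex_calls = calls$duplex_calls,
    decisions = calls$decisions,
    tallies = calls$tallies,
    qc = as.list(calls$qc)
  )
  if (!is.null(lengths_report)) tree$lengths_report <- lengths_report
  jsonlite::write_json(tree, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null", null = "null")
  utils::write.table(calls$decisions, file.path(dir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(calls$tallies, file.path(dir, "tallies.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(lengths_report))
    utils::write.table(lengths_report, file.path(dir, "lengths_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(calls$qc, file.path(dir, "qc_log.txt"))
  invisible(dir)
}

#' Read results written by [write_results()]
#'
#' @param dir directory containing `results.json`
#' @return list with `decisions`, `tallies`, `effects`, `per_experiment`,
#'   `knockdown`, `duplex_calls`, `thresholds`, `qc`, and `lengths_report`
#'   when present; tabular elements are data.frames.
#' @export
read_results <- function(dir) {
  path <- file.path(dir, "results.json")
  if (!file.exists(path)) stop("no results.json under ", dir, call. = FALSE)
  tree <- jsonlite::read_json(path, simplifyVector = TRUE)
  tree$qc <- as.character(unlist(tree$qc))
  if (!is.data.frame(tree$decisions))  # empty decision set serializes as []
    tree$decisions <- data.frame(gene = character(0), category = character(0),
                                 status = character(0), decided_in_round = integer(0),
                                 direction = character(0), rule = character(0),
                                 rationale = character(0), stringsAsFactors = FALSE)
  tree
}
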