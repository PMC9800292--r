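#' @title Tabular input/output for the GeoMx pipeline
#' @description Readers and writers for the three tabular formats the
#'   pipeline touches: probe-level count tables, ROI annotation tables and
#'   GMT marker-gene sets. Readers validate structural integrity and reject
#'   malformed input rather than coercing it; every writer produces a file
#'   its paired reader parses back to an equal value.
#' @name io_tabular
NULL

SCHEMA_COMMENT <- "# geomxnorm schema v1"

.read_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", colClasses = NA)
}

.write_table <- function(df, path, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SCHEMA_COMMENT, con)
  utils::write.table(df, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.sep_for <- function(path, csv = NULL) {
  if (!is.null(csv)) return(if (isTRUE(csv)) "," else "\t")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Construct a probe-level count table
#'
#' The entry point of the pipeline: raw probe x ROI counts with a probe ->
#' target mapping and a probe class distinguishing target probes from
#' negative-control (spike-in) probes. Negative probes carry the reserved
#' target id `"NegProbe"`.
#'
#' @param counts numeric matrix, probes in rows (rownames = probe ids),
#'   ROIs in columns (colnames = ROI ids); non-negative, no missing cells.
#' @param target_id character vector, one target per probe.
#' @param probe_class character vector, `"target"` or `"negative"` per probe.
#' @return An object of class `probe_counts` with elements `counts`
#'   (numeric matrix) and `probes` (data.frame of probe metadata).
#' @export
probe_counts <- function(counts, target_id, probe_class) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("counts must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must have probe ids as rownames and ROI ids as colnames")
  }
  if (anyNA(counts)) stopf("counts contain missing cells")
  if (any(counts < 0)) stopf("counts must be non-negative")
  probe_id <- rownames(counts)
  if (anyDuplicated(probe_id)) {
    stopf("duplicated probe_id: %s",
          paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  }
  if (length(target_id) != nrow(counts) ||
      length(probe_class) != nrow(counts)) {
    stopf("target_id and probe_class must have one entry per probe")
  }
  bad <- !probe_class %in% c("target", "negative")
  if (any(bad)) {
    stopf("invalid probe_class for probe %s (must be 'target' or 'negative')",
          probe_id[which(bad)[1L]])
  }
  target_id <- as.character(target_id)
  target_id[probe_class == "negative"] <- NEG_TARGET_SENTINEL
  structure(
    list(counts = counts,
         probes = data.frame(probe_id = probe_id,
                             target_id = target_id,
                             probe_class = probe_class,
                             stringsAsFactors = FALSE)),
    class = "probe_counts")
}

#' @export
print.probe_counts <- function(x, ...) {
  cat(sprintf("probe_counts: %d probes (%d target, %d negative), %d targets, %d ROIs\n",
              nrow(x$counts),
              sum(x$probes$probe_class == "target"),
              sum(x$probes$probe_class == "negative"),
              length(unique(x$probes$target_id[x$probes$probe_class == "target"])),
              ncol(x$counts)))
  invisible(x)
}

#' @export
dim.probe_counts <- function(x) dim(x$counts)

#' Read a probe-level count table
#'
#' Expects a header row with the metadata columns `probe_id`, `target_id`,
#' `probe_class` followed by one column per ROI. Lines starting with `#`
#' are ignored. Parsing is strict: duplicated probe ids, non-numeric count
#' cells or a missing class column are errors that name the offending
#' row or column.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param csv logical; force comma-separated parsing. By default the
#'   extension decides (`.csv` means comma).
#' @return A [probe_counts] object; ROI column order is preserved.
#' @export
read_probe_counts <- function(path, csv = NULL) {
  sep <- .sep_for(path, csv)
  df <- .read_table(path, sep)
  meta_cols <- c("probe_id", "target_id", "probe_class")
  missing_cols <- setdiff(meta_cols, names(df))
  if (length(missing_cols) > 0L) {
    stopf("probe count file %s is missing column(s): %s",
          path, paste(missing_cols, collapse = ", "))
  }
  roi_cols <- setdiff(names(df), meta_cols)
  if (length(roi_cols) == 0L) stopf("probe count file %s has no ROI columns", path)
  if (anyDuplicated(df$probe_id)) {
    stopf("duplicated probe_id in %s: %s", path,
          paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  }
  counts <- as.matrix(df[roi_cols])
  if (!is.numeric(counts)) {
    bad_col <- roi_cols[which(!vapply(df[roi_cols], is.numeric, logical(1)))[1L]]
    bad_row <- which(is.na(suppressWarnings(as.numeric(df[[bad_col]]))))[1L]
    stopf("non-numeric count cell in %s at ROI column '%s', probe '%s'",
          path, bad_col, df$probe_id[bad_row %||% 1L])
  }
  rownames(counts) <- df$probe_id
  probe_counts(counts, df$target_id, df$probe_class)
}

#' Write a probe-level count table
#'
#' @param x a [probe_counts] object.
#' @param path output path; `.csv` extension switches to comma separation.
#' @param csv logical; force comma separation.
#' @return `path`, invisibly.
#' @export
write_probe_counts <- function(x, path, csv = NULL) {
  stopifnot(inherits(x, "probe_counts"))
  df <- cbind(x$probes, as.data.frame(x$counts, check.names = FALSE))
  .write_table(df, path, .sep_for(path, csv))
  invisible(path)
}

#' Read an ROI annotation table
#'
#' Requires an `roi_id` column with unique values; `sample_id`,
#' `patient_id` and `group` are recognized when present, and every other
#' column is preserved as a trait (numeric where possible).
#'
#' @inheritParams read_probe_counts
#' @return A data.frame of class `roi_annotations`.
#' @export
read_annotations <- function(path, csv = NULL) {
  df <- .read_table(path, .sep_for(path, csv))
  if (!"roi_id" %in% names(df)) stopf("annotation file %s is missing roi_id column", path)
  if (anyDuplicated(df$roi_id)) {
    stopf("duplicated roi_id in %s: %s", path,
          paste(unique(df$roi_id[duplicated(df$roi_id)]), collapse = ", "))
  }
  df$roi_id <- as.character(df$roi_id)
  class(df) <- c("roi_annotations", "data.frame")
  df
}

#' Write an ROI annotation table
#'
#' @param x an annotation data.frame containing at least `roi_id`.
#' @inheritParams write_probe_counts
#' @export
write_annotations <- function(x, path, csv = NULL) {
  stopifnot(is.data.frame(x), "roi_id" %in% names(x))
  .write_table(as.data.frame(x), path, .sep_for(path, csv))
  invisible(path)
}

#' Read marker gene sets in GMT format
#'
#' Standard GMT dialect: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are dropped; the total number dropped is recorded in the
#' `"n_duplicates_dropped"` attribute and reported as a warning.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors (class `marker_gene_sets`);
#'   set descriptions in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L)) {
    stopf("GMT parse error at line %d: fewer than 3 tab-separated fields",
          which(n_fields < 3L)[1L])
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  descriptions <- vapply(fields, `[[`, character(1), 2L)
  n_dup <- sum(vapply(sets, function(g) sum(duplicated(g)), integer(1)))
  if (n_dup > 0L) {
    warningf("read_gmt: dropped %d duplicated gene(s) within sets", n_dup)
    sets <- lapply(sets, unique)
  }
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            n_duplicates_dropped = n_dup, class = "marker_gene_sets")
}

#' Write marker gene sets in GMT format
#'
#' @param sets a named list of character vectors (or `marker_gene_sets`).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- attr(sets, "descriptions") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a target-level matrix (collapsed or normalized values)
#'
#' @param x numeric matrix, targets in rows, ROIs in columns; the
#'   processing stage is carried in the `"stage"` attribute.
#' @inheritParams write_probe_counts
#' @export
write_target_matrix <- function(x, path, csv = NULL) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(target_id = rownames(x), as.data.frame(x, check.names = FALSE),
                   check.names = FALSE)
  .write_table(df, path, .sep_for(path, csv))
  invisible(path)
}

#' Read a target-level matrix written by [write_target_matrix()]
#'
#' @inheritParams read_probe_counts
#' @param stage processing stage tag to attach (`"collapsed"` by default).
#' @return numeric matrix with a `"stage"` attribute.
#' @export
read_target_matrix <- function(path, csv = NULL, stage = "collapsed") {
  df <- .read_table(path, .sep_for(path, csv))
  if (!"target_id" %in% names(df)) stopf("matrix file %s is missing target_id column", path)
  m <- as.matrix(df[setdiff(names(df), "target_id")])
  if (!is.numeric(m)) stopf("non-numeric cell in matrix file %s", path)
  rownames(m) <- df$target_id
  target_matrix(m, stage)
}

# Tag a matrix with its processing stage. Collapsed-stage matrices must be
# strictly positive (geometric means of counts >= 1).
target_matrix <- function(m, stage) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (identical(stage, "collapsed") && any(m <= 0)) {
    stopf("collapsed-stage target matrix must be strictly positive")
  }
  attr(m, "stage") <- stage
  m
}

matrix_stage <- function(m) attr(m, "stage") %||% "collapsed"
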