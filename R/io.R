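#' Read a cohort table
#'
#' Reads a delimited table of per-sample delta-CT values (one column per panel
#' gene, relative to the reference gene and computed upstream) together with a
#' batch label and the integer reported day after the positive ovulation test.
#' The delimiter is taken from the file extension (`.csv` = comma, anything
#' else = tab). Validation is strict: missing panel columns, non-numeric
#' expression values, missing values, duplicated sample ids and out-of-range
#' reported days are all errors, never silently coerced.
#'
#' @param path Path to a CSV/TSV file with header; must contain columns
#'   `sample_id`, `batch`, `reported_day` and one column per configured
#'   panel gene.
#' @param config An [endotime_config()].
#' @return A `data.frame` (class `cohort_table`) with columns `sample_id`,
#'   `batch`, `reported_day`, then the panel genes in configuration order.
#' @export
read_cohort <- function(path, config = endotime_config()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  as_cohort_table(raw, config)
}

#' Validate a data frame as a cohort table
#'
#' @param df Data frame with the columns described in [read_cohort()].
#' @inheritParams read_cohort
#' @return A validated `cohort_table` with gene columns in panel order.
#' @export
as_cohort_table <- function(df, config = endotime_config()) {
  genes <- names(config$panel_genes)
  meta <- c("sample_id", "batch", "reported_day")
  missing_cols <- setdiff(c(meta, genes), names(df))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- df[, c(meta, genes)]
  out$sample_id <- as.character(out$sample_id)
  if (anyDuplicated(out$sample_id))
    stop("duplicated sample_id values: ",
         paste(unique(out$sample_id[duplicated(out$sample_id)]), collapse = ", "))
  out$batch <- as.character(out$batch)
  day <- suppressWarnings(as.numeric(out$reported_day))
  bad <- which(is.na(day) | day != round(day))
  if (length(bad))
    stop("reported_day must be an integer; offending row(s): ",
         paste(bad, collapse = ", "))
  dr <- config$day_range
  out_of_range <- which(day < dr[1] | day > dr[2])
  if (length(out_of_range))
    stop(sprintf("reported_day outside %d..%d at row(s): %s",
                 dr[1], dr[2], paste(out_of_range, collapse = ", ")))
  out$reported_day <- as.integer(day)
  for (g in genes) {
    v <- suppressWarnings(as.numeric(out[[g]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing %s value at row(s): %s",
                   g, paste(bad, collapse = ", ")))
    out[[g]] <- v
  }
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Write timing results
#'
#' Writes one row per sample with the reported day, its continuized value,
#' the final timing estimate (eLH+), the asynchrony score, the per-gene
#' maximum-likelihood times and the outlier flag. Fields that a run does not
#' produce (e.g. asynchrony for a single-gene panel) are written as empty
#' cells, never as zeros.
#'
#' @param records A `timing_records` data frame as returned by
#'   [run_endotime()] or [estimate_fixed()].
#' @param path Output path; `.csv` writes comma-separated, otherwise tabs.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  out <- as.data.frame(records)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], format_full)
  out[] <- lapply(out, function(col) ifelse(is.na(col), "", as.character(col)))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a timing results table
#'
#' @param path Path written by [write_results()].
#' @return A data frame with numeric columns restored; empty cells become `NA`.
#' @export
read_results <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "")
  for (nm in setdiff(names(df), c("sample_id", "batch")))
    df[[nm]] <- if (nm == "outlier") as.logical(df[[nm]]) else as.numeric(df[[nm]])
  df
}

#' Write and read gene profile tables
#'
#' Temporal profiles are serialized as long-form rows
#' `(gene, window, tau, mu, sigma)`, one row per window per gene, so a trained
#' model can be reused by [estimate_fixed()] without retraining. When a
#' calibration reference is attached (see [calibration_ref()]) it is stored in
#' extra `ref_mean`/`ref_sd` columns repeated along each gene's rows.
#'
#' @param profiles A `gene_profiles` object from [run_endotime()] or
#'   [build_windows()].
#' @param path Output (input) path, `.csv` or tab-delimited.
#' @return `write_profiles()`: invisibly, `path`. `read_profiles()`: a
#'   `gene_profiles` object.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "gene_profiles"))
  ref <- attr(profiles, "calibration")
  w <- attr(profiles, "w")
  rows <- do.call(rbind, lapply(names(profiles), function(g) {
    p <- profiles[[g]]
    data.frame(gene = g, window = seq_along(p$tau),
               tau = p$tau, mu = p$mu, sigma = p$sigma,
               train_w = if (is.null(w)) NA_integer_ else as.integer(w),
               ref_mean = if (is.null(ref)) NA_real_ else ref$mean[[g]],
               ref_sd = if (is.null(ref)) NA_real_ else ref$sd[[g]])
  }))
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], format_full)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(rows, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = "NA")
  profiles <- lapply(split(df, factor(df$gene, levels = unique(df$gene))),
                     function(d) {
    d <- d[order(d$window), ]
    list(tau = as.numeric(d$tau), mu = as.numeric(d$mu),
         sigma = as.numeric(d$sigma))
  })
  out <- structure(profiles, class = "gene_profiles")
  if ("train_w" %in% names(df) && !all(is.na(df$train_w)))
    attr(out, "w") <- as.integer(df$train_w[1])
  if (!all(is.na(df$ref_mean))) {
    first <- df[!duplicated(df$gene), ]
    attr(out, "calibration") <- structure(
      list(mean = stats::setNames(as.numeric(first$ref_mean), first$gene),
           sd = stats::setNames(as.numeric(first$ref_sd), first$gene)),
      class = "calibration_ref")
  }
  out
}

#' Read a TPM matrix
#'
#' Expects genes in rows keyed by a `gene` symbol column, samples in the
#' remaining columns.
#'
#' @param path CSV/TSV path.
#' @return Numeric matrix, genes x samples, with gene symbols as row names.
#' @export
read_tpm <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(df)) stop("TPM table must have a 'gene' column")
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene
  m
}

# Full-precision numeric formatting for text round-trips (empty for NA).
format_full <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = TRUE),
    character(1))
  out
}
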