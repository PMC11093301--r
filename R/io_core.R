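# Domain containers and file IO: ROI time series, phenotypes, the
# per-subject connectivity store, and the atlas label table.

SRS_SUBSCALES <- c("awareness", "cognition", "communication",
                   "motivation", "mannerisms")

#' Construct a validated ROI time-series object
#'
#' @param data numeric T x R matrix (rows = time points, columns = ROIs)
#' @param subject_id subject identifier
#' @param tr sampling interval (seconds)
#' @return an object of class `"roi_timeseries"`
#' @export
roi_timeseries <- function(data, subject_id, tr) {
  data <- as.matrix(data)
  if (!is.numeric(data)) abort_parse("time-series matrix must be numeric")
  if (anyNA(data) || any(!is.finite(data))) {
    abort_validation("subject %s: time series contains missing/non-finite values",
                     subject_id)
  }
  if (nrow(data) < 30L) {
    abort_validation("subject %s: need at least 30 time points, got %d",
                     subject_id, nrow(data))
  }
  if (ncol(data) < 2L) {
    abort_validation("subject %s: need at least 2 ROIs, got %d",
                     subject_id, ncol(data))
  }
  v <- apply(data, 2L, stats::var)
  if (any(v == 0)) {
    abort_validation("subject %s: ROI column(s) %s have zero variance",
                     subject_id, paste(which(v == 0), collapse = ", "))
  }
  stopifnot_scalar_number(tr, "tr")
  structure(list(subject_id = as.character(subject_id),
                 data = unname(data), tr = tr),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries %s: %d time points x %d ROIs, TR %gs>\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Read one subject's ROI time series from delimited text
#'
#' Expects one row per time point and one column per ROI (tab- or
#' comma-separated, no header by default). The column count must match
#' `config$n_roi`; constant columns are rejected because they make the
#' Pearson correlation (and coherence denominators) undefined.
#'
#' @param path file path
#' @param config a [pipeline_config()]
#' @param subject_id identifier; defaults to the file stem
#' @param header whether the file has a header row
#' @return a [roi_timeseries()]
#' @export
read_roi_timeseries <- function(path, config,
                                subject_id = sub("\\.[^.]+$", "", basename(path)),
                                header = FALSE) {
  if (!file.exists(path)) abort_validation("time-series file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else "\t"
  df <- tryCatch(
    utils::read.table(path, sep = sep, header = header,
                      colClasses = "character", strip.white = TRUE),
    error = function(e) abort_parse("cannot read %s: %s", path, conditionMessage(e))
  )
  m <- as.matrix(df)
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad)) {
      abort_parse("%s: non-numeric value '%s' at row %d, column %d",
                  path, m[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2])
    }
    abort_parse("%s: missing values present", path)
  }
  if (ncol(num) != config$n_roi) {
    abort_dimension("%s: expected %d ROI columns, found %d",
                    path, config$n_roi, ncol(num))
  }
  roi_timeseries(num, subject_id = subject_id, tr = config$tr)
}

#' Read a phenotype table
#'
#' The CSV must contain `subject_id`, `label` (1 = ASD, 0 = TC) and the
#' five SRS subscale columns (`awareness`, `cognition`, `communication`,
#' `motivation`, `mannerisms`, optionally prefixed `srs_`). `sex`, `age`
#' and `site` are carried through when present. Subscale scaling is not
#' assumed (raw scores and T-scores are both accepted).
#'
#' @param path CSV file path
#' @return a tibble with columns `subject_id`, `label`,
#'   `srs_awareness` ... `srs_mannerisms` and any optional metadata
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort_validation("phenotype file not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_phenotypes(df, context = path)
}

#' Validate (and canonicalise) a phenotype data frame
#'
#' @param df data frame as read from disk or built in memory
#' @param context label used in error messages
#' @return canonical phenotype tibble
#' @export
validate_phenotypes <- function(df, context = "phenotypes") {
  nm <- names(df)
  if (!all(c("subject_id", "label") %in% nm)) {
    abort_schema("%s: need subject_id and label columns", context)
  }
  srs_cols <- character(5)
  for (i in seq_along(SRS_SUBSCALES)) {
    cand <- c(paste0("srs_", SRS_SUBSCALES[i]), SRS_SUBSCALES[i])
    hit <- cand[cand %in% nm]
    if (!length(hit)) {
      abort_schema("%s: missing SRS subscale column '%s'",
                   context, SRS_SUBSCALES[i])
    }
    srs_cols[i] <- hit[1]
  }
  out <- tibble::tibble(
    subject_id = as.character(df$subject_id),
    label = as.integer(df$label)
  )
  for (i in seq_along(SRS_SUBSCALES)) {
    out[[paste0("srs_", SRS_SUBSCALES[i])]] <- as.numeric(df[[srs_cols[i]]])
  }
  for (extra in intersect(c("sex", "age", "site"), nm)) out[[extra]] <- df[[extra]]
  if (anyDuplicated(out$subject_id)) {
    abort_validation("%s: duplicate subject_id(s): %s", context,
                     paste(unique(out$subject_id[duplicated(out$subject_id)]),
                           collapse = ", "))
  }
  if (!all(out$label %in% c(0L, 1L))) {
    abort_validation("%s: labels must be 0 (TC) or 1 (ASD)", context)
  }
  srs <- as.matrix(out[paste0("srs_", SRS_SUBSCALES)])
  if (anyNA(srs) || any(!is.finite(srs))) {
    abort_validation("%s: SRS subscales must be finite", context)
  }
  out
}

srs_matrix <- function(phenotypes) {
  unname(as.matrix(phenotypes[paste0("srs_", SRS_SUBSCALES)]))
}

#' Bundle a subject's phenotype with both connectomes
#'
#' @param phenotype one-row phenotype tibble
#' @param static_fc a [static_fc()] result
#' @param dynamic_fc a [dynamic_fc()] result
#' @return an object of class `"subject_record"`
#' @export
subject_record <- function(phenotype, static_fc, dynamic_fc) {
  ids <- c(phenotype$subject_id, static_fc$subject_id, dynamic_fc$subject_id)
  if (length(unique(ids)) != 1L) {
    abort_validation("subject_record: mismatched subject ids (%s)",
                     paste(ids, collapse = " / "))
  }
  if (nrow(static_fc$matrix) != dim(dynamic_fc$tensor)[1]) {
    abort_dimension("subject_record %s: static R=%d vs dynamic R=%d",
                    ids[1], nrow(static_fc$matrix), dim(dynamic_fc$tensor)[1])
  }
  structure(list(phenotype = phenotype, static_fc = static_fc,
                 dynamic_fc = dynamic_fc),
            class = "subject_record")
}

#' Write / read the per-subject connectivity store
#'
#' Persists a list of [subject_record()]s as one self-describing file.
#' Each subject carries its static R x R matrix, dynamic R x R x Q
#' tensor, 5 SRS scores and label; the round trip is lossless to full
#' floating precision. The container is R's native serialisation
#' (version 3), readable on any platform with `read_fc_store()`.
#'
#' @param records non-empty list of [subject_record()]s with consistent shapes
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_fc_store <- function(records, path) {
  if (!length(records)) abort_validation("fc store: empty record list")
  dims <- vapply(records, function(r) dim(r$dynamic_fc$tensor), numeric(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[3, ] != dims[3, 1])) {
    abort_validation("fc store: inconsistent tensor shapes across subjects")
  }
  payload <- list(format = "fchybrid_fc_store", version = 1L,
                  records = records)
  saveRDS(payload, path, version = 3L, compress = FALSE)
  invisible(path)
}

#' @rdname write_fc_store
#' @export
read_fc_store <- function(path) {
  if (!file.exists(path)) abort_validation("fc store not found: %s", path)
  payload <- readRDS(path)
  if (!identical(payload$format, "fchybrid_fc_store")) {
    abort_parse("%s is not an fchybrid connectivity store", path)
  }
  payload$records
}

#' AAL-116 atlas labels
#'
#' Region names of the Automated Anatomical Labeling atlas in standard
#' order, used only for reporting (computation is index-based).
#'
#' @return a tibble with columns `roi` (1-based index) and `label`
#' @export
aal_labels <- function() {
  path <- system.file("extdata", "aal116_labels.tsv", package = "fchybrid")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
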