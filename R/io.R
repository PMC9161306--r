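#' Read a replicate-level measurement table
#'
#' Reads log2-scale (or raw-scale, see [log2_transform()]) measurement tables
#' in either the long or the wide dialect. The long dialect has the header
#' `molecule_id, molecule_class, genotype, condition, replicate, value`; the
#' wide dialect has `molecule_id, molecule_class, genotype` followed by one
#' column per condition-replicate slot (`DR_1` ... `NS_6`), blank cells
#' meaning missing. TSV and CSV are auto-detected from the delimiter of the
#' header line unless `delim` is given.
#'
#' @param path Path to a TSV/CSV file.
#' @param format `"auto"` (default), `"long"` or `"wide"`.
#' @param delim Field delimiter; `NULL` auto-detects tab vs comma.
#' @return A long tibble with columns `molecule_id`, `molecule_class`,
#'   `genotype`, `condition`, `replicate`, `value` and `is_outlier`
#'   (initialised to `FALSE`).
#' @export
read_measurements <- function(path, format = c("auto", "long", "wide"),
                              delim = NULL) {
  format <- match.arg(format)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  # columns are read as character and converted with base R's strtod so
  # that full-precision decimal output round-trips bit-exactly
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  long_cols <- c("molecule_id", "molecule_class", "genotype",
                 "condition", "replicate", "value")
  if (format == "auto") {
    format <- if (all(long_cols %in% names(raw))) "long" else "wide"
  }
  if (format == "long") {
    missing_cols <- setdiff(long_cols, names(raw))
    if (length(missing_cols) > 0L) {
      stop("long measurement table lacks columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    out <- dplyr::select(raw, dplyr::all_of(long_cols))
  } else {
    id_cols <- c("molecule_id", "molecule_class", "genotype")
    slot_cols <- grep("^(DR|DS|NR|NS)_[0-9]+$", names(raw), value = TRUE)
    if (length(slot_cols) == 0L) {
      stop("wide measurement table has no condition-replicate columns ",
           "(expected e.g. DR_1 ... NS_6)", call. = FALSE)
    }
    out <- tidyr::pivot_longer(raw, dplyr::all_of(slot_cols),
                               names_to = c("condition", "replicate"),
                               names_sep = "_", values_to = "value")
    out$replicate <- as.integer(out$replicate)
    out <- dplyr::filter(out, !is.na(.data$value) & .data$value != "")
    out <- dplyr::select(out, dplyr::all_of(c(id_cols, "condition",
                                              "replicate", "value")))
  }
  out$condition <- as.character(out$condition)
  bad <- setdiff(unique(out$condition), condition_levels())
  if (length(bad) > 0L) {
    stop("unknown condition labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out$replicate <- as.integer(out$replicate)
  out$value <- as.numeric(out$value)
  out$is_outlier <- FALSE
  tibble::as_tibble(out)
}

#' Read a molecule-to-bin annotation table
#'
#' Functional-category ("bin") annotations in the Mapman dotted-code style,
#' e.g. `34.19` = transport.aquaporins. A molecule may map to several bins
#' (one row per mapping).
#'
#' @param path TSV/CSV with header `molecule_id, bin_code, bin_name`.
#' @param delim Field delimiter; `NULL` auto-detects tab vs comma.
#' @return Tibble with character columns `molecule_id`, `bin_code`,
#'   `bin_name`.
#' @export
read_annotation <- function(path, delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  ann <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  need <- c("molecule_id", "bin_code")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols) > 0L) {
    stop("annotation table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"bin_name" %in% names(ann)) ann$bin_name <- NA_character_
  tibble::as_tibble(ann[, c("molecule_id", "bin_code", "bin_name")])
}

#' Write a table as TSV
#'
#' Full double precision, `.` decimal separator, RFC-4180-compatible quoting.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) {
      v <- x[[j]]
      x[[j]] <- ifelse(is.finite(v), sprintf("%.17g", v), as.character(v))
    }
  }
  readr::write_tsv(x, path, progress = FALSE, na = "NA")
  invisible(path)
}
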