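#' Read and write the pipeline's tab-delimited formats
#'
#' Long-format intensity tables carry one row per probe/sample/channel with
#' header `probe_id, gene_id, is_negative_control, sample_id, group,
#' channel, median_signal`. Ct tables carry `sample_id, group, assay_id,
#' ct`, where `ct` may be the literal token `Undetermined` (parsed to `NA`
#' plus an `undetermined` flag). Prediction tables carry
#' `source, mirna_id, gene_id`.
#'
#' @param path file path.
#' @return a tibble in the corresponding in-memory format.
#' @name thyromir_io
NULL

#' @rdname thyromir_io
#' @export
read_intensity_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(tbl, c("probe_id", "gene_id", "is_negative_control",
                       "sample_id", "group", "channel", "median_signal"),
                "intensity file")
  tbl |>
    mutate(is_negative_control = as.logical(.data$is_negative_control),
           median_signal = as.numeric(.data$median_signal))
}

#' Read a Feature-Extraction-style wide intensity layout
#'
#' One row per probe with columns `probe_id`, `gene_id`,
#' `is_negative_control` followed by paired per-sample signal columns named
#' `<sample_id>.Cy5` (sample channel) and `<sample_id>.Cy3` (reference
#' channel).
#'
#' @param path file path.
#' @param groups sample-to-condition map: a tibble with columns
#'   `sample_id`, `group`, or a named character vector.
#' @return a long-format intensity tibble as read by
#'   [read_intensity_table()].
#' @export
read_intensity_wide <- function(path, groups) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(wide, c("probe_id", "gene_id", "is_negative_control"),
                "wide intensity file")
  if (!is.data.frame(groups)) {
    groups <- tibble(sample_id = names(groups),
                     group = unname(groups))
  }
  check_columns(groups, c("sample_id", "group"), "`groups`")
  signal_cols <- setdiff(names(wide),
                         c("probe_id", "gene_id", "is_negative_control"))
  bad <- signal_cols[!grepl("\\.(Cy5|Cy3)$", signal_cols)]
  if (length(bad) > 0L) {
    abort(sprintf("Unrecognised signal column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  long <- wide |>
    mutate(is_negative_control = as.logical(.data$is_negative_control)) |>
    tidyr::pivot_longer(dplyr::all_of(signal_cols),
                        names_to = c("sample_id", "dye"), names_sep = "\\.",
                        values_to = "median_signal") |>
    mutate(channel = ifelse(.data$dye == "Cy5", "sample", "reference")) |>
    select(-"dye")
  missing <- setdiff(unique(long$sample_id), groups$sample_id)
  if (length(missing) > 0L) {
    abort(sprintf("No group assignment for sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  long |>
    left_join(groups, by = "sample_id") |>
    select("probe_id", "gene_id", "is_negative_control", "sample_id",
           "group", "channel", "median_signal")
}

#' @rdname thyromir_io
#' @param tbl table to write.
#' @export
write_intensity_table <- function(tbl, path) {
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname thyromir_io
#' @export
read_ct_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    ct = readr::col_character(), .default = readr::col_guess()
  ))
  check_columns(tbl, c("sample_id", "group", "assay_id", "ct"), "Ct file")
  tbl |>
    mutate(
      undetermined = .data$ct %in% c("Undetermined", "undetermined"),
      ct = suppressWarnings(
        ifelse(.data$undetermined, NA_real_, as.numeric(.data$ct)))
    )
}

#' @rdname thyromir_io
#' @export
write_ct_matrix <- function(tbl, path) {
  check_columns(tbl, c("sample_id", "group", "assay_id", "ct"), "Ct table")
  out <- tbl
  undet <- if ("undetermined" %in% names(out)) {
    out$undetermined | is.na(out$ct)
  } else {
    is.na(out$ct)
  }
  out$ct <- ifelse(undet, "Undetermined", format(out$ct, trim = TRUE))
  readr::write_tsv(out[, c("sample_id", "group", "assay_id", "ct")], path)
  invisible(path)
}

#' @rdname thyromir_io
#' @export
read_predictions <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(tbl, c("source", "mirna_id", "gene_id"), "prediction file")
  tbl |> distinct(.data$source, .data$mirna_id, .data$gene_id)
}

#' @rdname thyromir_io
#' @export
write_truth_table <- function(tbl, path) {
  check_columns(tbl, c("feature_id", "true_log2_effect", "is_de"),
                "truth table")
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Write a differential-expression result with a metadata sidecar
#'
#' Writes the result rows as a tab-delimited file and, alongside it, a
#' `<path>.meta.json` sidecar recording the run parameters (seed, span,
#' trim, statistic choice, permutation/bootstrap budget, thresholds), so a
#' result file is always interpretable on its own.
#'
#' @param x an `array_de` or `tlda_de` object.
#' @param path output TSV path.
#' @param sidecar write the JSON metadata sidecar. Default TRUE.
#' @return `path`, invisibly.
#' @export
write_de_result <- function(x, path, sidecar = TRUE) {
  stopifnot(inherits(x, "array_de") || inherits(x, "tlda_de"))
  readr::write_tsv(x$results, path)
  if (sidecar) {
    jsonlite::write_json(x$meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}
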