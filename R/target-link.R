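#' Union of target predictions across sources and family members
#'
#' Applies the "predicted by either source" rule: for each miRNA family
#' (a named set of member miRNAs, e.g. the miR-1/206 cluster pooled), the
#' target set is the deduplicated union across all prediction sources and
#' all family members. Gene identity is by symbol string, case-sensitive
#' after whitespace trimming.
#'
#' @param predictions tibble `source`, `mirna_id`, `gene_id` (duplicated
#'   rows are collapsed on load).
#' @param families named list: family label -> character vector of member
#'   miRNA ids.
#' @return tibble `family`, `gene_id`, one row per family/gene. A family
#'   member absent from every source triggers a warning (and contributes an
#'   empty set).
#' @examples
#' preds <- tibble::tibble(
#'   source = c("A", "A", "B", "B"),
#'   mirna_id = c("miR-1", "miR-206", "miR-1", "miR-206"),
#'   gene_id = c("g1", "g2", "g2", "g3"))
#' union_predictions(preds, list("miR-1/206" = c("miR-1", "miR-206")))
#' @export
union_predictions <- function(predictions, families) {
  check_columns(predictions, c("source", "mirna_id", "gene_id"),
                "prediction table")
  if (is.null(names(families)) || any(!nzchar(names(families)))) {
    abort("`families` must be a named list of member id vectors.")
  }
  preds <- predictions |>
    mutate(gene_id = trimws(.data$gene_id),
           mirna_id = trimws(.data$mirna_id)) |>
    distinct(.data$source, .data$mirna_id, .data$gene_id)
  absent <- setdiff(unique(unlist(families)), unique(preds$mirna_id))
  if (length(absent) > 0L) {
    warn(sprintf("miRNA(s) absent from every prediction source: %s",
                 paste(absent, collapse = ", ")))
  }
  purrr::imap(families, function(members, fam) {
    preds |>
      filter(.data$mirna_id %in% members) |>
      distinct(.data$gene_id) |>
      mutate(family = fam)
  }) |>
    purrr::list_rbind() |>
    select("family", "gene_id")
}

#' Filter a differential-expression table to significant genes
#'
#' Keeps rows with `|fc_signed| > fc_min` and p below `p_max` (both strict
#' inequalities). By default the adjusted p-value column is used where
#' available.
#'
#' @param de DE result tibble with `fc_signed` and a p-value column.
#' @param fc_min fold-change threshold (absolute, on the signed-fold-change
#'   scale where |fc| >= 1). Default 1.5.
#' @param p_max p-value threshold. Default 0.05.
#' @param p_col which p column to compare: `"p_adj"` (default) or
#'   `"p_raw"`; any column name present in `de` is accepted.
#' @return the filtered tibble (possibly empty).
#' @export
filter_de_genes <- function(de, fc_min = 1.5, p_max = 0.05,
                            p_col = "p_adj") {
  check_columns(de, "fc_signed", "DE table")
  if (!p_col %in% names(de)) {
    fallback <- intersect(c("p_adj", "p_raw", "p"), names(de))
    if (length(fallback) == 0L) {
      abort("DE table has no usable p-value column.")
    }
    p_col <- fallback[1L]
  }
  de |>
    filter(abs(.data$fc_signed) > fc_min, .data[[p_col]] < p_max)
}

#' Overlap of predicted targets with significant genes, with direction
#' concordance
#'
#' Intersects each family's predicted target set with the significant DE
#' gene set, classifies each overlapping gene as up- or down-regulated from
#' the sign of its fold change, and tallies concordance: a target is
#' concordant when its direction is *opposite* to its miRNA family's
#' direction (miRNAs suppress their targets). Genes targeted by more than
#' one family are reported under each, with a duplication note.
#'
#' @param targets tibble `family`, `gene_id` from [union_predictions()].
#' @param sig significant DE tibble with `gene_id` and `fc_signed` (e.g.
#'   from [filter_de_genes()]).
#' @param mirna_direction named character vector: family -> `"up"` or
#'   `"down"`, the observed direction of the miRNA family itself.
#' @return object of class `overlap_report`: list with `rows` (tibble
#'   `family`, `gene_id`, `fc_signed`, `direction`, `concordant`,
#'   `shared_across_families`) and `summary` (per-family and overall
#'   `n_total`, `n_down`, `n_up`, `n_concordant`, `concordance`).
#'   Supports [tidy()], [glance()], [autoplot()].
#' @export
overlap_and_concordance <- function(targets, sig, mirna_direction) {
  check_columns(targets, c("family", "gene_id"), "target table")
  check_columns(sig, c("gene_id", "fc_signed"), "significant DE table")
  fams <- unique(targets$family)
  missing_dir <- setdiff(fams, names(mirna_direction))
  if (length(missing_dir) > 0L) {
    abort(sprintf("No miRNA direction supplied for family(ies): %s",
                  paste(missing_dir, collapse = ", ")))
  }
  if (!all(mirna_direction %in% c("up", "down"))) {
    abort("`mirna_direction` values must be 'up' or 'down'.")
  }
  sig_clean <- sig |>
    mutate(gene_id = trimws(.data$gene_id)) |>
    distinct(.data$gene_id, .keep_all = TRUE)
  rows <- targets |>
    inner_join(sig_clean |> select("gene_id", "fc_signed"),
               by = "gene_id") |>
    mutate(
      direction = ifelse(.data$fc_signed >= 0, "up", "down"),
      mirna_dir = unname(mirna_direction[.data$family]),
      concordant = .data$direction != .data$mirna_dir
    ) |>
    group_by(.data$gene_id) |>
    mutate(shared_across_families = dplyr::n() > 1L) |>
    ungroup() |>
    select("family", "gene_id", "fc_signed", "direction", "concordant",
           "shared_across_families")
  per_family <- rows |>
    group_by(.data$family) |>
    summarise(
      n_total = dplyr::n(),
      n_down = sum(.data$direction == "down"),
      n_up = sum(.data$direction == "up"),
      n_concordant = sum(.data$concordant),
      .groups = "drop"
    )
  overall <- rows |>
    summarise(
      family = "overall",
      n_total = dplyr::n(),
      n_down = sum(.data$direction == "down"),
      n_up = sum(.data$direction == "up"),
      n_concordant = sum(.data$concordant)
    )
  summary_tbl <- bind_rows(per_family, overall) |>
    mutate(concordance = ifelse(.data$n_total > 0,
                                .data$n_concordant / .data$n_total,
                                NA_real_))
  structure(
    list(rows = rows, summary = summary_tbl,
         mirna_direction = mirna_direction),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  ov <- x$summary[x$summary$family == "overall", ]
  cat("miRNA target / DE-gene overlap report\n")
  cat(sprintf(
    "  %d overlapping targets: %d down, %d up; %d/%d concordant (%.1f%%)\n",
    ov$n_total, ov$n_down, ov$n_up, ov$n_concordant, ov$n_total,
    100 * ov$concordance
  ))
  for (i in seq_len(nrow(x$summary))) {
    r <- x$summary[i, ]
    if (r$family == "overall") next
    cat(sprintf("  %s: %d targets (%d down / %d up), miRNA %s\n",
                r$family, r$n_total, r$n_down, r$n_up,
                x$mirna_direction[[r$family]]))
  }
  invisible(x)
}
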