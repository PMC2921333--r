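#' Tidiers for fitted pipeline objects
#'
#' `tidy()` returns the per-feature (or per-term) result table of a fitted
#' object as a tibble; `glance()` returns a one-row summary.
#'
#' @param x a fitted object (`array_de`, `tlda_de`, `standard_curve`,
#'   `overlap_report`, `rq_table`).
#' @param ... unused.
#' @return a tibble.
#' @name thyromir_tidiers
NULL

#' @rdname thyromir_tidiers
#' @method tidy array_de
#' @export
tidy.array_de <- function(x, ...) x$results

#' @rdname thyromir_tidiers
#' @method glance array_de
#' @export
glance.array_de <- function(x, ...) {
  tibble(
    n_tested = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_skipped = nrow(x$skipped),
    statistic = x$meta$statistic,
    permutation = x$meta$permutation,
    n_shuffles = x$meta$n_shuffles,
    span = x$meta$span,
    alpha = x$meta$alpha,
    seed = x$meta$seed
  )
}

#' @rdname thyromir_tidiers
#' @method tidy tlda_de
#' @export
tidy.tlda_de <- function(x, ...) x$results

#' @rdname thyromir_tidiers
#' @method glance tlda_de
#' @export
glance.tlda_de <- function(x, ...) {
  tibble(
    n_tested = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_untestable = nrow(x$untestable),
    B = x$meta$B,
    alpha = x$meta$alpha,
    undetermined = x$meta$undetermined,
    seed = x$meta$seed
  )
}

#' @rdname thyromir_tidiers
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @rdname thyromir_tidiers
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
         efficiency = x$efficiency, valid = x$valid, n = x$n)
}

#' @rdname thyromir_tidiers
#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) x$rows

#' @rdname thyromir_tidiers
#' @method glance overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  x$summary |>
    filter(.data$family == "overall") |>
    select(-"family")
}
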