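#' Delta-delta-Ct relative quantification against a calibrator sample
#'
#' Classical ddCt quantification for a single target assay: duplicate-well
#' Ct values are averaged per sample and assay, then
#' `dCt = Ct(target) - Ct(housekeeping)` per sample,
#' `ddCt = dCt(sample) - dCt(calibrator)`, and the relative quantity is
#' `RQ = 2^(-ddCt)`. The calibrator sample has RQ = 1 by construction.
#'
#' @param ct Ct tibble: `sample_id`, `group`, `assay_id`, `ct` (repeated
#'   rows per sample/assay are treated as duplicate wells and averaged),
#'   optional `undetermined` logical.
#' @param target target assay id.
#' @param housekeeping housekeeping assay id (U6 / Hprt role).
#' @param calibrator sample id used as the reference; must have determined
#'   Ct for both assays.
#' @param undetermined `"omit"` (drop samples with undetermined target Ct)
#'   or `"ceiling"` (substitute `max_ct`).
#' @param max_ct ceiling substitute. Default 40.
#' @return tibble of class `rq_table`: `sample_id`, `group`, `dct`, `ddct`,
#'   `rq`, with `target`, `housekeeping` and `calibrator` attached as
#'   attributes.
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("c1", "t1"), each = 2),
#'   group = rep(c("control", "hypo"), each = 2),
#'   assay_id = rep(c("mir1", "U6"), 2),
#'   ct = c(24, 20, 22, 20))
#' ddct_quantify(ct, "mir1", "U6", calibrator = "c1")
#' @export
ddct_quantify <- function(ct, target, housekeeping, calibrator,
                          undetermined = c("omit", "ceiling"), max_ct = 40) {
  undetermined <- match.arg(undetermined)
  check_columns(ct, c("sample_id", "group", "assay_id", "ct"), "Ct table")
  work <- ct |> filter(.data$assay_id %in% c(target, housekeeping))
  if (!target %in% work$assay_id) {
    abort(sprintf("Target assay '%s' not found.", target))
  }
  if (!housekeeping %in% work$assay_id) {
    abort(sprintf("Housekeeping assay '%s' not found.", housekeeping))
  }
  if (!"undetermined" %in% names(work)) work$undetermined <- is.na(work$ct)
  if (undetermined == "ceiling") {
    work <- work |>
      mutate(ct = ifelse(.data$undetermined & .data$assay_id == target,
                         max_ct, .data$ct),
             undetermined = .data$undetermined & .data$assay_id != target)
  }
  # duplicate wells: average the threshold cycles per sample and assay
  averaged <- work |>
    filter(!.data$undetermined, !is.na(.data$ct)) |>
    group_by(.data$sample_id, .data$group, .data$assay_id) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  wide <- averaged |>
    tidyr::pivot_wider(names_from = "assay_id", values_from = "ct") |>
    rename(ct_target = dplyr::all_of(target),
           ct_hk = dplyr::all_of(housekeeping))
  if (!calibrator %in% wide$sample_id) {
    abort(sprintf("Calibrator sample '%s' not found.", calibrator))
  }
  cal <- wide |> filter(.data$sample_id == calibrator)
  if (is.na(cal$ct_target) || is.na(cal$ct_hk)) {
    abort(sprintf(
      "Calibrator sample '%s' lacks a determined Ct for the target or housekeeping assay.",
      calibrator
    ))
  }
  out <- wide |>
    filter(!is.na(.data$ct_target), !is.na(.data$ct_hk)) |>
    mutate(
      dct = .data$ct_target - .data$ct_hk,
      ddct = .data$dct - (cal$ct_target - cal$ct_hk),
      rq = 2^(-.data$ddct)
    ) |>
    select("sample_id", "group", "dct", "ddct", "rq")
  attr(out, "target") <- target
  attr(out, "housekeeping") <- housekeeping
  attr(out, "calibrator") <- calibrator
  class(out) <- c("rq_table", class(out))
  out
}

#' Per-group summary of relative quantities
#'
#' @param rq an `rq_table` from [ddct_quantify()] (or any tibble with
#'   `group` and `rq` columns).
#' @return tibble `group`, `n`, `mean_rq`, `se_rq`.
#' @export
rq_group_summary <- function(rq) {
  check_columns(rq, c("group", "rq"), "RQ table")
  rq |>
    as_tibble() |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(), mean_rq = mean(.data$rq),
              se_rq = sd(.data$rq) / sqrt(dplyr::n()), .groups = "drop")
}

#' Two-group comparison of expression values
#'
#' Two-tailed Student's t-test between two condition groups. By default the
#' comparison is made on log2(RQ) — fold-change data are approximately
#' log-normal, and on the log scale the result is invariant to the choice
#' of calibrator — with the raw scale available via `scale = "raw"`.
#' Pooled-variance (classical Student) by default; Welch via
#' `var_equal = FALSE`.
#'
#' Degenerate inputs (zero variance in both groups) return p = 1 when the
#' group means are equal, and p = 0 with a warning when they differ.
#'
#' @param data tibble containing a grouping column `group` and the value
#'   column named by `value`.
#' @param group_a,group_b the two condition labels to compare.
#' @param value column to compare (unquoted). Default `rq`.
#' @param scale `"log2"` (default; applied to the value column) or `"raw"`.
#' @param var_equal pooled variance (TRUE, default) or Welch.
#' @return one-row tibble `t`, `df`, `p`, `mean_a`, `mean_b`, `scale`.
#' @examples
#' d <- tibble::tibble(group = rep(c("a", "b"), each = 3),
#'                     y = c(1, 2, 3, 4, 5, 6))
#' group_compare(d, "a", "b", value = y, scale = "raw")
#' @export
group_compare <- function(data, group_a, group_b, value = .data$rq,
                          scale = c("log2", "raw"), var_equal = TRUE) {
  scale <- match.arg(scale)
  check_columns(data, "group", "data")
  v <- dplyr::pull(dplyr::mutate(data, .val = {{ value }}), ".val")
  g <- data$group
  xa <- v[g == group_a]
  xb <- v[g == group_b]
  if (length(xa) < 2L || length(xb) < 2L) {
    abort("Need at least 2 values per group.")
  }
  if (scale == "log2") {
    if (any(c(xa, xb) <= 0)) {
      abort("log2 scale requires strictly positive values; use scale = 'raw'.")
    }
    xa <- log2(xa)
    xb <- log2(xb)
  }
  if (sd(xa) == 0 && sd(xb) == 0) {
    if (isTRUE(all.equal(mean(xa), mean(xb)))) {
      return(tibble(t = 0, df = length(xa) + length(xb) - 2L, p = 1,
                    mean_a = mean(xa), mean_b = mean(xb), scale = scale))
    }
    warn("Zero within-group variance with unequal means; p reported as 0.")
    return(tibble(t = sign(mean(xa) - mean(xb)) * Inf,
                  df = length(xa) + length(xb) - 2L, p = 0,
                  mean_a = mean(xa), mean_b = mean(xb), scale = scale))
  }
  tt <- t.test(xa, xb, var.equal = var_equal)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_a = mean(xa), mean_b = mean(xb),
         scale = scale)
}

#' Standard-curve fit and PCR amplification efficiency
#'
#' Ordinary least-squares fit of Ct against log10 template dilution:
#' `Ct = intercept + slope * log10(dilution)`. The amplification efficiency
#' is `E = 10^(-1/slope) - 1` (0 = no amplification, 1 = perfect doubling;
#' the textbook slope of -3.3219 cycles per decade gives E = 1). Curves
#' with non-negative slope are flagged invalid and no efficiency is
#' reported.
#'
#' @param data tibble with columns `log10_dilution` and `ct` (at least 3
#'   distinct dilution points).
#' @return object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r2`, `efficiency` (`NA` when invalid), `valid`, `n`, and
#'   the underlying `lm` fit. Supports [tidy()], [glance()], [autoplot()].
#' @examples
#' d <- tibble::tibble(log10_dilution = c(0, -1, -2, -3),
#'                     ct = 20 - 3.3219 * c(0, -1, -2, -3))
#' standard_curve(d)
#' @export
standard_curve <- function(data) {
  check_columns(data, c("log10_dilution", "ct"), "standard-curve data")
  d <- data |> filter(is.finite(.data$log10_dilution), is.finite(.data$ct))
  if (nrow(d) < 3L || length(unique(d$log10_dilution)) < 3L) {
    abort("Need at least 3 distinct dilution points.")
  }
  fit <- lm(ct ~ log10_dilution, data = d)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  valid <- slope < 0
  if (!valid) {
    warn("Standard curve has non-negative slope; flagged invalid, efficiency omitted.")
  }
  structure(
    list(slope = slope, intercept = intercept, r2 = r2,
         efficiency = if (valid) 10^(-1 / slope) - 1 else NA_real_,
         valid = valid, n = nrow(d), fit = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve\n")
  cat(sprintf("  slope %.4f Ct/log10(dilution), intercept %.2f, r2 %.4f\n",
              x$slope, x$intercept, x$r2))
  if (x$valid) {
    cat(sprintf("  amplification efficiency %.1f%%\n", 100 * x$efficiency))
  } else {
    cat("  INVALID (non-negative slope); efficiency omitted\n")
  }
  invisible(x)
}
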