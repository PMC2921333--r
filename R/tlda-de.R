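#' Delta-Ct normalization against a housekeeping assay
#'
#' Subtracts each sample's housekeeping Ct from every assay's Ct:
#' `dCt = Ct(assay, sample) - Ct(housekeeping, sample)`. Because Ct is a
#' log2-scale quantity, dCt is the log2 expression of the assay relative to
#' the housekeeping gene (up to sign). Any per-sample loading offset cancels
#' exactly. Undetermined Ct values are handled per `undetermined` policy:
#' `"omit"` drops the observation, `"ceiling"` substitutes `max_ct`.
#'
#' @param ct Ct tibble: columns `sample_id`, `group`, `assay_id`, `ct`
#'   (numeric, `NA` = undetermined) and optionally `undetermined` (logical).
#' @param housekeeping id of the housekeeping assay (U6 / Hprt role); must
#'   be determined in every sample.
#' @param undetermined `"omit"` (default) or `"ceiling"`.
#' @param max_ct substitute used by the `"ceiling"` policy. Default 40.
#' @return tibble `sample_id`, `group`, `assay_id`, `dct`; the housekeeping
#'   assay's own rows have `dct = 0`.
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("s1", "s2"), each = 2),
#'   group = rep(c("control", "hypo"), each = 2),
#'   assay_id = rep(c("m1", "U6"), 2),
#'   ct = c(25, 20, 23, 20))
#' delta_ct(ct, housekeeping = "U6")
#' @export
delta_ct <- function(ct, housekeeping, undetermined = c("omit", "ceiling"),
                     max_ct = 40) {
  undetermined <- match.arg(undetermined)
  check_columns(ct, c("sample_id", "group", "assay_id", "ct"), "Ct table")
  if (!housekeeping %in% ct$assay_id) {
    abort(sprintf("Housekeeping assay '%s' is absent from the Ct table.",
                  housekeeping))
  }
  work <- ct
  if (!"undetermined" %in% names(work)) {
    work$undetermined <- is.na(work$ct)
  }
  hk <- work |> filter(.data$assay_id == housekeeping)
  bad_hk <- hk$sample_id[hk$undetermined | is.na(hk$ct)]
  if (length(bad_hk) > 0L) {
    abort(sprintf(
      "Housekeeping assay '%s' is undetermined in sample(s): %s",
      housekeeping, paste(unique(bad_hk), collapse = ", ")
    ))
  }
  missing_hk <- setdiff(unique(work$sample_id), hk$sample_id)
  if (length(missing_hk) > 0L) {
    abort(sprintf("Housekeeping assay missing entirely in sample(s): %s",
                  paste(missing_hk, collapse = ", ")))
  }
  if (undetermined == "ceiling") {
    work <- work |>
      mutate(ct = ifelse(.data$undetermined, max_ct, .data$ct))
  } else {
    work <- work |> filter(!.data$undetermined)
  }
  hk_ref <- hk |> select("sample_id", hk_ct = "ct")
  work |>
    inner_join(hk_ref, by = "sample_id") |>
    mutate(dct = .data$ct - .data$hk_ct) |>
    select("sample_id", "group", "assay_id", "dct")
}

#' Per-assay one-way ANOVA on delta-Ct values
#'
#' Classical one-way ANOVA F per assay on dCt across condition groups, with
#' the per-observation residuals returned grouped by condition so the
#' bootstrap stage can resample within each group. Assays with fewer than 2
#' determined values in any group are reported untestable rather than
#' raising an error.
#'
#' @param dct tibble from [delta_ct()].
#' @return tibble `assay_id`, `F`, `df1`, `df2`, `testable`, `reason`, and
#'   list-columns `residuals_by_group` (named list of per-group residual
#'   vectors) and `n_by_group`.
#' @export
anova_f <- function(dct) {
  check_columns(dct, c("sample_id", "group", "assay_id", "dct"),
                "delta-Ct table")
  groups <- sort(unique(dct$group))
  if (length(groups) < 2L) abort("Need at least 2 groups.")
  per_assay <- split(dct[, c("group", "dct")], dct$assay_id)
  rows <- purrr::imap(per_assay, function(d, aid) {
    d <- d[is.finite(d$dct), ]
    sizes <- table(factor(d$group, levels = groups))
    if (any(sizes < 2L)) {
      return(tibble(
        assay_id = aid, F = NA_real_, df1 = NA_integer_,
        df2 = NA_integer_, testable = FALSE,
        reason = "fewer than 2 determined values in a group",
        residuals_by_group = list(NULL),
        n_by_group = list(as.list(as.integer(sizes)) |>
                            setNames(names(sizes)))
      ))
    }
    k <- length(groups)
    gm <- tapply(d$dct, d$group, mean)
    nj <- tapply(d$dct, d$group, length)
    grand <- mean(d$dct)
    ssb <- sum(nj * (gm[names(nj)] - grand)^2)
    resid <- d$dct - gm[d$group]
    ssw <- sum(resid^2)
    df1 <- k - 1L
    df2 <- nrow(d) - k
    f <- if (ssw > 0) (ssb / df1) / (ssw / df2) else if (ssb > 0) Inf else 0
    tibble(
      assay_id = aid, F = f, df1 = df1, df2 = df2, testable = TRUE,
      reason = NA_character_,
      residuals_by_group = list(split(resid, d$group)),
      n_by_group = list(as.list(as.integer(nj)) |> setNames(names(nj)))
    )
  })
  purrr::list_rbind(rows)
}

#' Bootstrap p-value for the one-way ANOVA F
#'
#' Builds the null distribution of the F statistic by resampling model
#' residuals with replacement *within each condition* — so no common-variance
#' assumption is made — forming null pseudo-data around a common mean, and
#' recomputing F. The p-value uses the add-one convention
#' `p = (1 + #(F* >= F_obs)) / (B + 1)`, which keeps p on the grid
#' `k / (B + 1)` and strictly positive.
#'
#' @param F_obs observed F statistic.
#' @param residuals_by_group named list of per-group residual vectors (each
#'   of length >= 2), as returned by [anova_f()].
#' @param B number of bootstrap iterations (>= 99).
#' @param seed integer seed; required.
#' @return scalar p-value in (0, 1].
#' @export
bootstrap_pvalue <- function(F_obs, residuals_by_group, B = 1000, seed) {
  seed <- check_seed(seed)
  if (B < 99) abort("`B` must be >= 99.")
  if (is.null(residuals_by_group) || length(residuals_by_group) < 2L) {
    abort("Need residual pools for at least 2 groups.")
  }
  sizes <- lengths(residuals_by_group)
  if (any(sizes == 0L)) abort("Empty residual pool.")
  if (any(sizes < 2L)) abort("Each group needs at least 2 residuals.")
  set.seed(seed)
  k <- length(residuals_by_group)
  n <- sum(sizes)
  # resample within groups; F is location-invariant so the common null mean
  # can be dropped from the pseudo-data
  draws <- lapply(residuals_by_group, function(r) {
    matrix(sample(r, length(r) * B, replace = TRUE), nrow = length(r))
  })
  gmeans <- vapply(draws, colMeans, numeric(B))          # B x k
  gsum <- vapply(draws, colSums, numeric(B))
  grand <- rowSums(gsum) / n
  ssb <- as.vector((gmeans - grand)^2 %*% sizes)
  ssw <- numeric(B)
  for (j in seq_len(k)) {
    ssw <- ssw + colSums((draws[[j]] - rep(gmeans[, j],
                                           each = sizes[j]))^2)
  }
  fstar <- ifelse(ssw > 0, (ssb / (k - 1)) / (ssw / (n - k)),
                  ifelse(ssb > 0, Inf, 0))
  (1 + sum(fstar >= F_obs)) / (B + 1)
}

#' Delta-delta-Ct fold changes between two conditions
#'
#' `ddCt = mean dCt(treated) - mean dCt(control)`; the relative quantity is
#' `RQ = 2^(-ddCt)` (a 2-cycle *decrease* in Ct means 4-fold *more*
#' template), reported as a signed fold change: `RQ` when `RQ >= 1`,
#' `-1/RQ` otherwise.
#'
#' @param dct tibble from [delta_ct()].
#' @param treated,control condition labels, passed explicitly.
#' @return tibble `assay_id`, `ddct`, `fc_signed`, `testable`; assays
#'   missing in either group are flagged untestable.
#' @export
fold_change_ddct <- function(dct, treated, control) {
  check_columns(dct, c("group", "assay_id", "dct"), "delta-Ct table")
  missing <- setdiff(c(treated, control), unique(dct$group))
  if (length(missing) > 0L) {
    abort(sprintf("Unknown group label(s): %s",
                  paste(missing, collapse = ", ")))
  }
  dct |>
    filter(.data$group %in% c(treated, control),
           is.finite(.data$dct)) |>
    group_by(.data$assay_id) |>
    summarise(
      m_treated = mean(.data$dct[.data$group == treated]),
      m_control = mean(.data$dct[.data$group == control]),
      .groups = "drop"
    ) |>
    mutate(
      ddct = .data$m_treated - .data$m_control,
      fc_signed = signed_fc_from_log2(-.data$ddct),
      testable = is.finite(.data$ddct)
    ) |>
    select("assay_id", "ddct", "fc_signed", "testable")
}

#' TLDA miRNA differential-expression pipeline
#'
#' Runs the low-density-array stage: delta-Ct against the housekeeping
#' assay, per-assay one-way ANOVA F, bootstrap p-values from
#' within-condition residual resampling, Benjamini-Hochberg FDR adjustment,
#' and delta-delta-Ct fold changes. The housekeeping assay is excluded from
#' testing. The default significance threshold is adjusted p < 0.1.
#'
#' @param ct Ct tibble (see [delta_ct()]).
#' @param housekeeping housekeeping assay id.
#' @param treated,control condition labels, passed explicitly.
#' @param B bootstrap iterations per assay. Default 1000.
#' @param alpha FDR threshold for the `significant` column. Default 0.1.
#' @param undetermined `"omit"` or `"ceiling"` (see [delta_ct()]).
#' @param max_ct ceiling substitute. Default 40.
#' @param seed integer seed; per-assay bootstrap seeds are derived from it.
#' @return an object of class `tlda_de`: list with `results` (tibble
#'   `assay_id`, `F`, `p_boot`, `p_adj`, `fc_signed`, `ddct`,
#'   `n_used_<group>`, `significant`, sorted by `p_adj`), `untestable`
#'   (tibble with reasons) and `meta`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' sim <- simulate_ct_experiment(ct_sim_config(
#'   n_assays = 6, effects = c(mir_001 = 8), seed = 3))
#' fit <- run_tlda_pipeline(sim$ct, housekeeping = "U6",
#'                          treated = "hypo", control = "control",
#'                          B = 199, seed = 3)
#' tidy(fit)
#' @export
run_tlda_pipeline <- function(ct, housekeeping, treated, control, B = 1000,
                              alpha = 0.1,
                              undetermined = c("omit", "ceiling"),
                              max_ct = 40, seed) {
  undetermined <- match.arg(undetermined)
  seed <- check_seed(seed)
  dct <- delta_ct(ct, housekeeping = housekeeping,
                  undetermined = undetermined, max_ct = max_ct) |>
    filter(.data$assay_id != housekeeping)
  av <- anova_f(dct)
  fc <- fold_change_ddct(dct, treated = treated, control = control)

  testable <- av |> filter(.data$testable)
  p_boot <- purrr::map2_dbl(
    testable$F, seq_len(nrow(testable)),
    function(f, i) {
      bootstrap_pvalue(
        f, testable$residuals_by_group[[i]], B = B,
        seed = (seed + i) %% .Machine$integer.max
      )
    }
  )

  n_used <- testable |>
    select("assay_id", "n_by_group") |>
    tidyr::unnest_wider("n_by_group", names_sep = "_") |>
    rename_with_prefix("n_by_group_", "n_used_")

  results <- testable |>
    select("assay_id", "F") |>
    mutate(p_boot = p_boot, p_adj = bh_adjust(p_boot)) |>
    left_join(fc, by = "assay_id") |>
    left_join(n_used, by = "assay_id") |>
    mutate(significant = .data$p_adj < alpha) |>
    select("assay_id", "F", "p_boot", "p_adj", "ddct", "fc_signed",
           dplyr::starts_with("n_used_"), "significant") |>
    arrange(.data$p_adj, .data$p_boot, .data$assay_id)

  structure(
    list(
      results = results,
      untestable = av |>
        filter(!.data$testable) |>
        select("assay_id", "reason"),
      meta = list(housekeeping = housekeeping, treated = treated,
                  control = control, B = B, alpha = alpha,
                  undetermined = undetermined, max_ct = max_ct,
                  seed = seed)
    ),
    class = "tlda_de"
  )
}

rename_with_prefix <- function(df, old, new) {
  names(df) <- sub(paste0("^", old), new, names(df))
  df
}

#' @export
print.tlda_de <- function(x, ...) {
  cat("TLDA miRNA differential expression (bootstrap ANOVA)\n")
  cat(sprintf("  %d assays tested, B = %d, undetermined policy '%s'\n",
              nrow(x$results), x$meta$B, x$meta$undetermined))
  cat(sprintf("  %d significant at FDR %.3g; %d untestable\n",
              sum(x$results$significant), x$meta$alpha,
              nrow(x$untestable)))
  invisible(x)
}
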