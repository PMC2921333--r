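#' Flag probes indistinguishable from background
#'
#' Negative-control probes carry no target sequence, so their signals define
#' the background distribution of each array. Per sample and channel the
#' flagging threshold is
#' `trimmed_mean(negative-control signals) + k * trimmed_sd(negative-control signals)`,
#' and a probe is flagged absent wherever its median signal is strictly less
#' than that threshold. Trimming removes `floor(trim * n)` observations from
#' each tail before both the mean and the standard deviation.
#'
#' @param tbl intensity table: columns `probe_id`, `is_negative_control`,
#'   `sample_id`, `channel`, `median_signal` (long format, one row per
#'   probe/sample/channel).
#' @param trim symmetric trimming fraction in \[0, 0.5). Default 0.05.
#' @param k multiplier on the trimmed standard deviation. Default 3.
#' @return tibble with columns `probe_id`, `sample_id`, `channel`, `absent`;
#'   the per-(sample, channel) thresholds are attached as attribute
#'   `"thresholds"` (tibble `sample_id`, `channel`, `threshold`). Inputs are
#'   not mutated.
#' @examples
#' tbl <- tibble::tibble(
#'   probe_id = c("n1", "n2", "n3", "p1", "p2"),
#'   is_negative_control = c(TRUE, TRUE, TRUE, FALSE, FALSE),
#'   sample_id = "s1", channel = "sample",
#'   median_signal = c(100, 100, 100, 99, 100)
#' )
#' flag_absent_probes(tbl)  # p1 absent (99 < 100), p2 present
#' @export
flag_absent_probes <- function(tbl, trim = 0.05, k = 3) {
  check_columns(tbl, c("probe_id", "is_negative_control", "sample_id",
                       "channel", "median_signal"), "intensity table")
  if (trim < 0 || trim >= 0.5) abort("`trim` must lie in [0, 0.5).")
  if (!any(tbl$is_negative_control)) {
    abort("No negative-control probes present; background cannot be estimated.")
  }
  thresholds <- tbl |>
    filter(.data$is_negative_control) |>
    group_by(.data$sample_id, .data$channel) |>
    summarise(
      threshold = {
        st <- trimmed_stats(.data$median_signal, trim = trim)
        st$mean + k * st$sd
      },
      .groups = "drop"
    )
  missing_thr <- tbl |>
    distinct(.data$sample_id, .data$channel) |>
    anti_join(thresholds, by = c("sample_id", "channel"))
  if (nrow(missing_thr) > 0L) {
    abort("Some sample/channel combinations have no negative-control observations.")
  }
  flags <- tbl |>
    left_join(thresholds, by = c("sample_id", "channel")) |>
    mutate(absent = .data$median_signal < .data$threshold) |>
    select("probe_id", "sample_id", "channel", "absent")
  attr(flags, "thresholds") <- thresholds
  flags
}

#' MA transform of a two-channel intensity table
#'
#' Converts paired sample/reference signals into the log-ratio and mean
#' log-intensity coordinates used for normalization:
#' `M = log2(sample) - log2(reference)` and
#' `A = (log2(sample) + log2(reference)) / 2`.
#' Zero or negative signals yield no M/A value and force the absent flag.
#'
#' @param tbl intensity table as in [flag_absent_probes()], with columns
#'   `probe_id`, `gene_id`, `is_negative_control`, `sample_id`, `group`,
#'   `channel` (values `"sample"` and `"reference"`), `median_signal`.
#' @param flags optional per-(probe, sample, channel) flag tibble from
#'   [flag_absent_probes()]; a probe/sample is marked absent if either
#'   channel is flagged.
#' @return MA tibble: `probe_id`, `gene_id`, `is_negative_control`,
#'   `sample_id`, `group`, `M`, `A`, `absent`.
#' @export
ma_transform <- function(tbl, flags = NULL) {
  check_columns(tbl, c("probe_id", "gene_id", "is_negative_control",
                       "sample_id", "group", "channel", "median_signal"),
                "intensity table")
  bad_ch <- setdiff(unique(tbl$channel), c("sample", "reference"))
  if (length(bad_ch) > 0L) {
    abort(sprintf("Unknown channel label(s): %s",
                  paste(bad_ch, collapse = ", ")))
  }
  wide <- tbl |>
    tidyr::pivot_wider(
      id_cols = c("probe_id", "gene_id", "is_negative_control",
                  "sample_id", "group"),
      names_from = "channel", values_from = "median_signal"
    )
  incomplete <- wide |>
    filter(is.na(.data$sample) | is.na(.data$reference))
  if (nrow(incomplete) > 0L) {
    first <- incomplete[1L, ]
    abort(sprintf(
      "Probe %s in sample %s is missing a channel observation.",
      first$probe_id, first$sample_id
    ))
  }
  out <- wide |>
    mutate(
      nonpositive = .data$sample <= 0 | .data$reference <= 0,
      M = ifelse(.data$nonpositive, NA_real_,
                 log2(.data$sample) - log2(.data$reference)),
      A = ifelse(.data$nonpositive, NA_real_,
                 (log2(.data$sample) + log2(.data$reference)) / 2)
    )
  if (!is.null(flags)) {
    flag_wide <- flags |>
      group_by(.data$probe_id, .data$sample_id) |>
      summarise(flagged = any(.data$absent), .groups = "drop")
    out <- out |>
      left_join(flag_wide, by = c("probe_id", "sample_id")) |>
      mutate(flagged = dplyr::coalesce(.data$flagged, FALSE))
  } else {
    out$flagged <- FALSE
  }
  out |>
    mutate(absent = .data$nonpositive | .data$flagged) |>
    select("probe_id", "gene_id", "is_negative_control", "sample_id",
           "group", "M", "A", "absent")
}

#' Global lowess normalization of M on A
#'
#' Removes intensity-dependent dye bias per array by fitting a locally
#' weighted regression (locally linear, tricube weights, 3 robustness
#' iterations) of M on A over the array's non-absent probes and subtracting
#' the fitted trend: `M' = M - g_hat(A)`. A values and absent flags are
#' unchanged. Probes outside the fitted A range use the nearest fitted
#' value.
#'
#' @param ma MA tibble from [ma_transform()].
#' @param span lowess span (fraction of probes in each local fit) in
#'   (0, 1]. Default 0.2.
#' @param min_probes minimum number of non-absent probes required per array.
#' @return MA tibble of the same shape with `M` replaced by the normalized
#'   values; the per-array fit metadata (span, iterations) is attached as
#'   attribute `"normalization"`.
#' @export
lowess_normalize <- function(ma, span = 0.2, min_probes = 10L) {
  check_columns(ma, c("probe_id", "sample_id", "M", "A", "absent"),
                "MA table")
  if (!(span > 0 && span <= 1)) abort("`span` must lie in (0, 1].")
  iter <- 3L
  out <- ma |>
    group_by(.data$sample_id) |>
    mutate(M = {
      usable <- !.data$absent & is.finite(.data$M) & is.finite(.data$A)
      if (sum(usable) < min_probes) {
        abort(sprintf(
          "Array %s has only %d non-absent probes (need >= %d) for lowess.",
          .data$sample_id[1L], sum(usable), min_probes
        ))
      }
      fit <- lowess(.data$A[usable], .data$M[usable], f = span, iter = iter)
      ghat <- approx(fit$x, fit$y, xout = .data$A, rule = 2, ties = mean)$y
      .data$M - ghat
    }) |>
    ungroup()
  attr(out, "normalization") <- list(method = "global lowess", span = span,
                                     iterations = iter)
  out
}

# --- internal one-way ANOVA machinery (vectorised over features) ---------

# X: features x samples matrix (may contain NA); g: factor of group labels.
# Returns between-group mean square, residual variance, dfs and usability.
anova_core <- function(X, g) {
  g <- droplevels(as.factor(g))
  k <- nlevels(g)
  Ig <- outer(g, levels(g), `==`) * 1
  obs <- !is.na(X)
  Xz <- X
  Xz[!obs] <- 0
  ngj <- obs %*% Ig
  mgj <- (Xz %*% Ig) / ngj
  Ng <- rowSums(obs)
  grand <- rowSums(Xz) / Ng
  dev <- mgj - grand
  dev[ngj == 0] <- 0
  ssb <- rowSums(ngj * dev^2)
  m2 <- mgj^2
  m2[ngj == 0] <- 0
  ssw <- pmax(rowSums(Xz^2 * obs) - rowSums(ngj * m2), 0)
  testable <- rowSums(ngj >= 2) == k
  df1 <- k - 1
  df2 <- Ng - k
  s2 <- ifelse(df2 > 0, ssw / df2, NA_real_)
  list(msb = ssb / df1, s2 = s2, df1 = df1, df2 = df2,
       testable = testable, n_by_group = ngj, group_means = mgj,
       levels = levels(g))
}

# James-Stein shrinkage of per-feature residual variances on the log scale.
# log s2 is bias-corrected (E[log chi2_df/df] = digamma(df/2) - log(df/2)),
# shrunk toward the across-feature mean with factor
# max(0, 1 - (G - 3) * mean(trigamma(df/2)) / sum((x - xbar)^2)),
# then exponentiated.
shrink_variances <- function(s2, df2) {
  ok <- is.finite(s2) & s2 > 0 & df2 > 0
  G <- sum(ok)
  if (G < 4L) return(list(s2 = s2, factor = 1))
  x <- log(s2[ok]) - (digamma(df2[ok] / 2) - log(df2[ok] / 2))
  v <- trigamma(df2[ok] / 2)
  xbar <- mean(x)
  ss <- sum((x - xbar)^2)
  b <- if (ss > 0) max(0, 1 - (G - 3) * mean(v) / ss) else 0
  out <- s2
  out[ok] <- exp(xbar + b * (x - xbar))
  list(s2 = out, factor = b)
}

f_from_parts <- function(msb, s2) {
  ifelse(is.na(s2), NA_real_,
         ifelse(s2 > 0, msb / s2, ifelse(msb > 0, Inf, 0)))
}

# matrix-level statistic used by the permutation machinery
stat_matrix <- function(X, g, shrink = TRUE) {
  a <- anova_core(X, g)
  s2 <- if (shrink) shrink_variances(a$s2, a$df2)$s2 else a$s2
  f <- f_from_parts(a$msb, s2)
  f[!a$testable] <- NA_real_
  f
}

de_matrix <- function(df, feature_col = "probe_id", value_col = "M",
                      absent_col = "absent") {
  vals <- df
  if (absent_col %in% names(vals)) {
    vals[[value_col]][vals[[absent_col]]] <- NA_real_
  }
  wide <- vals |>
    select(dplyr::all_of(c(feature_col, "sample_id", value_col))) |>
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = dplyr::all_of(value_col))
  X <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(X) <- wide[[feature_col]]
  grp <- vals |>
    distinct(.data$sample_id, .data$group)
  g <- setNames(grp$group, grp$sample_id)[colnames(X)]
  list(X = X, g = g)
}

#' Shrinkage-variance F statistic for small-sample array designs
#'
#' One-way ANOVA F statistic per feature in which the per-feature residual
#' variance is replaced by a James-Stein shrinkage estimate: log residual
#' variances are bias-corrected, shrunk toward their across-feature mean
#' (the shrinkage factor vanishes when features genuinely share one
#' variance, and approaches 1 when their variances are truly heterogeneous),
#' and exponentiated. With `shrink = FALSE` the classical per-feature
#' one-way ANOVA F is returned.
#'
#' Features with fewer than 2 available values in any group are reported as
#' untestable (`NA` statistic); absent entries count as unavailable.
#'
#' @param ma tibble with columns `probe_id` (or `feature_id`), `sample_id`,
#'   `group`, `M` and optionally `absent`.
#' @param shrink logical: use the shrinkage residual variance (default) or
#'   the classical F.
#' @return tibble `feature_id`, `statistic`, `df1`, `df2`, `resid_var`,
#'   `shrunk_var`, `testable`; the shrinkage factor is attached as
#'   attribute `"shrinkage_factor"`.
#' @export
fs_statistic <- function(ma, shrink = TRUE) {
  feature_col <- if ("probe_id" %in% names(ma)) "probe_id" else "feature_id"
  check_columns(ma, c(feature_col, "sample_id", "group", "M"), "MA table")
  dm <- de_matrix(ma, feature_col = feature_col)
  sizes <- table(dm$g)
  if (length(sizes) < 2L) abort("Need at least 2 groups.")
  if (any(sizes < 2L)) {
    abort(sprintf("Group(s) with fewer than 2 samples: %s",
                  paste(names(sizes)[sizes < 2L], collapse = ", ")))
  }
  a <- anova_core(dm$X, dm$g)
  if (all(!is.finite(a$s2) | a$s2 == 0)) {
    abort("Zero residual variance for every feature; use the exhaustive permutation grid instead of an F reference.")
  }
  sh <- if (shrink) shrink_variances(a$s2, a$df2) else list(s2 = a$s2,
                                                           factor = NA_real_)
  f <- f_from_parts(a$msb, sh$s2)
  f[!a$testable] <- NA_real_
  out <- tibble(
    feature_id = rownames(dm$X),
    statistic = unname(f),
    df1 = a$df1, df2 = unname(a$df2),
    resid_var = unname(a$s2), shrunk_var = unname(sh$s2),
    testable = unname(a$testable)
  )
  attr(out, "shrinkage_factor") <- sh$factor
  out
}

# all distinct assignments of n samples to labelled groups of given sizes
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    combs <- combn(avail, sizes[1L], simplify = FALSE)
    out <- list()
    for (cc in combs) {
      rest <- rec(setdiff(avail, cc), sizes[-1L])
      out <- c(out, lapply(rest, function(r) c(list(cc), r)))
    }
    out
  }
  lapply(rec(seq_len(n), sizes), function(asg) {
    g <- integer(n)
    for (j in seq_along(asg)) g[asg[[j]]] <- j
    g
  })
}

n_assignments <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

count_ge <- function(obs, pool_sorted) {
  length(pool_sorted) - findInterval(obs, pool_sorted, left.open = TRUE)
}

#' Permutation p-values by residual shuffling
#'
#' Builds a null distribution for a per-feature ANOVA-type statistic by
#' shuffling null-model residuals across all samples — which, for a
#' location-invariant statistic, is the same as re-assigning samples to
#' groups — with the same shuffle applied jointly to every feature so that
#' between-feature correlation is preserved. When the number of distinct
#' group assignments is at most `n_perm`, the full grid is enumerated and
#' p-values are exact counts `#(stat* >= stat_obs) / n_assignments`
#' (the identity assignment guarantees p > 0); otherwise `n_perm` random
#' shuffles are drawn and the add-one convention
#' `p = (1 + #(stat* >= stat_obs)) / (n_perm + 1)` keeps p in (0, 1].
#'
#' With `pool = TRUE` the null statistics of all testable features are
#' pooled into one reference distribution, giving p-value resolution
#' `1 / (n_shuffles * n_features)` — the conventional choice for designs
#' whose per-feature grid is too coarse for FDR control.
#'
#' @param ma tibble as in [fs_statistic()].
#' @param statistic `"fs"` (shrinkage F), `"f"` (classical F), or a
#'   function `(X, g) -> numeric` over a features-by-samples matrix.
#' @param n_perm number of random shuffles (and the enumeration ceiling).
#' @param seed integer seed; required when sampling is used.
#' @param pool pool null statistics across features (default FALSE).
#' @param independent shuffle each feature independently instead of jointly
#'   (default FALSE; joint shuffling preserves between-feature correlation).
#' @return tibble `feature_id`, `statistic`, `p_raw`; attributes `"method"`
#'   (`"enumeration"` or `"sampling"`) and `"n_shuffles"`.
#' @export
permutation_pvalues <- function(ma, statistic = c("fs", "f"), n_perm = 1000,
                                seed, pool = FALSE, independent = FALSE) {
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  feature_col <- if ("probe_id" %in% names(ma)) "probe_id" else "feature_id"
  dm <- de_matrix(ma, feature_col = feature_col)
  stat_fn <- if (is.function(statistic)) {
    statistic
  } else {
    statistic <- match.arg(statistic)
    function(X, g) stat_matrix(X, g, shrink = statistic == "fs")
  }
  g <- droplevels(as.factor(dm$g))
  sizes <- as.integer(table(g))
  n <- length(g)
  obs <- stat_fn(dm$X, g)
  testable <- !is.na(obs)

  n_exact <- n_assignments(sizes)
  enumerate <- n_exact <= n_perm
  if (!enumerate) seed <- check_seed(seed)

  shuffles <- if (enumerate) {
    # sizes follow levels(g), so group index j in an assignment maps to
    # levels(g)[j]; the observed labelling is one of the enumerated ones
    lev <- levels(g)
    lapply(enumerate_assignments(sizes), function(a) lev[a])
  } else {
    set.seed(seed)
    lapply(seq_len(n_perm), function(i) as.character(g)[sample(n)])
  }
  B <- length(shuffles)

  cnt <- numeric(length(obs))
  pooled_cnt <- numeric(length(obs))
  n_pool <- 0
  valid_b <- numeric(length(obs))
  for (b in seq_along(shuffles)) {
    fb <- tryCatch(
      if (independent && !enumerate) {
        Xb <- dm$X
        for (r in seq_len(nrow(Xb))) Xb[r, ] <- Xb[r, sample(n)]
        stat_fn(Xb, as.character(g))
      } else {
        stat_fn(dm$X, shuffles[[b]])
      },
      error = function(e) abort(sprintf(
        "Statistic failed on shuffle %d: %s", b, conditionMessage(e)))
    )
    ok <- !is.na(fb)
    cnt <- cnt + ifelse(testable & ok, fb >= obs, 0)
    valid_b <- valid_b + ifelse(testable & ok, 1, 0)
    if (pool) {
      pool_vals <- sort(fb[ok & testable])
      pooled_cnt[testable] <- pooled_cnt[testable] +
        count_ge(obs[testable], pool_vals)
      n_pool <- n_pool + length(pool_vals)
    }
  }

  p <- rep(NA_real_, length(obs))
  if (pool) {
    p[testable] <- if (enumerate) {
      pooled_cnt[testable] / n_pool
    } else {
      (1 + pooled_cnt[testable]) / (n_pool + 1)
    }
  } else {
    p[testable] <- if (enumerate) {
      cnt[testable] / valid_b[testable]
    } else {
      (1 + cnt[testable]) / (valid_b[testable] + 1)
    }
  }
  out <- tibble(feature_id = rownames(dm$X), statistic = unname(obs),
                p_raw = unname(p))
  attr(out, "method") <- if (enumerate) "enumeration" else "sampling"
  attr(out, "n_shuffles") <- B
  out
}

#' Least-square-mean fold changes
#'
#' Computes per-feature least-square means of the normalized log ratios per
#' group (for a one-way design, the group means over available values) and
#' converts the treated-minus-control difference `d` into a signed fold
#' change: `2^d` for `d >= 0`, `-2^(-d)` otherwise, so `|fc| >= 1` always
#' and `fc = 1` means no change.
#'
#' @param ma tibble as in [fs_statistic()].
#' @param treated,control condition labels; both must occur in the data.
#' @return tibble `feature_id`, `lsmean_<control>`, `lsmean_<treated>`,
#'   `delta_log2`, `fc_signed`.
#' @export
fold_change_lsmeans <- function(ma, treated, control) {
  feature_col <- if ("probe_id" %in% names(ma)) "probe_id" else "feature_id"
  check_columns(ma, c(feature_col, "sample_id", "group", "M"), "MA table")
  groups <- unique(ma$group)
  missing <- setdiff(c(treated, control), groups)
  if (length(missing) > 0L) {
    abort(sprintf("Unknown group label(s): %s",
                  paste(missing, collapse = ", ")))
  }
  vals <- ma
  if ("absent" %in% names(vals)) vals$M[vals$absent] <- NA_real_
  means <- vals |>
    filter(.data$group %in% c(treated, control)) |>
    group_by(feature_id = .data[[feature_col]], .data$group) |>
    summarise(lsmean = mean(.data$M, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "lsmean",
                       names_prefix = "lsmean_")
  d <- means[[paste0("lsmean_", treated)]] -
    means[[paste0("lsmean_", control)]]
  means |>
    mutate(delta_log2 = d, fc_signed = signed_fc_from_log2(d)) |>
    select("feature_id", dplyr::all_of(paste0("lsmean_", control)),
           dplyr::all_of(paste0("lsmean_", treated)),
           "delta_log2", "fc_signed")
}

#' Two-channel microarray differential-expression pipeline
#'
#' Runs the full array stage: background flagging from negative controls,
#' MA transform, per-array global lowess normalization, shrinkage-variance
#' (or classical) F statistics, permutation p-values by joint residual
#' shuffling, Benjamini-Hochberg FDR adjustment, and least-square-mean fold
#' changes. Negative-control probes and probes absent in every sample are
#' excluded from inference and reported in the skipped-features log.
#'
#' @param tbl intensity table (see [ma_transform()] for required columns).
#' @param treated,control condition labels (passed explicitly; no guessing).
#' @param span lowess span. Default 0.2.
#' @param trim,k flagging parameters, see [flag_absent_probes()].
#' @param stat `"fs"` (default) or `"f"`.
#' @param n_perm permutation budget; the assignment grid is enumerated when
#'   it fits within `n_perm`.
#' @param alpha FDR level used for the `significant` column. Default 0.05.
#' @param pool pool permutation nulls across features (default TRUE; see
#'   [permutation_pvalues()]).
#' @param seed integer seed; required.
#' @return an object of class `array_de`: list with `results` (tibble
#'   `feature_id`, `gene_id`, `statistic`, `p_raw`, `p_adj`, `fc_signed`,
#'   `lsmean_*`, `significant`, sorted by `p_adj`), `skipped` (tibble
#'   `feature_id`, `reason`), `ma` (normalized MA tibble) and `meta`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' sim <- simulate_two_channel_arrays(array_sim_config(
#'   n_per_group = 4, n_probes = 60, n_negctrl = 8,
#'   effects = c(p0001 = 2), seed = 7))
#' fit <- run_array_pipeline(sim$intensities, treated = "hypo",
#'                           control = "control", seed = 7)
#' head(tidy(fit))
#' @export
run_array_pipeline <- function(tbl, treated, control, span = 0.2,
                               trim = 0.05, k = 3, stat = c("fs", "f"),
                               n_perm = 1000, alpha = 0.05, pool = TRUE,
                               seed) {
  stat <- match.arg(stat)
  seed <- check_seed(seed)
  flags <- flag_absent_probes(tbl, trim = trim, k = k)
  ma <- ma_transform(tbl, flags = flags)
  ma_norm <- lowess_normalize(ma, span = span)

  candidates <- ma_norm |> filter(!.data$is_negative_control)
  presence <- candidates |>
    group_by(.data$probe_id) |>
    summarise(n_present = sum(!.data$absent & is.finite(.data$M)),
              .groups = "drop")
  all_absent <- presence$probe_id[presence$n_present == 0L]
  eligible <- candidates |> filter(!(.data$probe_id %in% all_absent))

  stats_tbl <- fs_statistic(eligible, shrink = stat == "fs")
  perm <- permutation_pvalues(eligible, statistic = stat, n_perm = n_perm,
                              seed = seed, pool = pool)
  fc <- fold_change_lsmeans(eligible, treated = treated, control = control)

  untestable <- stats_tbl$feature_id[!stats_tbl$testable]
  skipped <- bind_rows(
    tibble(feature_id = all_absent, reason = "absent in all samples"),
    tibble(feature_id = untestable,
           reason = "fewer than 2 present values in a group")
  )

  gene_map <- candidates |> distinct(.data$probe_id, .data$gene_id)
  results <- perm |>
    filter(!is.na(.data$p_raw)) |>
    left_join(gene_map, by = c(feature_id = "probe_id")) |>
    left_join(fc, by = "feature_id") |>
    mutate(p_adj = bh_adjust(.data$p_raw),
           significant = .data$p_adj < alpha) |>
    select("feature_id", "gene_id", "statistic", "p_raw", "p_adj",
           "fc_signed", dplyr::starts_with("lsmean_"), "delta_log2",
           "significant") |>
    arrange(.data$p_adj, .data$p_raw, .data$feature_id)

  structure(
    list(
      results = results, skipped = skipped, ma = ma_norm,
      meta = list(
        treated = treated, control = control, span = span, trim = trim,
        k = k, statistic = stat, n_perm = n_perm, alpha = alpha,
        pool = pool, seed = seed,
        permutation = attr(perm, "method"),
        n_shuffles = attr(perm, "n_shuffles"),
        normalization = attr(ma_norm, "normalization")
      )
    ),
    class = "array_de"
  )
}

#' @export
print.array_de <- function(x, ...) {
  cat("Two-channel array differential expression\n")
  cat(sprintf("  %d features tested (%s statistic, %s with %d shuffles%s)\n",
              nrow(x$results), x$meta$statistic, x$meta$permutation,
              x$meta$n_shuffles,
              if (x$meta$pool) ", pooled null" else ""))
  cat(sprintf("  %d significant at FDR %.3g; %d features skipped\n",
              sum(x$results$significant), x$meta$alpha, nrow(x$skipped)))
  invisible(x)
}
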