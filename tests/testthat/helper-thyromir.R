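# shared helpers: tiny fixture builders and independent oracles

# long-format intensity table from per-channel signal matrices
# (rows = probes, cols = samples); controls appended with their own signals
make_intensity <- function(sample_mat, reference_mat, groups,
                           negctrl_sample = NULL, negctrl_reference = NULL) {
  probe_ids <- rownames(sample_mat)
  sample_ids <- colnames(sample_mat)
  stopifnot(!is.null(probe_ids), !is.null(sample_ids),
            identical(dim(sample_mat), dim(reference_mat)))
  long_one <- function(mat, channel, ids, is_ctrl) {
    tibble::tibble(
      probe_id = rep(ids, times = ncol(mat)),
      gene_id = if (is_ctrl) NA_character_ else sub("^p", "g", rep(ids, times = ncol(mat))),
      is_negative_control = is_ctrl,
      sample_id = rep(colnames(mat), each = nrow(mat)),
      group = rep(groups[colnames(mat)], each = nrow(mat)),
      channel = channel,
      median_signal = as.vector(mat)
    )
  }
  out <- dplyr::bind_rows(
    long_one(sample_mat, "sample", probe_ids, FALSE),
    long_one(reference_mat, "reference", probe_ids, FALSE)
  )
  if (!is.null(negctrl_sample)) {
    out <- dplyr::bind_rows(
      out,
      long_one(negctrl_sample, "sample", rownames(negctrl_sample), TRUE),
      long_one(negctrl_reference, "reference",
               rownames(negctrl_reference), TRUE)
    )
  }
  out
}

# MA tibble straight from a value matrix (already "normalized" M values)
make_ma <- function(M, groups, A = NULL) {
  if (is.null(A)) A <- matrix(10, nrow(M), ncol(M), dimnames = dimnames(M))
  tibble::tibble(
    probe_id = rep(rownames(M), times = ncol(M)),
    sample_id = rep(colnames(M), each = nrow(M)),
    group = rep(groups[colnames(M)], each = nrow(M)),
    M = as.vector(M),
    A = as.vector(A),
    absent = is.na(as.vector(M))
  )
}

# brute-force Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# classical one-way ANOVA F through stats::aov (independent route)
aov_f <- function(vals, g) {
  ok <- !is.na(vals)
  s <- summary(stats::aov(vals[ok] ~ factor(g[ok])))[[1]]
  s$`F value`[1L]
}

# exhaustive relabeling p-value for one feature, two groups
perm_oracle_2g <- function(vals, g) {
  g <- as.factor(g)
  n <- length(vals)
  n1 <- sum(g == levels(g)[1L])
  fobs <- aov_f(vals, g)
  combs <- utils::combn(n, n1)
  stats_null <- apply(combs, 2L, function(idx) {
    gg <- rep(levels(g)[2L], n)
    gg[idx] <- levels(g)[1L]
    aov_f(vals, gg)
  })
  # aov's QR route differs from closed-form arithmetic in the last bits, so
  # count ties up to relative round-off
  mean(stats_null >= fobs - 1e-8 * max(1, abs(fobs)))
}

# Ct table for two groups from a named list assay -> per-sample ct vector
make_ct <- function(cts, groups) {
  samples <- names(groups)
  purrr::imap(cts, function(v, a) {
    tibble::tibble(sample_id = samples, group = unname(groups),
                   assay_id = a, ct = v)
  }) |>
    purrr::list_rbind()
}
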