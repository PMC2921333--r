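#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment of a vector of p-values: sort
#' ascending, take the running minimum of `p * m / rank` from the largest
#' rank down, and return the adjusted values in the original order.
#' Rejecting features with adjusted p below a level `alpha` is equivalent to
#' the classical Benjamini-Hochberg step-up rule at FDR `alpha`.
#'
#' @param p numeric vector of raw p-values, each in (0, 1]. An empty vector
#'   is returned unchanged.
#' @return numeric vector of adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.005, 0.1, 0.9))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || anyNA(p) || any(p <= 0 | p > 1)) {
    abort("`p` must be numeric with all values in (0, 1] and no missing values.")
  }
  p.adjust(p, method = "BH")
}

# trimmed mean and sd with symmetric trimming of floor(trim * n) per side
trimmed_stats <- function(x, trim = 0.05) {
  if (trim < 0 || trim >= 0.5) abort("`trim` must lie in [0, 0.5).")
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) abort("No values to trim.")
  drop <- floor(trim * n)
  kept <- if (drop > 0L) x[(drop + 1L):(n - drop)] else x
  list(
    mean = mean(kept),
    sd = if (length(kept) > 1L) sd(kept) else 0,
    n_kept = length(kept)
  )
}

# signed fold change from a log2 difference: 2^d for d >= 0, -2^(-d) below,
# so |fc| >= 1 always and fc = 1 means "no change"
signed_fc_from_log2 <- function(d) {
  ifelse(d >= 0, 2^d, -(2^(-d)))
}

# inverse: log2 difference from a signed fold change
log2_from_signed_fc <- function(fc) {
  sign(fc) * log2(abs(fc))
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed) ||
      !is.numeric(seed) || seed != as.integer(seed)) {
    abort("`seed` must be supplied as a single integer; it is never implicit.")
  }
  as.integer(seed)
}
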