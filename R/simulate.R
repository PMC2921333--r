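#' Configuration for the two-channel array simulator
#'
#' Describes a synthetic two-colour microarray experiment: each array
#' hybridises a Cy5-labelled sample against a Cy3-labelled common reference,
#' and the simulator emits per-probe median signals for both channels. The
#' generative model works on the log2 scale: probe `i` on an array from
#' group `g` has log ratio
#' `M = effect(i) * 1[g = treated] + c0 + c1 * A + N(0, noise_sd)`, where
#' `A` is the probe's mean log2 intensity, `(c0, c1)` is a linear
#' intensity-dependent dye bias, and the two channel signals are
#' reconstructed as `2^(A + M/2)` and `2^(A - M/2)`. Negative-control
#' probes draw both channels from a log-normal background distribution.
#'
#' @param n_per_group arrays per condition (>= 1). Default 5, the per-group
#'   replication typical of a small in-vivo expression study.
#' @param n_probes number of non-control probes.
#' @param n_negctrl number of negative-control probes (>= 1).
#' @param effects named numeric vector of log2 effects in the treated group,
#'   names are probe ids (e.g. `c(p0001 = 2)`); or a data frame with columns
#'   `probe_id`, `log2_effect`. Probes not listed have effect 0.
#' @param noise_sd per-array log2-scale noise standard deviation (>= 0).
#' @param dye_bias length-2 numeric `(c0, c1)`: additive M-versus-A trend
#'   `c0 + c1 * A`.
#' @param negctrl_mean,negctrl_sd log2-scale mean and sd of the background
#'   signal distribution for negative-control probes.
#' @param baseline_range range (log2 scale) from which per-probe baseline
#'   abundances `A` are drawn uniformly. The default keeps expressed probes
#'   comfortably above the negative-control background (mean 6 on log2
#'   scale), as on a real array where annotated transcripts are detected;
#'   near-background behaviour is the province of the flagging stage and
#'   its negative controls.
#' @param groups length-2 character: control and treated condition labels,
#'   in that order.
#' @param seed integer seed; required, never implicit.
#' @return an `array_sim_config` list.
#' @seealso [simulate_two_channel_arrays()]
#' @export
array_sim_config <- function(n_per_group = 5, n_probes = 200, n_negctrl = 10,
                             effects = NULL, noise_sd = 0.25,
                             dye_bias = c(0, 0),
                             negctrl_mean = 6, negctrl_sd = 0.5,
                             baseline_range = c(9, 14),
                             groups = c("control", "hypo"),
                             seed) {
  seed <- check_seed(seed)
  if (n_per_group < 1 || n_probes < 1 || n_negctrl < 1) {
    abort("`n_per_group`, `n_probes` and `n_negctrl` must all be >= 1.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (length(dye_bias) != 2L) abort("`dye_bias` must be length 2: (c0, c1).")
  if (length(groups) != 2L || anyDuplicated(groups)) {
    abort("`groups` must be two distinct condition labels (control, treated).")
  }
  effects <- normalise_effects(effects, id_col = "probe_id",
                               value_col = "log2_effect")
  structure(
    list(
      n_per_group = as.integer(n_per_group),
      n_probes = as.integer(n_probes),
      n_negctrl = as.integer(n_negctrl),
      effects = effects, noise_sd = noise_sd,
      dye_bias = as.numeric(dye_bias),
      negctrl_mean = negctrl_mean, negctrl_sd = negctrl_sd,
      baseline_range = as.numeric(baseline_range),
      groups = as.character(groups), seed = seed
    ),
    class = "array_sim_config"
  )
}

# accept a named vector or a two-column data frame; return a tibble
normalise_effects <- function(effects, id_col, value_col) {
  if (is.null(effects)) {
    out <- tibble(id = character(0), value = numeric(0))
  } else if (is.data.frame(effects)) {
    check_columns(effects, c(id_col, value_col), "`effects`")
    out <- tibble(id = as.character(effects[[id_col]]),
                  value = as.numeric(effects[[value_col]]))
  } else if (is.numeric(effects) && !is.null(names(effects))) {
    out <- tibble(id = names(effects), value = as.numeric(effects))
  } else {
    abort("`effects` must be a named numeric vector or a data frame.")
  }
  if (anyDuplicated(out$id)) abort("`effects` lists an id more than once.")
  names(out) <- c(id_col, value_col)
  out
}

#' Simulate a two-channel microarray experiment with known truth
#'
#' Generates per-probe, per-array Cy5 (sample) and Cy3 (common reference)
#' median signals under the model described in [array_sim_config()], plus a
#' truth table recording each probe's planted log2 effect.
#'
#' @param cfg an [array_sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{intensities}{tibble with columns `probe_id`, `gene_id`,
#'       `is_negative_control`, `sample_id`, `group`, `channel`
#'       (`"sample"` or `"reference"`), `median_signal`.}
#'     \item{truth}{tibble with columns `feature_id`, `true_log2_effect`,
#'       `is_de`; one row per simulated probe (controls included, effect 0).}
#'   }
#' @examples
#' cfg <- array_sim_config(n_probes = 20, n_negctrl = 4,
#'                         effects = c(p0001 = 2), seed = 1)
#' sim <- simulate_two_channel_arrays(cfg)
#' head(sim$intensities)
#' @export
simulate_two_channel_arrays <- function(cfg) {
  stopifnot(inherits(cfg, "array_sim_config"))
  probe_ids <- sprintf("p%04d", seq_len(cfg$n_probes))
  ctrl_ids <- sprintf("negctrl_%02d", seq_len(cfg$n_negctrl))
  bad <- intersect(cfg$effects$probe_id, ctrl_ids)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Effects may not be assigned to negative-control probes: %s",
      paste(bad, collapse = ", ")
    ))
  }
  unknown <- setdiff(cfg$effects$probe_id, probe_ids)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown effect probe id(s): %s",
                  paste(unknown, collapse = ", ")))
  }

  set.seed(cfg$seed)
  effect <- setNames(rep(0, cfg$n_probes), probe_ids)
  effect[cfg$effects$probe_id] <- cfg$effects$log2_effect

  samples <- tibble(
    sample_id = paste0(rep(cfg$groups, each = cfg$n_per_group), "_",
                       rep(seq_len(cfg$n_per_group), 2L)),
    group = rep(cfg$groups, each = cfg$n_per_group)
  )
  treated <- cfg$groups[2L]

  baseline <- runif(cfg$n_probes, cfg$baseline_range[1L],
                    cfg$baseline_range[2L])
  n_s <- nrow(samples)

  grid <- tidyr::expand_grid(probe_id = probe_ids, samples)
  grid$A <- rep(baseline, each = n_s)
  mu <- rep(effect, each = n_s) * (grid$group == treated) +
    cfg$dye_bias[1L] + cfg$dye_bias[2L] * grid$A
  grid$M <- mu + rnorm(nrow(grid), 0, cfg$noise_sd)

  probes_long <- tibble(
    probe_id = rep(grid$probe_id, 2L),
    gene_id = sub("^p", "g", rep(grid$probe_id, 2L)),
    is_negative_control = FALSE,
    sample_id = rep(grid$sample_id, 2L),
    group = rep(grid$group, 2L),
    channel = rep(c("sample", "reference"), each = nrow(grid)),
    median_signal = c(2^(grid$A + grid$M / 2), 2^(grid$A - grid$M / 2))
  )

  ctrl_grid <- tidyr::expand_grid(probe_id = ctrl_ids, samples,
                                  channel = c("sample", "reference"))
  ctrl_grid$median_signal <-
    2^rnorm(nrow(ctrl_grid), cfg$negctrl_mean, cfg$negctrl_sd)
  ctrl_long <- tibble(
    probe_id = ctrl_grid$probe_id, gene_id = NA_character_,
    is_negative_control = TRUE, sample_id = ctrl_grid$sample_id,
    group = ctrl_grid$group, channel = ctrl_grid$channel,
    median_signal = ctrl_grid$median_signal
  )

  intensities <- bind_rows(probes_long, ctrl_long) |>
    arrange(.data$probe_id, .data$sample_id, .data$channel)

  truth <- tibble(
    feature_id = c(probe_ids, ctrl_ids),
    true_log2_effect = c(unname(effect), rep(0, cfg$n_negctrl)),
    is_de = c(unname(effect) != 0, rep(FALSE, cfg$n_negctrl))
  )
  list(intensities = intensities, truth = truth)
}

#' Configuration for the Ct (qPCR / TLDA) simulator
#'
#' Describes a synthetic threshold-cycle experiment. For assay `a` and
#' sample `s` in group `g`,
#' `Ct = baseline_ct - log2(fold(a)) * 1[g = treated] + offset(s) + N(0, sigma(g))`,
#' where `offset(s)` is a sample-level loading surrogate shared by every
#' assay of that sample (including the housekeeping assay, so delta-Ct is
#' offset-free by construction) and `sigma(g)` may differ between groups.
#' Values exceeding `max_ct` are recorded as undetermined.
#'
#' @param n_per_group samples per condition. Default 4, matching a typical
#'   low-density-array design.
#' @param n_assays number of target assays (the housekeeping assay is added
#'   on top).
#' @param housekeeping_id identifier of the housekeeping assay (U6 role).
#' @param effects named numeric vector of true fold changes (> 0), names are
#'   target assay ids (e.g. `c(mir_001 = 4)`); or a data frame with columns
#'   `assay_id`, `fold`. The housekeeping assay always has fold 1.
#' @param sigma_by_group per-group Ct standard deviations, length 2
#'   (control, treated); they may differ.
#' @param baseline_ct mean Ct of unchanged assays; must lie in (0, max_ct).
#' @param max_ct detection ceiling; Ct above it is undetermined. Default 40.
#' @param sample_offset_sd sd of the shared per-sample offset.
#' @param groups length-2 character: control and treated labels.
#' @param seed integer seed; required.
#' @return a `ct_sim_config` list.
#' @seealso [simulate_ct_experiment()]
#' @export
ct_sim_config <- function(n_per_group = 4, n_assays = 20,
                          housekeeping_id = "U6", effects = NULL,
                          sigma_by_group = c(0.25, 0.25),
                          baseline_ct = 28, max_ct = 40,
                          sample_offset_sd = 0.5,
                          groups = c("control", "hypo"), seed) {
  seed <- check_seed(seed)
  if (n_per_group < 1 || n_assays < 1) {
    abort("`n_per_group` and `n_assays` must be >= 1.")
  }
  if (!(baseline_ct > 0 && baseline_ct < max_ct)) {
    abort("`baseline_ct` must lie strictly between 0 and `max_ct`.")
  }
  if (length(sigma_by_group) != 2L || any(sigma_by_group < 0)) {
    abort("`sigma_by_group` must be two non-negative values.")
  }
  if (is.null(housekeeping_id) || !nzchar(housekeeping_id)) {
    abort("`housekeeping_id` must be a non-empty assay identifier.")
  }
  effects <- normalise_effects(effects, id_col = "assay_id",
                               value_col = "fold")
  if (any(effects$fold <= 0)) abort("True fold changes must be > 0.")
  if (housekeeping_id %in% effects$assay_id) {
    abort("The housekeeping assay must have true fold change 1; do not list it in `effects`.")
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group), n_assays = as.integer(n_assays),
      housekeeping_id = housekeeping_id, effects = effects,
      sigma_by_group = as.numeric(sigma_by_group),
      baseline_ct = baseline_ct, max_ct = max_ct,
      sample_offset_sd = sample_offset_sd,
      groups = as.character(groups), seed = seed
    ),
    class = "ct_sim_config"
  )
}

#' Simulate a Ct experiment (TLDA / single-assay qPCR) with known truth
#'
#' Draws threshold-cycle values under the model in [ct_sim_config()]. A
#' planted fold change `f` shifts the treated group's Ct by `-log2(f)`
#' (more template, earlier threshold crossing), so downstream delta-delta-Ct
#' quantification should recover `f` exactly in the noise-free limit.
#'
#' @param cfg a [ct_sim_config()].
#' @return a list with elements
#'   \describe{
#'     \item{ct}{tibble with columns `sample_id`, `group`, `assay_id`, `ct`
#'       (numeric, `NA` where undetermined) and `undetermined` (logical).}
#'     \item{truth}{tibble `feature_id`, `true_log2_effect`, `is_de`, one
#'       row per assay including the housekeeping assay (effect 0).}
#'   }
#' @examples
#' cfg <- ct_sim_config(n_assays = 5, effects = c(mir_001 = 4),
#'                      sigma_by_group = c(0, 0), seed = 1)
#' sim <- simulate_ct_experiment(cfg)
#' @export
simulate_ct_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "ct_sim_config"))
  target_ids <- sprintf("mir_%03d", seq_len(cfg$n_assays))
  unknown <- setdiff(cfg$effects$assay_id, target_ids)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown effect assay id(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  assay_ids <- c(target_ids, cfg$housekeeping_id)

  set.seed(cfg$seed)
  fold <- setNames(rep(1, length(assay_ids)), assay_ids)
  fold[cfg$effects$assay_id] <- cfg$effects$fold

  samples <- tibble(
    sample_id = paste0(rep(cfg$groups, each = cfg$n_per_group), "_",
                       rep(seq_len(cfg$n_per_group), 2L)),
    group = rep(cfg$groups, each = cfg$n_per_group),
    offset = rnorm(2L * cfg$n_per_group, 0, cfg$sample_offset_sd)
  )
  treated <- cfg$groups[2L]
  sigma <- setNames(cfg$sigma_by_group, cfg$groups)

  grid <- tidyr::expand_grid(assay_id = assay_ids, samples)
  mu <- cfg$baseline_ct -
    log2(fold[grid$assay_id]) * (grid$group == treated) + grid$offset
  ct <- mu + rnorm(nrow(grid), 0, sigma[grid$group])
  undet <- ct > cfg$max_ct

  ct_tbl <- tibble(
    sample_id = grid$sample_id, group = grid$group,
    assay_id = grid$assay_id,
    ct = ifelse(undet, NA_real_, ct), undetermined = undet
  ) |>
    arrange(.data$assay_id, .data$sample_id)

  truth <- tibble(
    feature_id = assay_ids,
    true_log2_effect = unname(log2(fold)),
    is_de = unname(fold != 1)
  )
  list(ct = ct_tbl, truth = truth)
}

#' Simulate miRNA target-prediction tables from two sources
#'
#' Emits a prediction table in the shape produced by exporting two target
#' prediction databases (e.g. a seed-match-based and a
#' complementarity-based algorithm): one row per (source, miRNA, gene).
#' The two sources' per-miRNA target sets share a controllable fraction of
#' entries, so the downstream "predicted by either source" union rule can be
#' tested against a known composition.
#'
#' @param mirnas character vector of miRNA ids.
#' @param genes character vector of candidate gene symbols.
#' @param targets_per_mirna number of targets each source predicts per
#'   miRNA; must not exceed `length(genes)`.
#' @param overlap_fraction fraction (0-1) of each miRNA's targets shared by
#'   both sources.
#' @param seed integer seed; required.
#' @param sources length-2 character labels for the two prediction sources.
#' @return a list with elements
#'   \describe{
#'     \item{predictions}{tibble `source`, `mirna_id`, `gene_id`.}
#'     \item{truth}{tibble `mirna_id`, `gene_id`, `in_both` — the per-miRNA
#'       union with a flag for genes predicted by both sources.}
#'   }
#' @export
simulate_target_table <- function(mirnas, genes, targets_per_mirna,
                                  overlap_fraction, seed,
                                  sources = c("sourceA", "sourceB")) {
  seed <- check_seed(seed)
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    abort("`overlap_fraction` must lie in [0, 1].")
  }
  if (targets_per_mirna > length(genes)) {
    abort("`targets_per_mirna` must not exceed the number of genes.")
  }
  n_shared <- round(overlap_fraction * targets_per_mirna)
  n_unique <- targets_per_mirna - n_shared
  if (n_shared + 2L * n_unique > length(genes)) {
    abort("Not enough genes to draw disjoint source-specific targets; supply more genes or raise `overlap_fraction`.")
  }
  if (length(sources) != 2L) abort("`sources` must be two labels.")

  set.seed(seed)
  per_mirna <- purrr::map(mirnas, function(m) {
    picked <- sample(genes, n_shared + 2L * n_unique)
    shared <- picked[seq_len(n_shared)]
    only_a <- picked[n_shared + seq_len(n_unique)]
    only_b <- picked[n_shared + n_unique + seq_len(n_unique)]
    list(
      predictions = tibble(
        source = rep(sources, times = c(n_shared + n_unique,
                                        n_shared + n_unique)),
        mirna_id = m,
        gene_id = c(shared, only_a, shared, only_b)
      ),
      truth = tibble(
        mirna_id = m, gene_id = c(shared, only_a, only_b),
        in_both = c(rep(TRUE, n_shared), rep(FALSE, 2L * n_unique))
      )
    )
  })
  list(
    predictions = purrr::list_rbind(purrr::map(per_mirna, "predictions")),
    truth = purrr::list_rbind(purrr::map(per_mirna, "truth"))
  )
}
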