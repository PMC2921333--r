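test_that("array simulator is deterministic and truth-consistent", {
  cfg <- array_sim_config(n_per_group = 3, n_probes = 30, n_negctrl = 5,
                          effects = c(p0002 = 1.5), seed = 7)
  a <- simulate_two_channel_arrays(cfg)
  b <- simulate_two_channel_arrays(cfg)
  expect_identical(a, b)
  # every intensity feature appears exactly once in the truth table
  expect_setequal(unique(a$intensities$probe_id), a$truth$feature_id)
  expect_false(anyDuplicated(a$truth$feature_id) > 0)
  expect_true(all(a$truth$is_de == (abs(a$truth$true_log2_effect) > 0)))
})

test_that("noise-free, bias-free arrays have M = 0 for non-control probes", {
  cfg <- array_sim_config(n_per_group = 2, n_probes = 15, n_negctrl = 3,
                          noise_sd = 0, seed = 3)
  sim <- simulate_two_channel_arrays(cfg)
  ma <- ma_transform(sim$intensities)
  m <- ma$M[!ma$is_negative_control]
  expect_true(all(abs(m) < 1e-12))
})

test_that("planted array effect is recovered in the group-mean M contrast", {
  cfg <- array_sim_config(n_per_group = 50, n_probes = 40, n_negctrl = 5,
                          effects = c(p0001 = 2), noise_sd = 0.25, seed = 21)
  sim <- simulate_two_channel_arrays(cfg)
  ma <- ma_transform(sim$intensities)
  p1 <- ma[ma$probe_id == "p0001", ]
  diff <- mean(p1$M[p1$group == "hypo"]) - mean(p1$M[p1$group == "control"])
  # standard error is 0.25 * sqrt(2/50) ~= 0.05
  expect_lt(abs(diff - 2), 0.1)
})

test_that("dye bias enters M as c0 + c1 * A", {
  cfg <- array_sim_config(n_per_group = 2, n_probes = 25, n_negctrl = 3,
                          noise_sd = 0, dye_bias = c(0.3, 0.1), seed = 9)
  sim <- simulate_two_channel_arrays(cfg)
  ma <- ma_transform(sim$intensities) |>
    dplyr::filter(!is_negative_control)
  expect_equal(ma$M, 0.3 + 0.1 * ma$A, tolerance = 1e-10)
})

test_that("effects on negative-control probes are rejected by name", {
  expect_error(
    simulate_two_channel_arrays(
      array_sim_config(n_probes = 5, n_negctrl = 2,
                       effects = c(negctrl_01 = 1), seed = 1)),
    "negctrl_01"
  )
  expect_error(array_sim_config(n_probes = 0, seed = 1), ">= 1")
  expect_error(array_sim_config(n_probes = 5, noise_sd = -1, seed = 1))
  expect_error(array_sim_config(n_probes = 5), "seed")
})

test_that("ct simulator honours the delta-Ct algebra", {
  # all folds 1, sigma 0: dCt identical across samples for every assay
  null_cfg <- ct_sim_config(n_assays = 4, sigma_by_group = c(0, 0), seed = 2)
  sim <- simulate_ct_experiment(null_cfg)
  dct <- delta_ct(sim$ct, housekeeping = "U6")
  spread <- tapply(dct$dct, dct$assay_id, function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))

  # planted fold 4, sigma 0: treated - control dCt contrast is exactly -2
  cfg <- ct_sim_config(n_assays = 4, effects = c(mir_001 = 4),
                       sigma_by_group = c(0, 0), seed = 2)
  sim2 <- simulate_ct_experiment(cfg)
  dct2 <- delta_ct(sim2$ct, housekeeping = "U6")
  m1 <- dct2[dct2$assay_id == "mir_001", ]
  expect_equal(mean(m1$dct[m1$group == "hypo"]) -
                 mean(m1$dct[m1$group == "control"]), -2)
  expect_equal(sim2$truth$true_log2_effect[sim2$truth$feature_id == "mir_001"], 2)
})

test_that("Ct values beyond the ceiling are emitted as undetermined", {
  cfg <- ct_sim_config(n_assays = 3, effects = c(mir_002 = 0.1),
                       sigma_by_group = c(0, 0), sample_offset_sd = 0,
                       baseline_ct = 39, max_ct = 40, seed = 4)
  sim <- simulate_ct_experiment(cfg)
  m2 <- sim$ct[sim$ct$assay_id == "mir_002", ]
  treated <- m2[m2$group == "hypo", ]
  # 39 + log2(10) ~= 42.3 > 40
  expect_true(all(treated$undetermined))
  expect_true(all(is.na(treated$ct)))
  expect_false(any(m2$undetermined[m2$group == "control"]))
})

test_that("ct simulator validates its configuration", {
  expect_error(ct_sim_config(effects = c(U6 = 2), seed = 1), "housekeeping")
  expect_error(ct_sim_config(baseline_ct = 45, max_ct = 40, seed = 1))
  expect_error(ct_sim_config(effects = c(mir_001 = -2), seed = 1), "> 0")
  a <- simulate_ct_experiment(ct_sim_config(n_assays = 3, seed = 5))
  b <- simulate_ct_experiment(ct_sim_config(n_assays = 3, seed = 5))
  expect_identical(a, b)
})

test_that("target table overlap fraction controls the union composition", {
  mirnas <- c("miR-1", "miR-206")
  genes <- sprintf("gene%02d", 1:40)
  full <- simulate_target_table(mirnas, genes, targets_per_mirna = 7,
                                overlap_fraction = 1, seed = 6)
  per <- split(full$predictions, full$predictions$source)
  expect_identical(
    sort(paste(per[[1]]$mirna_id, per[[1]]$gene_id)),
    sort(paste(per[[2]]$mirna_id, per[[2]]$gene_id))
  )

  none <- simulate_target_table(mirnas, genes, targets_per_mirna = 7,
                                overlap_fraction = 0, seed = 6)
  union_sizes <- tapply(none$truth$gene_id, none$truth$mirna_id,
                        function(x) length(unique(x)))
  expect_true(all(union_sizes == 14))

  expect_error(simulate_target_table(mirnas, genes, 7, overlap_fraction = 2,
                                     seed = 1), "\\[0, 1\\]")
  expect_error(simulate_target_table(mirnas, genes, 50, 0.5, seed = 1),
               "exceed")
})

test_that("a two-family, 7-target union table matches the published shape", {
  sim <- simulate_target_table(c("miR-1/206", "miR-133a/b"),
                               sprintf("g%02d", 1:60),
                               targets_per_mirna = 7,
                               overlap_fraction = 1, seed = 8)
  fam_sets <- union_predictions(
    sim$predictions,
    list("miR-1/206" = "miR-1/206", "miR-133a/b" = "miR-133a/b")
  )
  expect_equal(nrow(fam_sets), 14L)  # 7 + 7 rows, as in the reference table
  expect_equal(as.vector(table(fam_sets$family)[c("miR-1/206", "miR-133a/b")]),
               c(7L, 7L))
})

test_that("null simulation yields approximately uniform raw p-values", {
  cfg <- array_sim_config(n_per_group = 4, n_probes = 2000, n_negctrl = 20,
                          seed = 13)
  sim <- simulate_two_channel_arrays(cfg)
  fit <- run_array_pipeline(sim$intensities, treated = "hypo",
                            control = "control", seed = 13)
  p <- tidy(fit)$p_raw
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
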