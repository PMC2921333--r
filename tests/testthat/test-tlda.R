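groups_ct <- setNames(rep(c("control", "hypo"), each = 3),
                      c("c1", "c2", "c3", "h1", "h2", "h3"))

test_that("delta-Ct subtracts the housekeeping cycle per sample", {
  ct <- make_ct(list(m1 = c(25, 26, 24, 23, 22, 24),
                     U6 = c(20, 21, 20, 20, 19, 21)), groups_ct)
  d <- delta_ct(ct, housekeeping = "U6")
  expect_equal(d$dct[d$assay_id == "m1" & d$sample_id == "c1"], 5)
  expect_true(all(d$dct[d$assay_id == "U6"] == 0))
})

test_that("a constant shift of one sample's Ct values cancels in delta-Ct", {
  ct <- make_ct(list(m1 = c(25, 26, 24, 23, 22, 24),
                     m2 = c(30, 31, 29, 30, 30, 31),
                     U6 = c(20, 21, 20, 20, 19, 21)), groups_ct)
  shifted <- ct
  shifted$ct[shifted$sample_id == "h2"] <-
    shifted$ct[shifted$sample_id == "h2"] + 1.3
  expect_equal(delta_ct(ct, "U6"), delta_ct(shifted, "U6"))
  # and therefore the whole downstream pipeline is invariant
  f1 <- run_tlda_pipeline(ct, "U6", treated = "hypo", control = "control",
                          B = 199, seed = 2)
  f2 <- run_tlda_pipeline(shifted, "U6", treated = "hypo",
                          control = "control", B = 199, seed = 2)
  expect_equal(tidy(f1), tidy(f2))
})

test_that("undetermined handling follows the configured policy", {
  ct <- make_ct(list(m1 = c(25, NA, 24, 23, 22, 24),
                     U6 = c(20, 21, 20, 20, 19, 21)), groups_ct)
  d_omit <- delta_ct(ct, "U6", undetermined = "omit")
  expect_false(any(d_omit$assay_id == "m1" & d_omit$sample_id == "c2"))
  d_ceil <- delta_ct(ct, "U6", undetermined = "ceiling", max_ct = 40)
  expect_equal(d_ceil$dct[d_ceil$assay_id == "m1" & d_ceil$sample_id == "c2"],
               40 - 21)
  bad <- make_ct(list(m1 = c(25, 26, 24, 23, 22, 24),
                      U6 = c(20, NA, 20, 20, 19, 21)), groups_ct)
  expect_error(delta_ct(bad, "U6"), "c2")
  expect_error(delta_ct(ct, "U7"), "U7")
})

test_that("per-assay ANOVA matches the closed form and reports residuals", {
  ct <- make_ct(list(m1 = c(21, 22, 23, 24, 25, 26),
                     U6 = c(20, 20, 20, 20, 20, 20)), groups_ct)
  av <- anova_f(delta_ct(ct, "U6") |> dplyr::filter(assay_id == "m1"))
  expect_equal(av$F, 13.5)
  expect_equal(av$F, aov_f(c(1, 2, 3, 4, 5, 6), unname(groups_ct)))
  resid <- av$residuals_by_group[[1]]
  expect_equal(vapply(resid, sum, numeric(1)), c(control = 0, hypo = 0))

  flat <- make_ct(list(m1 = c(22, 23, 21, 23, 21, 22),
                       U6 = rep(20, 6)), groups_ct)
  av0 <- anova_f(delta_ct(flat, "U6") |> dplyr::filter(assay_id == "m1"))
  expect_equal(av0$F, 0)
})

test_that("assays without enough determined values become untestable records", {
  ct <- make_ct(list(m1 = c(25, NA, NA, 23, 22, 24),
                     U6 = rep(20, 6)), groups_ct)
  av <- anova_f(delta_ct(ct, "U6") |> dplyr::filter(assay_id == "m1"))
  expect_false(av$testable)
  expect_match(av$reason, "fewer than 2")
})

test_that("bootstrap p-values obey the add-one convention and the grid", {
  # distinct residual values, so no resample can reproduce a zero-variance tie
  resid <- list(control = c(-1.3, 0.4, 1.2, -0.3), hypo = c(-2.1, 0.9, 1.4, -0.2))
  p_min <- bootstrap_pvalue(Inf, resid, B = 999, seed = 9)
  expect_equal(p_min, 1 / 1000)
  p_max <- bootstrap_pvalue(0, resid, B = 999, seed = 9)
  expect_equal(p_max, 1)
  p1 <- bootstrap_pvalue(2.3, resid, B = 499, seed = 10)
  p2 <- bootstrap_pvalue(2.3, resid, B = 499, seed = 10)
  expect_identical(p1, p2)
  expect_true(abs(p1 * 500 - round(p1 * 500)) < 1e-9)
  expect_error(bootstrap_pvalue(1, list(a = 1, b = c(1, 2)), B = 99,
                                seed = 1), "at least 2")
  expect_error(bootstrap_pvalue(1, resid, B = 50, seed = 1), ">= 99")
})

test_that("ddCt fold changes follow the 2^(-ddCt) sign convention", {
  ct <- make_ct(list(m1 = c(24, 24, 24, 22, 22, 22),  # dct 4 -> 2: up 4x
                     m2 = c(22, 22, 22, 23.5, 23.5, 23.5),  # +1.5: down
                     m3 = c(25, 25, 25, 25, 25, 25),
                     U6 = rep(20, 6)), groups_ct)
  fc <- fold_change_ddct(delta_ct(ct, "U6"), treated = "hypo",
                         control = "control")
  expect_equal(fc$fc_signed[fc$assay_id == "m1"], 4)
  expect_equal(fc$fc_signed[fc$assay_id == "m2"], -2^1.5)
  expect_equal(fc$fc_signed[fc$assay_id == "m3"], 1)
  expect_equal(fc$ddct[fc$assay_id == "m1"], -2)
})

test_that("noise-free planted folds are recovered exactly through the pipeline", {
  cfg <- ct_sim_config(n_assays = 5, n_per_group = 4,
                       effects = c(mir_002 = 6, mir_004 = 0.25),
                       sigma_by_group = c(0, 0), seed = 15)
  sim <- simulate_ct_experiment(cfg)
  fit <- run_tlda_pipeline(sim$ct, "U6", treated = "hypo",
                           control = "control", B = 199, seed = 15)
  res <- tidy(fit)
  expect_equal(res$fc_signed[res$assay_id == "mir_002"], 6)
  expect_equal(res$fc_signed[res$assay_id == "mir_004"], -4)
})

test_that("large planted folds are detected with calibrated magnitudes", {
  eff <- c(mir_001 = 500, mir_002 = 100, mir_003 = 90, mir_004 = 59)
  sim <- simulate_ct_experiment(ct_sim_config(
    n_assays = 20, n_per_group = 4, effects = eff,
    sigma_by_group = c(0.25, 0.25), seed = 16))
  fit <- run_tlda_pipeline(sim$ct, "U6", treated = "hypo",
                           control = "control", B = 999, seed = 16)
  res <- tidy(fit)
  planted <- res[match(names(eff), res$assay_id), ]
  expect_true(all(planted$significant))
  # ddCt noise sd is 0.25*sqrt(2)*sqrt(2/4) = 0.25; allow 4 sigma per assay
  log2_err <- log2(planted$fc_signed) - log2(eff)
  expect_true(all(abs(log2_err) < 1))
  # and the aggregate (geometric-mean) recovery is within 30 percent
  expect_lt(abs(2^mean(log2_err) - 1), 0.3)
  expect_false("U6" %in% res$assay_id)
})

test_that("the null TLDA pipeline makes no discoveries at FDR 0.1", {
  n_sig <- vapply(1:10, function(s) {
    sim <- simulate_ct_experiment(ct_sim_config(
      n_assays = 50, n_per_group = 4, seed = 400 + s))
    fit <- run_tlda_pipeline(sim$ct, "U6", treated = "hypo",
                             control = "control", B = 199,
                             seed = 400 + s)
    sum(tidy(fit)$significant)
  }, numeric(1))
  expect_equal(median(n_sig), 0)
})
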