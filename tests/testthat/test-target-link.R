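preds_ab <- tibble::tibble(
  source = c("A", "A", "B", "B"),
  mirna_id = "miR-1",
  gene_id = c("g1", "g2", "g2", "g3")
)

test_that("the either-source union rule pools and deduplicates", {
  u <- union_predictions(preds_ab, list("miR-1" = "miR-1"))
  expect_setequal(u$gene_id, c("g1", "g2", "g3"))
  # identical sources: union equals either one
  same <- preds_ab
  same$gene_id <- rep(c("g1", "g2"), 2)
  u2 <- union_predictions(same, list("miR-1" = "miR-1"))
  expect_setequal(u2$gene_id, c("g1", "g2"))
})

test_that("family members pool their target sets", {
  preds <- tibble::tibble(
    source = "A", mirna_id = c("miR-1", "miR-206"),
    gene_id = c("g1", "g2")
  )
  u <- union_predictions(preds, list("miR-1/206" = c("miR-1", "miR-206")))
  expect_setequal(u$gene_id, c("g1", "g2"))
  expect_true(all(u$family == "miR-1/206"))
})

test_that("union is order-independent and idempotent across sources", {
  set.seed(61)
  sim <- simulate_target_table(c("m1", "m2"), sprintf("g%02d", 1:30),
                               targets_per_mirna = 6,
                               overlap_fraction = 0.5, seed = 61)
  fams <- list(f1 = "m1", f2 = "m2")
  u1 <- union_predictions(sim$predictions, fams)
  shuffled <- sim$predictions[sample(nrow(sim$predictions)), ]
  u2 <- union_predictions(shuffled, fams)
  expect_equal(dplyr::arrange(u1, family, gene_id),
               dplyr::arrange(u2, family, gene_id))
  doubled <- dplyr::bind_rows(sim$predictions, sim$predictions)
  u3 <- union_predictions(doubled, fams)
  expect_equal(dplyr::arrange(u1, family, gene_id),
               dplyr::arrange(u3, family, gene_id))
})

test_that("a miRNA absent from every source warns and yields an empty set", {
  expect_warning(
    u <- union_predictions(preds_ab, list(fam = c("miR-1", "miR-999"))),
    "miR-999"
  )
  expect_setequal(u$gene_id, c("g1", "g2", "g3"))
})

test_that("DE filtering uses strict inequalities on both axes", {
  de <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    fc_signed = c(1.5, -1.6, 2.0, -3.0),
    p_adj = c(0.01, 0.05, 0.04, 0.002)
  )
  kept <- filter_de_genes(de, fc_min = 1.5, p_max = 0.05)
  expect_setequal(kept$gene_id, c("c", "d"))  # |1.5| and p = 0.05 excluded
  expect_equal(nrow(filter_de_genes(de[0, ])), 0L)
})

test_that("overlap report classifies directions and tallies concordance", {
  targets <- tibble::tibble(family = c("f1", "f1", "f2"),
                            gene_id = c("g1", "g2", "g3"))
  sig <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g9"),
                        fc_signed = c(-2, 1.8, -1.7, -5))
  rep <- overlap_and_concordance(targets, sig,
                                 c(f1 = "up", f2 = "up"))
  ov <- glance(rep)
  expect_equal(ov$n_total, 3L)
  expect_equal(ov$n_down, 2L)
  expect_equal(ov$n_up, 1L)
  expect_equal(ov$n_concordant, 2L)
  expect_equal(ov$n_total, ov$n_down + ov$n_up)
  # disjoint sets produce an empty report with zero tallies
  rep0 <- overlap_and_concordance(
    targets, tibble::tibble(gene_id = "zz", fc_signed = 2),
    c(f1 = "up", f2 = "up"))
  expect_equal(glance(rep0)$n_total, 0L)
})

test_that("re-reporting a report's own rows is a fixed point", {
  rep <- overlap_and_concordance(
    tibble::tibble(family = "f1", gene_id = c("g1", "g2")),
    tibble::tibble(gene_id = c("g1", "g2"), fc_signed = c(-2, 3)),
    c(f1 = "up"))
  again <- overlap_and_concordance(
    tidy(rep)[, c("family", "gene_id")],
    tidy(rep)[, c("gene_id", "fc_signed")],
    c(f1 = "up"))
  expect_equal(tidy(again), tidy(rep))
})

test_that("genes shared between families are reported under both", {
  targets <- tibble::tibble(family = c("f1", "f2"), gene_id = "g1")
  sig <- tibble::tibble(gene_id = "g1", fc_signed = -2)
  rep <- overlap_and_concordance(targets, sig, c(f1 = "up", f2 = "down"))
  rows <- tidy(rep)
  expect_equal(nrow(rows), 2L)
  expect_true(all(rows$shared_across_families))
})

test_that("planted suppressed targets of an up-regulated miRNA are fully concordant", {
  sim <- simulate_target_table(c("m1", "m2"), sprintf("g%02d", 1:40),
                               targets_per_mirna = 5,
                               overlap_fraction = 0.4, seed = 77)
  fams <- list(fam = c("m1", "m2"))
  targets <- union_predictions(sim$predictions, fams)
  # noise-free DE outcome: every predicted target suppressed
  sig <- tibble::tibble(gene_id = unique(sim$truth$gene_id),
                        fc_signed = -2)
  rep <- overlap_and_concordance(targets, sig, c(fam = "up"))
  expect_equal(glance(rep)$concordance, 1)
  expect_equal(glance(rep)$n_total, nrow(targets))
})

test_that("the published reference tables reproduce their printed tallies", {
  mir <- reference_mirna_de()
  expect_equal(nrow(filter_de_genes(mir, fc_min = 4, p_max = 1,
                                    p_col = "p")), 11L)
  # the row printed at p = 0.10 sits exactly on the strict boundary
  expect_equal(nrow(filter_de_genes(mir, fc_min = 4, p_max = 0.1,
                                    p_col = "p")), 10L)
  tgt <- reference_target_de()
  fams <- split(tgt$gene_id, tgt$family)
  rep <- overlap_and_concordance(
    tibble::tibble(family = tgt$family, gene_id = tgt$gene_id),
    tgt[, c("gene_id", "fc_signed")],
    c("miR-1/206" = "up", "miR-133a/b" = "up"))
  expect_equal(glance(rep)$n_total, 14L)
  expect_equal(glance(rep)$n_down, 11L)
  expect_equal(glance(rep)$n_concordant, 11L)
})
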