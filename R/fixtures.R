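#' Reference miRNA differential-expression values (hypothyroid mouse liver)
#'
#' The published low-density-array profile of hepatic miRNAs altered in
#' juvenile mice rendered hypothyroid with goitrogens, as printed: the 11
#' miRNAs passing the reported filter (p < 0.1, |fold change| > 4), with
#' their fold changes, p-values and family assignment. Three clustered
#' muscle-associated families (miR-1/206, miR-133a/b, miR-135a/b) dominate
#' the up-regulated set. Used as a small in-package fixture for the
#' filtering and tallying logic.
#'
#' @return tibble `assay_id`, `family`, `fc_signed`, `p`.
#' @export
reference_mirna_de <- function() {
  tibble(
    assay_id = c("mmu-miR-133b", "mmu-miR-133a", "mmu-miR-1",
                 "mmu-miR-206", "mmu-miR-135b", "mmu-miR-135a",
                 "mmu-miR-138", "mmu-miR-199b", "mmu-miR-148a",
                 "mmu-miR-582-5p", "mmu-miR-200a"),
    family = c("miR-133", "miR-133", "miR-1/206", "miR-1/206",
               "miR-135", "miR-135", "other", "other", "other",
               "other", "other"),
    fc_signed = c(501.39, 100.36, 92.11, 58.90, 85.11, 14.62,
                  27.77, 4.96, -4.20, -5.14, -5.49),
    p = c(0.05, 0.02, 0.01, 0.07, 0.09, 0.09, 0.08, 0.05, 0.04,
          0.07, 0.10)
  )
}

#' Reference predicted-target differential-expression values
#' (hypothyroid mouse liver)
#'
#' The published overlap between predicted targets of the miR-1/206 and
#' miR-133a/b families and the genes significantly altered in hypothyroid
#' juvenile mouse liver (p < 0.05, |fold change| > 1.5), as printed: 14
#' genes, 7 per family, with signed fold changes (negative = down in
#' hypothyroid liver) and p-values. With both miRNA families strongly
#' up-regulated, 11 of the 14 targets move in the opposite (concordant)
#' direction. Used as a small in-package fixture for the overlap and
#' concordance logic.
#'
#' @return tibble `accession`, `gene_id`, `family`, `p`, `fc_signed`.
#' @export
reference_target_de <- function() {
  tibble(
    accession = c("NM_013703", "NM_001013785", "NM_029692", "NM_010274",
                  "NM_031188", "NM_008737", "NM_026460",
                  "NM_016919", "NM_182959", "NM_025989", "NM_009344",
                  "NM_008693", "NM_010639", "NM_007769"),
    gene_id = c("Vldlr", "Akr1c19", "Upp2", "Gpd2", "Mup1", "Nrp1",
                "Serpini2",
                "Col5a3", "Slc17a8", "Gp2", "Phlda1", "Klk1b3", "Klk1",
                "Dmbt1"),
    family = rep(c("miR-1/206", "miR-133a/b"), each = 7L),
    p = c(0.001, 0.000, 0.008, 0.000, 0.003, 0.000, 0.001,
          0.000, 0.000, 0.002, 0.000, 0.002, 0.001, 0.004),
    fc_signed = c(1.669, 1.612, -1.562, -1.695, -1.815, -2.000, -3.080,
                  1.752, -1.637, -1.727, -1.815, -2.103, -2.111, -4.236)
  )
}
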