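test_that("gene-wise ANOVA matches the least-squares oracle on toys", {
  set.seed(10)
  designs <- list(
    list(status = rep(c("p", "c"), each = 4),
         treatment = rep(c("t", "v"), 4)),
    list(status = rep(c("p", "c"), each = 8),
         couple = rep(rep(c("c1", "c2"), each = 2), 4),
         treatment = rep(c("t", "v"), 8)),
    list(a = rep(letters[1:4], each = 3),
         b = rep(c("x", "y", "z"), 4))
  )
  for (fac in designs) {
    n <- length(fac[[1]])
    for (rep_i in 1:3) {
      y <- rnorm(n, 5)
      C <- matrix(y, 1, n, dimnames = list("g1", NULL))
      got <- genewise_anova(C, as.data.frame(fac))
      oracle <- anova_lm_oracle(y, fac)
      for (j in seq_along(fac)) {
        f <- names(fac)[j]
        expect_equal(got[[paste0("ss_", f)]], oracle$ss[j],
                     tolerance = 1e-8)
        expect_equal(got[[paste0("F_", f)]], oracle$F[j],
                     tolerance = 1e-8)
        expect_equal(got[[paste0("p_", f)]], oracle$p[j],
                     tolerance = 1e-8)
      }
      expect_equal(got$ss_resid, oracle$ss_resid, tolerance = 1e-8)
    }
  }
})

test_that("hand-chosen couple design reproduces an explicit additive fit", {
  # 2 couples x 2 status x 2 treatments, one gene
  fac <- list(status = rep(c("pat", "ctl"), each = 4),
              couple = rep(rep(c("c1", "c2"), each = 2), 2),
              treatment = rep(c("thaps", "veh"), 4))
  y <- c(7.1, 7.3, 6.8, 7.0, 8.0, 8.2, 7.9, 8.1)
  got <- suppressMessages(
    genewise_anova(matrix(y, 1, 8), as.data.frame(fac)))
  oracle <- anova_lm_oracle(y, fac)
  expect_equal(got$F_status, oracle$F[1], tolerance = 1e-8)
  expect_equal(got$F_couple, oracle$F[2], tolerance = 1e-8)
  expect_equal(got$F_treatment, oracle$F[3], tolerance = 1e-8)
})

test_that("zero-variance genes are reported as F = 0, p = 1", {
  fac <- data.frame(status = rep(c("p", "c"), each = 2))
  C <- matrix(c(5, 5, 5, 5,
                1, 2, 3, 4), 2, 4, byrow = TRUE,
              dimnames = list(c("flat", "var"), NULL))
  got <- suppressMessages(genewise_anova(C, fac))
  expect_equal(got$F_status[1], 0)
  expect_equal(got$p_status[1], 1)
  expect_gt(got$F_status[2], 0)
})

test_that("unbalanced designs need the sequential-SS opt-in", {
  fac <- data.frame(status = c("p", "p", "p", "c", "c"),
                    treatment = c("t", "v", "t", "t", "v"))
  C <- matrix(rnorm(5), 1, 5)
  expect_error(genewise_anova(C, fac), "balanced")
  got <- suppressMessages(genewise_anova(C, fac,
                                         allow_unbalanced = TRUE))
  oracle <- anova_lm_oracle(C[1, ], as.list(fac))  # aov is Type-I too
  expect_equal(got$ss_status, oracle$ss[1], tolerance = 1e-8)
  expect_equal(got$ss_treatment, oracle$ss[2], tolerance = 1e-8)
})

test_that("noise-free bundle separates implanted from null genes", {
  b <- noise_free_bundle()
  C <- corrected_from(b)
  de <- anova_case_control(C, b$design, "EIF2B")
  implanted <- b$truth$class %in% c("shared_de", "specific_down",
                                    "specific_up")
  expect_true(all(de$p_status[implanted] < 1e-10))
  expect_true(all(de$F_status[b$truth$class == "null"] < 1e-6))
  # cross-cohort model flags only the eIF2B-specific genes
  cross <- anova_cross_cohort(C, b$design)
  spec <- b$truth$class %in% c("specific_down", "specific_up")
  expect_true(all(cross$p_cohort[spec] < 1e-10))
  expect_true(all(cross$F_cohort[b$truth$class == "shared_de"] < 1e-6))
})

test_that("BH adjustment reproduces hand computations", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # order preserved
  p <- c(0.03, 0.001, 0.2)
  expect_equal(order(fdr_adjust(p)), order(p))
})

test_that("BH keeps the false-discovery proportion at the nominal level", {
  # 200 all-null simulations through the gene-wise ANOVA
  set.seed(20)
  fac <- data.frame(status = rep(c("p", "c"), each = 4),
                    treatment = rep(c("t", "v"), 4))
  fdp <- replicate(200, {
    C <- matrix(rnorm(200 * 8), 200, 8)
    tab <- genewise_anova(C, fac)
    q <- fdr_adjust(tab$p_status)
    n_disc <- sum(q <= 0.0012)
    if (n_disc == 0) 0 else 1  # every discovery is false here
  })
  # P(any BH rejection) <= q under the global null; allow 3 MC sds
  expect_lte(mean(fdp), 0.0012 + 3 * sqrt(0.0012 / 200))
})

test_that("expression rates follow the couple-ratio arithmetic", {
  # toy: 2 couples, single treatment
  design <- data.frame(
    sample_id = c("p1", "c1", "p2", "c2"),
    subject_id = c("p1", "c1", "p2", "c2"),
    cohort = "EIF2B",
    couple_id = c("cp1", "cp1", "cp2", "cp2"),
    role = c("patient", "control", "patient", "control"),
    treatment = "vehicle", stringsAsFactors = FALSE)
  C <- matrix(c(7.2, 8.0, 6.8, 8.5), 1, 4,
              dimnames = list("g1", design$sample_id))
  r <- expression_rate(C, design)
  expect_equal(r$rate, (7.2 / 8.0 + 6.8 / 8.5) / 2)
  expect_equal(r$direction, "under")
  # patient row == control row -> rate 1, neutral
  C2 <- matrix(c(5, 5, 7, 7), 1, 4,
               dimnames = list("g1", design$sample_id))
  r2 <- expression_rate(C2, design)
  expect_equal(r2$rate, 1)
  expect_equal(r2$direction, "neutral")
})

test_that("specificity selection recovers implanted genes and is monotone", {
  b <- noise_free_bundle()
  C <- corrected_from(b)
  de <- anova_case_control(C, b$design, "EIF2B")
  cross <- anova_cross_cohort(C, b$design)
  rates <- expression_rate(C, b$design, "EIF2B")
  sel <- select_specific(de, cross, rates)
  spec_truth <- sort(b$truth$gene_id[b$truth$class %in%
                                       c("specific_down", "specific_up")])
  expect_identical(sort(sel$gene), spec_truth)
  # direction matches implanted direction
  tr <- b$truth[match(sel$gene, b$truth$gene_id), ]
  expect_identical(sel$direction,
                   ifelse(tr$class == "specific_down", "under", "over"))
  # relaxing any threshold never shrinks the set
  relaxed <- select_specific(de, cross, rates, fdr = 0.01,
                             cross_fdr = 0.01, rate_low = 0.95,
                             rate_high = 1.01)
  expect_true(all(sel$gene %in% relaxed$gene))
})

test_that("selection threshold logic excludes near-misses", {
  de <- data.frame(gene = c("a", "b", "c"),
                   q_status = c(0.0005, 0.0005, 0.5))
  cross <- data.frame(gene = c("a", "b", "c"),
                      q_cohort = c(0.0005, 0.0005, 0.0005))
  rates <- data.frame(gene = c("a", "b", "c"),
                      rate = c(0.8, 0.95, 0.7),
                      direction = c("under", "under", "under"))
  sel <- select_specific(de, cross, rates)
  expect_identical(sel$gene, "a")  # b fails rate, c fails FDR
  # empty DE set stays a valid empty report
  sel0 <- select_specific(de, cross, rates, fdr = 1e-9,
                          cross_fdr = 1e-9)
  expect_equal(nrow(sel0), 0)
  expect_equal(attr(sel0, "counts")$n_selected, 0)
  # misaligned tables error
  expect_error(select_specific(de[c(2, 1, 3), ], cross, rates),
               "aligned")
})
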