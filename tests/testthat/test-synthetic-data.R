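test_that("default bundle honours the design and count contracts", {
  cfg <- generator_config(seed = 42)
  b <- generate_microarray(cfg)
  expect_identical(dim(b$G), c(2000L, 80L))
  expect_identical(dim(b$R), dim(b$G))
  expect_true(all(is.finite(b$G)) && all(b$G > 0))
  expect_true(all(is.finite(b$R)) && all(b$R > 0))
  # every couple: one patient + one control, two arrays each
  per_subj <- table(b$design$subject_id)
  expect_true(all(per_subj == 2))
  roles <- tapply(b$design$role, paste(b$design$cohort, b$design$couple_id),
                  function(r) length(unique(r)))
  expect_true(all(roles == 2))
  cls <- table(b$truth$class)
  expect_equal(unname(cls[["specific_down"]] + cls[["specific_up"]]), 70)
  expect_equal(unname(cls[["specific_up"]]), 3)
  expect_equal(sum(cls[c("shared_de", "specific_down", "specific_up")]), 253)
  expect_equal(unname(cls[["stress"]]), 150)
  expect_true(all(b$truth$implanted_shift[b$truth$class == "null"] == 0))
})

test_that("noise-free corrected log-value ratios equal implanted rates", {
  b <- noise_free_bundle()
  C <- corrected_from(b)
  rates <- expression_rate(C, b$design, cohort = "EIF2B")
  spec <- b$truth$class %in% c("specific_down", "specific_up")
  expect_equal(rates$rate[spec], b$truth$implanted_rate[spec],
               tolerance = 1e-10)
})

test_that("different seeds change values but not the truth composition", {
  b1 <- generate_microarray(generator_config(n_genes = 300,
                                             n_de_total = 40,
                                             n_specific = 10,
                                             n_stress_genes = 20,
                                             seed = 1))
  b2 <- generate_microarray(generator_config(n_genes = 300,
                                             n_de_total = 40,
                                             n_specific = 10,
                                             n_stress_genes = 20,
                                             seed = 2))
  expect_false(identical(b1$G, b2$G))
  expect_identical(table(b1$truth$class), table(b2$truth$class))
  # identical seed reproduces byte-identical written output
  d1 <- tempfile(); d2 <- tempfile()
  write_bundle(generate_microarray(generator_config(n_genes = 50,
                                                    n_de_total = 10,
                                                    n_specific = 4,
                                                    n_stress_genes = 5,
                                                    seed = 3)), d1)
  write_bundle(generate_microarray(generator_config(n_genes = 50,
                                                    n_de_total = 10,
                                                    n_specific = 4,
                                                    n_stress_genes = 5,
                                                    seed = 3)), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("generator rejects inconsistent configurations", {
  expect_error(generator_config(n_specific = 300, n_de_total = 253),
               "n_specific")
  expect_error(generator_config(n_genes = 100, n_de_total = 90,
                                n_stress_genes = 50), "exceed")
  expect_error(generator_config(specific_down_rate_interval = c(0.5, 0.95)),
               "0.9")
  expect_error(generator_config(specific_up_rate_interval = c(1.01, 1.02)),
               "1.05")
})

test_that("qPCR panel has the replicate design and log2 Ct identity", {
  b <- noise_free_bundle()
  q <- generate_qpcr_panel(b$truth, b$design, ct_noise_sd = 0, seed = 5)
  # 2 RT x 2 duplicates per (sample, gene)
  reps <- table(paste(q$sample_id, q$gene))
  expect_true(all(reps == 4))
  # a specific gene implanted at fold f: patient Ct - control Ct = -log2(f)
  spec_genes <- intersect(unique(q$gene),
                          b$truth$gene_id[b$truth$class == "specific_down"])
  g <- spec_genes[1]
  f <- b$truth$implanted_rate[b$truth$gene_id == g]
  qq <- q[q$gene == g & q$cohort == "EIF2B" & q$rt_batch == 1 &
            q$replicate == 1 & q$treatment == "vehicle", ]
  dct <- qq$ct[qq$role == "patient"] - qq$ct[qq$role == "control"]
  expect_equal(dct, rep(-log2(f), length(dct)), tolerance = 1e-12)
  expect_error(generate_qpcr_panel(b$truth, b$design,
                                   gene_ids = "NOT_A_GENE"),
               "unknown gene")
})

test_that("B2M within-subject replicate spread matches its sampling law", {
  # Monte-Carlo oracle: P(range of 4 replicates <= 4 sd) ~ 0.976 for
  # normal Ct noise, independently of sd
  set.seed(11)
  n_sim <- 1000
  ok <- replicate(n_sim, {
    x <- rnorm(4, 20, 0.2)
    (max(x) - min(x)) <= 4 * 0.2
  })
  expect_gt(mean(ok), 0.976 - 0.02)
  expect_lt(mean(ok), 0.976 + 0.02)
})

test_that("brain panel censors foetal control PLP and implants folds", {
  cfg <- brain_panel_config(ct_noise_sd = 0)
  p <- generate_brain_panel(cfg, seed = 3)
  fc_plp <- p[p$stage == "foetus" & p$group == "control" &
                p$gene %in% c("PLP", "PLP_DM20"), ]
  expect_true(all(fc_plp$censored))
  expect_true(all(fc_plp$ct == 40))
  # noise-free child GFAP-delta ratio mutated/control = 4.5 exactly
  d <- delta_ct(collapse_replicates(p), "B2M")
  gf <- gfap_metrics(d)
  child <- gf[gf$stage == "child", ]
  expect_equal(mean(child$GFAP_delta[child$group == "mutated"]) /
                 mean(child$GFAP_delta[child$group == "control"]),
               4.5, tolerance = 1e-12)
  # noise-free adult 13-gene panel fold = postnatal fold for all genes
  panel13 <- setdiff(unique(p$gene),
                     c("PLP", "PLP_DM20", "GFAP_pan", "GFAP_alpha",
                       "GFAP_delta", "B2M", "GAPDH", "HPRT"))
  expect_length(panel13, 13)
  ad <- d[d$stage == "adult" & d$gene %in% panel13, ]
  folds <- vapply(panel13, function(g) {
    m <- 2^(-ad$delta_ct[ad$gene == g & ad$group == "mutated"])
    ctl <- 2^(-ad$delta_ct[ad$gene == g & ad$group == "control"])
    mean(m) / mean(ctl)
  }, numeric(1))
  expect_equal(unname(folds), rep(0.6, 13), tolerance = 1e-12)
})

test_that("brain panel config validates group sizes and folds", {
  expect_error(brain_panel_config(group_sizes = list(
    foetus = c(mutated = 0, control = 6),
    child = c(mutated = 7, control = 5),
    adult = c(mutated = 2, control = 3))), ">= 1")
  expect_error(brain_panel_config(plp_postnatal_reduction = -1), "> 0")
})
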