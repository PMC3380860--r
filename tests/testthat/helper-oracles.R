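# Independent oracles used across the suite.

# Least-squares additive-model ANOVA for a single response via aov();
# returns per-factor SS, F and p in the order of `factors`.
anova_lm_oracle <- function(y, factors) {
  dat <- as.data.frame(lapply(factors, factor))
  dat$y <- y
  fit <- stats::aov(stats::reformulate(names(factors), "y"), data = dat)
  sm <- summary(fit)[[1]]
  idx <- seq_along(factors)
  list(ss = sm[idx, "Sum Sq"], F = sm[idx, "F value"],
       p = sm[idx, "Pr(>F)"], ss_resid = sm[length(factors) + 1, "Sum Sq"])
}

# Exact two-sided Mann-Whitney p by full enumeration of all
# choose(n1+n2, n1) group assignments (no ties assumed).
mw_enum_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  idx <- utils::combn(n1 + n2, n1)
  u_all <- apply(idx, 2, function(i) {
    x <- pooled[i]; y <- pooled[-i]
    sum(outer(x, y, ">"))
  })
  u_obs <- sum(outer(a, b, ">"))
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Small noise-free bundle shared by several tests.
noise_free_bundle <- function(n_genes = 120, n_couples = 3, seed = 7) {
  cfg <- generator_config(
    n_genes = n_genes, n_couples_per_cohort = n_couples,
    n_stress_genes = 10, n_de_total = 20, n_specific = 8,
    n_specific_up = 2, noise_sd = 0, array_effect_sd = 0, seed = seed)
  generate_microarray(cfg)
}

# strip dimnames and provenance attributes for value-only comparison
bare <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))

corrected_from <- function(bundle) {
  reference_correct(log_standardize(bundle$G),
                    log_standardize(bundle$R))
}
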