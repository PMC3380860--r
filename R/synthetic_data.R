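# Synthetic study-design emulation: two-channel microarray bundle,
# fibroblast qPCR panel, developmental brain isoform panel, and the
# packaged cohort table.

# Gene symbols attached to the implanted disease-specific genes. The first
# 14 are members of the disease-specific set named in the literature
# (HNRNP family, MBNL, mitochondrial and cytoskeletal genes); the SYNT*
# symbols are synthetic placeholders for the remainder of the 70-gene set,
# whose full membership is not reproduced here.
.specific_symbols <- c(
  "HNRNPH1", "HNRNPC", "HNRNPD", "HNRNPL", "HNRNPU", "HNRNPR",
  "MBNL1", "MBNL2",
  "MRPS26", "MRPL28", "HCCS", "VDAC3",
  "KIF5B", "DIAPH3",
  sprintf("SYNT%02d", seq_len(56))
)

# Default qPCR validation panel (fibroblasts): named members of the
# specific set used for cross-platform concordance.
.default_qpcr_panel <- c(
  "HNRNPH1", "HNRNPL", "HNRNPC", "HNRNPD", "MRPS26", "MRPL28",
  "HCCS", "VDAC3", "KIF5B", "DIAPH3"
)

# 13-gene brain panel: the fibroblast panel plus the remaining HNRNP
# members and MBNL1.
.default_brain_panel <- c(
  "HNRNPH1", "HNRNPL", "HNRNPC", "HNRNPD", "HNRNPU", "HNRNPR",
  "MRPS26", "MRPL28", "HCCS", "VDAC3", "KIF5B", "DIAPH3", "MBNL1"
)

#' Configuration for the synthetic microarray generator
#'
#' Builds and validates the parameter set describing the simulated
#' matched-couple dual-cohort two-channel microarray experiment: two
#' cohorts (EIF2B-mutated and other-leukodystrophy patients), each with
#' matched patient/control couples, every subject assayed under an
#' ER-stress treatment (thapsigargin) and vehicle.
#'
#' Implanted effect classes: `shared_de` genes are shifted in the
#' patients of both cohorts; `specific_down`/`specific_up` genes are
#' shifted only in EIF2B patients, with the shift chosen on the
#' corrected-log-value-ratio scale so that the expected patient/control
#' ratio of corrected log values equals the implanted rate; `stress`
#' genes respond identically in every group under thapsigargin.
#'
#' @param n_genes number of genes on the array.
#' @param n_couples_per_cohort matched patient/control couples per cohort.
#' @param n_stress_genes genes carrying a treatment (ER-stress) response.
#' @param n_de_total genes differentially expressed patient vs control in
#'   the EIF2B cohort (shared plus specific).
#' @param n_specific genes deregulated only in the EIF2B cohort.
#' @param n_specific_up specific genes that are over-expressed.
#' @param baseline_log_mean,baseline_log_sd per-gene baseline natural-log
#'   intensity distribution.
#' @param specific_down_rate_interval,specific_up_rate_interval intervals
#'   from which implanted corrected-log-value ratios are drawn; the down
#'   interval must lie strictly below 0.9 and the up interval at or above
#'   1.05 so implanted genes pass the selection thresholds at low noise.
#' @param shared_de_shift log-intensity shift applied to `shared_de`
#'   genes in the patients of both cohorts.
#' @param stress_shift_sd standard deviation of per-gene stress shifts.
#' @param noise_sd per-observation log-intensity noise (both channels).
#' @param array_effect_sd standard deviation of per-array log offsets.
#' @param seed master seed for the generator.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 2000,
                             n_couples_per_cohort = 10,
                             n_stress_genes = 150,
                             n_de_total = 253,
                             n_specific = 70,
                             n_specific_up = 3,
                             baseline_log_mean = 8.0,
                             baseline_log_sd = 1.5,
                             specific_down_rate_interval = c(0.66, 0.88),
                             specific_up_rate_interval = c(1.06, 1.07),
                             shared_de_shift = -0.6,
                             stress_shift_sd = 0.5,
                             noise_sd = 0.05,
                             array_effect_sd = 0.1,
                             seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_couples_per_cohort = as.integer(n_couples_per_cohort),
    n_stress_genes = as.integer(n_stress_genes),
    n_de_total = as.integer(n_de_total),
    n_specific = as.integer(n_specific),
    n_specific_up = as.integer(n_specific_up),
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    specific_down_rate_interval = specific_down_rate_interval,
    specific_up_rate_interval = specific_up_rate_interval,
    shared_de_shift = shared_de_shift,
    stress_shift_sd = stress_shift_sd,
    noise_sd = noise_sd,
    array_effect_sd = array_effect_sd,
    seed = as.integer(seed)
  )
  if (cfg$n_specific > cfg$n_de_total)
    stop("n_specific must not exceed n_de_total")
  if (cfg$n_de_total + cfg$n_stress_genes > cfg$n_genes)
    stop("implanted gene counts exceed n_genes")
  if (cfg$n_specific_up > cfg$n_specific)
    stop("n_specific_up must not exceed n_specific")
  if (length(cfg$specific_down_rate_interval) != 2 ||
      any(cfg$specific_down_rate_interval >= 0.9) ||
      any(cfg$specific_down_rate_interval <= 0))
    stop("specific_down_rate_interval must lie strictly within (0, 0.9)")
  if (length(cfg$specific_up_rate_interval) != 2 ||
      any(cfg$specific_up_rate_interval < 1.05))
    stop("specific_up_rate_interval must lie at or above 1.05")
  if (cfg$noise_sd < 0 || cfg$array_effect_sd < 0)
    stop("noise parameters must be non-negative")
  class(cfg) <- "generator_config"
  cfg
}

# Sample design sheet: one row per array.
.make_design <- function(n_couples) {
  grid <- expand.grid(
    treatment = c("thapsigargin", "vehicle"),
    role = c("patient", "control"),
    couple_id = sprintf("c%02d", seq_len(n_couples)),
    cohort = c("EIF2B", "OL"),
    stringsAsFactors = FALSE
  )
  grid <- grid[, c("cohort", "couple_id", "role", "treatment")]
  grid$subject_id <- paste(grid$cohort, grid$couple_id,
                           substr(grid$role, 1, 3), sep = "_")
  grid$sample_id <- paste(grid$subject_id,
                          substr(grid$treatment, 1, 5), sep = "_")
  grid[, c("sample_id", "subject_id", "cohort", "couple_id",
           "role", "treatment")]
}

#' Generate a synthetic two-channel microarray bundle
#'
#' Simulates sample-channel (G) and pooled-reference-channel (R)
#' intensity matrices over the full dual-cohort matched-couple design,
#' together with the design sheet and a ground-truth table recording the
#' implanted class, shift and expected corrected-log-value ratio of every
#' gene. Log intensities are
#' `baseline + array effect + class shift + stress shift + noise`,
#' exponentiated; the reference channel shares the baseline and array
#' effect (the pooled control reference is co-hybridized on each slide)
#' but carries none of the disease or stress shifts.
#'
#' @param config a [generator_config()].
#' @return a list of class `microarray_bundle` with elements `G`, `R`
#'   (gene-by-array intensity matrices), `design` (data frame) and
#'   `truth` (data frame with `gene_id`, `class`, `implanted_shift`,
#'   `implanted_rate`).
#' @export
generate_microarray <- function(config) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  set.seed(config$seed)
  ng <- config$n_genes
  design <- .make_design(config$n_couples_per_cohort)
  na <- nrow(design)

  gene_id <- sprintf("g%04d", seq_len(ng))
  # baseline log intensities; redraw the rare values below 2 so that
  # rate = (baseline + shift)/baseline stays a meaningful positive ratio
  baseline <- rnorm(ng, config$baseline_log_mean, config$baseline_log_sd)
  while (any(bad <- baseline < 2))
    baseline[bad] <- rnorm(sum(bad), config$baseline_log_mean,
                           config$baseline_log_sd)

  # class assignment
  cls <- rep("null", ng)
  n_shared <- config$n_de_total - config$n_specific
  picked <- sample.int(ng, config$n_specific + n_shared +
                         config$n_stress_genes)
  spec_idx <- picked[seq_len(config$n_specific)]
  shared_idx <- picked[config$n_specific + seq_len(n_shared)]
  stress_idx <- picked[config$n_specific + n_shared +
                         seq_len(config$n_stress_genes)]
  up_local <- if (config$n_specific_up > 0)
    sample.int(config$n_specific, config$n_specific_up) else integer(0)
  cls[spec_idx] <- "specific_down"
  cls[spec_idx[up_local]] <- "specific_up"
  cls[shared_idx] <- "shared_de"
  cls[stress_idx] <- "stress"

  # symbols for the specific set (recycled panel if n_specific > 70)
  syms <- rep_len(.specific_symbols, config$n_specific)
  if (config$n_specific > length(.specific_symbols))
    syms <- make.unique(syms)
  gene_id[spec_idx] <- syms

  # implanted rates and shifts (corrected-log-value-ratio scale)
  rate <- rep(1, ng)
  rate[cls == "specific_down"] <-
    runif(sum(cls == "specific_down"),
          config$specific_down_rate_interval[1],
          config$specific_down_rate_interval[2])
  rate[cls == "specific_up"] <-
    runif(sum(cls == "specific_up"),
          config$specific_up_rate_interval[1],
          config$specific_up_rate_interval[2])
  shift <- numeric(ng)
  is_spec <- cls %in% c("specific_down", "specific_up")
  shift[is_spec] <- baseline[is_spec] * (rate[is_spec] - 1)
  shift[cls == "shared_de"] <- config$shared_de_shift
  rate[cls == "shared_de"] <-
    (baseline[cls == "shared_de"] + config$shared_de_shift) /
    baseline[cls == "shared_de"]
  stress_shift <- numeric(ng)
  stress_shift[cls == "stress"] <-
    rnorm(sum(cls == "stress"), 0, config$stress_shift_sd)

  array_eff <- rnorm(na, 0, config$array_effect_sd)
  is_patient <- design$role == "patient"
  is_eif2b_pat <- is_patient & design$cohort == "EIF2B"
  is_thaps <- design$treatment == "thapsigargin"

  L <- matrix(baseline, ng, na) +
    matrix(array_eff, ng, na, byrow = TRUE)
  # disease shifts
  shared_col <- as.numeric(is_patient)
  spec_col <- as.numeric(is_eif2b_pat)
  shift_shared <- ifelse(cls == "shared_de", shift, 0)
  shift_spec <- ifelse(is_spec, shift, 0)
  L <- L + outer(shift_shared, shared_col) + outer(shift_spec, spec_col)
  L <- L + outer(stress_shift, as.numeric(is_thaps))
  L <- L + matrix(rnorm(ng * na, 0, config$noise_sd), ng, na)

  Rlog <- matrix(baseline, ng, na) +
    matrix(array_eff, ng, na, byrow = TRUE) +
    matrix(rnorm(ng * na, 0, config$noise_sd), ng, na)

  G <- exp(L)
  R <- exp(Rlog)
  dimnames(G) <- dimnames(R) <- list(gene_id, design$sample_id)

  truth <- data.frame(
    gene_id = gene_id,
    class = cls,
    implanted_shift = shift,
    implanted_rate = rate,
    stress_shift = stress_shift,
    stringsAsFactors = FALSE
  )
  out <- list(G = G, R = R, design = design, truth = truth,
              config = config)
  class(out) <- "microarray_bundle"
  out
}

#' @export
print.microarray_bundle <- function(x, ...) {
  cat("Synthetic two-channel microarray bundle\n")
  cat(sprintf("  %d genes x %d arrays (%d couples per cohort)\n",
              nrow(x$G), ncol(x$G), x$config$n_couples_per_cohort))
  cat("  implanted classes:",
      paste(sprintf("%s=%d", names(table(x$truth$class)),
                    table(x$truth$class)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic fibroblast qPCR panel
#'
#' Emits a long-format replicate-level Ct table for a panel of genes over
#' the fibroblast study design: both cohorts, matched couples, both
#' treatments, two independent reverse-transcription batches and two PCR
#' duplicates per RT. The Ct model is
#' `Ct = ct0_gene - log2(relative expression) + noise`, so a gene
#' implanted at fold f satisfies `Ct_patient - Ct_control = -log2(f)` up
#' to noise. The reference gene B2M is constant across subjects up to
#' noise. Genes shifted only in the EIF2B cohort (classes
#' `specific_down`/`specific_up`) are applied in EIF2B patients only;
#' `shared_de` genes in the patients of both cohorts.
#'
#' @param truth the `truth` table of a [generate_microarray()] bundle.
#' @param design the matching design sheet.
#' @param gene_ids panel genes (must be present in `truth`); defaults to
#'   the built-in 10-gene validation panel intersected with `truth`.
#' @param ct_noise_sd replicate Ct noise in cycles.
#' @param censor_ct detection limit in cycles.
#' @param seed RNG seed for this table.
#' @return data frame with columns `sample_id`, `cohort`, `couple_id`,
#'   `role`, `treatment`, `gene`, `rt_batch`, `replicate`, `ct`,
#'   `censored`.
#' @export
generate_qpcr_panel <- function(truth, design, gene_ids = NULL,
                                ct_noise_sd = 0.2, censor_ct = 40,
                                seed = 1L) {
  if (is.null(gene_ids))
    gene_ids <- intersect(.default_qpcr_panel, truth$gene_id)
  unknown <- setdiff(gene_ids, truth$gene_id)
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  genes <- c(gene_ids, "B2M")
  ct0 <- c(runif(length(gene_ids), 22, 30), 20)
  names(ct0) <- genes

  samples <- unique(design[, c("sample_id", "cohort", "couple_id",
                               "role", "treatment")])
  grid <- expand.grid(
    replicate = 1:2, rt_batch = 1:2, gene = genes,
    sample_id = samples$sample_id,
    stringsAsFactors = FALSE
  )
  grid <- merge(grid, samples, by = "sample_id", sort = FALSE)

  tr <- truth[match(grid$gene, truth$gene_id), ]
  fold <- rep(1, nrow(grid))
  is_pat <- grid$role == "patient"
  spec <- tr$class %in% c("specific_down", "specific_up") &
    grid$cohort == "EIF2B" & is_pat
  shared <- !is.na(tr$class) & tr$class == "shared_de" & is_pat
  fold[spec] <- tr$implanted_rate[spec]
  fold[shared] <- tr$implanted_rate[shared]

  ct <- ct0[grid$gene] - log2(fold) +
    rnorm(nrow(grid), 0, ct_noise_sd)
  censored <- ct > censor_ct
  ct[censored] <- censor_ct
  out <- data.frame(
    sample_id = grid$sample_id, cohort = grid$cohort,
    couple_id = grid$couple_id, role = grid$role,
    treatment = grid$treatment, gene = grid$gene,
    rt_batch = grid$rt_batch, replicate = grid$replicate,
    ct = as.numeric(ct), censored = censored,
    stringsAsFactors = FALSE
  )
  out[order(out$sample_id, out$gene, out$rt_batch, out$replicate), ,
      drop = FALSE]
}

#' Configuration for the synthetic brain isoform panel
#'
#' Group sizes per developmental stage default to the autopsy roster of
#' the study design (2 mutated / 6 control foetuses, 7/5 children,
#' 2/3 adults; the child control group is enlarged from the literal 3 to
#' give the rank test usable resolution and is configurable back).
#' Disease effects are stage-specific fold changes: GFAP-delta
#' up-regulation (2, 4.5 and 7 fold in foetus, child, adult), a
#' post-natal PLP-family reduction, a foetal increase of the
#' PLP+DM20/PLP ratio, and foetal over- / post-natal under-expression of
#' the 13-gene panel.
#'
#' @param group_sizes named list `foetus`, `child`, `adult`, each
#'   `c(mutated=, control=)`.
#' @param gfap_delta_fold named numeric, GFAP-delta mutated/control fold
#'   per stage.
#' @param plp_postnatal_reduction fold applied to PLP and PLP+DM20 in
#'   post-natal mutated brains.
#' @param foetal_dm20_ratio_increase factor by which the foetal mutated
#'   PLP+DM20/PLP ratio exceeds the baseline ratio.
#' @param selected_gene_foetal_fold,selected_gene_postnatal_fold fold of
#'   the 13-gene panel in mutated brains, foetal and post-natal.
#' @param ct_noise_sd replicate Ct noise in cycles.
#' @param censor_ct detection limit in cycles.
#' @return list of class `brain_panel_config`.
#' @export
brain_panel_config <- function(group_sizes = list(
                                 foetus = c(mutated = 2, control = 6),
                                 child = c(mutated = 7, control = 5),
                                 adult = c(mutated = 2, control = 3)),
                               gfap_delta_fold = c(foetus = 2.0,
                                                   child = 4.5,
                                                   adult = 7.0),
                               plp_postnatal_reduction = 0.3,
                               foetal_dm20_ratio_increase = 2.0,
                               selected_gene_foetal_fold = 1.5,
                               selected_gene_postnatal_fold = 0.6,
                               ct_noise_sd = 0.2,
                               censor_ct = 40) {
  cfg <- list(group_sizes = group_sizes,
              gfap_delta_fold = gfap_delta_fold,
              plp_postnatal_reduction = plp_postnatal_reduction,
              foetal_dm20_ratio_increase = foetal_dm20_ratio_increase,
              selected_gene_foetal_fold = selected_gene_foetal_fold,
              selected_gene_postnatal_fold = selected_gene_postnatal_fold,
              ct_noise_sd = ct_noise_sd,
              censor_ct = censor_ct)
  stages <- c("foetus", "child", "adult")
  if (!all(stages %in% names(cfg$group_sizes)))
    stop("group_sizes must name foetus, child and adult")
  if (any(unlist(cfg$group_sizes) < 1))
    stop("group sizes must be >= 1")
  if (!all(stages %in% names(cfg$gfap_delta_fold)))
    stop("gfap_delta_fold must name foetus, child and adult")
  folds <- c(unlist(cfg$gfap_delta_fold), cfg$plp_postnatal_reduction,
             cfg$foetal_dm20_ratio_increase,
             cfg$selected_gene_foetal_fold,
             cfg$selected_gene_postnatal_fold)
  if (any(folds <= 0)) stop("fold parameters must be > 0")
  class(cfg) <- "brain_panel_config"
  cfg
}

# Control-brain relative expressions (2^-DeltaCt units vs B2M) per stage.
# PLP family is below the detection limit in control foetal brain; GFAP
# peaks in childhood and declines in the adult.
.brain_base_expr <- function(stage) {
  base <- switch(stage,
    foetus = c(PLP = 2^-25, dm20_ratio = 1.5,
               GFAP_pan = 2^-8, GFAP_alpha = 0.8 * 2^-8,
               GFAP_delta = 0.1 * 2^-8, panel = 2^-5),
    child = c(PLP = 2^-2, dm20_ratio = 1.5,
              GFAP_pan = 2^-3, GFAP_alpha = 0.8 * 2^-3,
              GFAP_delta = 0.1 * 2^-3, panel = 2^-5),
    adult = c(PLP = 2^-3, dm20_ratio = 1.5,
              GFAP_pan = 2^-5, GFAP_alpha = 0.8 * 2^-5,
              GFAP_delta = 0.1 * 2^-5, panel = 2^-5)
  )
  base
}

#' Generate a synthetic developmental brain isoform panel
#'
#' Long-format replicate-level Ct table (2 RT batches x 2 duplicates) for
#' PLP, PLP+DM20, pan-GFAP, GFAP-alpha, GFAP-delta, the 13-gene panel and
#' the reference genes B2M, GAPDH and HPRT, over foetal, child and adult
#' brains of control and eIF2B-mutated donors. Control foetal PLP-family
#' transcripts sit below the detection limit and are censored at
#' `censor_ct`; foetal mutated brains are detectable with an elevated
#' PLP+DM20/PLP ratio.
#'
#' @param config a [brain_panel_config()].
#' @param seed RNG seed.
#' @return data frame with columns `sample_id`, `group`, `stage`, `gene`,
#'   `rt_batch`, `replicate`, `ct`, `censored`.
#' @export
generate_brain_panel <- function(config = brain_panel_config(),
                                 seed = 1L) {
  if (!inherits(config, "brain_panel_config"))
    config <- do.call(brain_panel_config, config)
  set.seed(seed)
  stages <- c("foetus", "child", "adult")
  panel13 <- .default_brain_panel
  rows <- list()
  for (st in stages) {
    sizes <- config$group_sizes[[st]]
    base <- .brain_base_expr(st)
    for (grp in c("control", "mutated")) {
      n <- sizes[[grp]]
      for (i in seq_len(n)) {
        sid <- sprintf("%s_%s_%02d", st, grp, i)
        mut <- grp == "mutated"
        expr <- c()
        plp <- base[["PLP"]]
        ratio <- base[["dm20_ratio"]]
        if (mut && st == "foetus") {
          plp <- 2^-12  # detectable, still far below post-natal levels
          ratio <- ratio * config$foetal_dm20_ratio_increase
        }
        if (mut && st != "foetus")
          plp <- plp * config$plp_postnatal_reduction
        expr["PLP"] <- plp
        expr["PLP_DM20"] <- plp * ratio
        delta_fold <- if (mut) config$gfap_delta_fold[[st]] else 1
        expr["GFAP_pan"] <- base[["GFAP_pan"]]
        expr["GFAP_alpha"] <- base[["GFAP_alpha"]]
        expr["GFAP_delta"] <- base[["GFAP_delta"]] * delta_fold
        gene_fold <- if (!mut) 1 else if (st == "foetus")
          config$selected_gene_foetal_fold else
          config$selected_gene_postnatal_fold
        expr[panel13] <- base[["panel"]] * gene_fold
        ct_target <- 20 - log2(expr)
        ct_ref <- c(B2M = 20, GAPDH = 18, HPRT = 24)
        cts <- c(ct_target, ct_ref)
        for (g in names(cts)) {
          for (rt in 1:2) for (rep_i in 1:2) {
            ct <- cts[[g]] + rnorm(1, 0, config$ct_noise_sd)
            cens <- ct > config$censor_ct
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sid, group = grp, stage = st, gene = g,
              rt_batch = rt, replicate = rep_i,
              ct = if (cens) config$censor_ct else ct,
              censored = cens, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

# ---- cohort fixture -------------------------------------------------------

# Parse a printed age string ("2.3 y", "13 m", "10 d", "At birth", "NA",
# decimal commas allowed) into years.
.parse_age_years <- function(x) {
  x <- trimws(x)
  x[is.na(x)] <- "NA"
  out <- rep(NA_real_, length(x))
  out[tolower(x) == "at birth"] <- 0
  num <- gsub(",", ".", x)
  m <- regmatches(num, regexec("^([0-9]+\\.?[0-9]*)\\s*([ymd])$", num))
  for (i in seq_along(m)) {
    if (length(m[[i]]) == 3) {
      v <- as.numeric(m[[i]][2])
      out[i] <- switch(m[[i]][3], y = v, m = v / 12, d = v / 365)
    }
  }
  bad <- is.na(out) & !(x %in% c("NA", "")) & tolower(x) != "at birth"
  if (any(bad))
    stop("unparseable age value(s): ", paste(x[bad], collapse = ", "))
  out
}

#' Load the packaged fibroblast cohort table
#'
#' Reads the packaged transcription of the study cohort table (10
#' eIF2B-related-disorder patients and 10 patients with other
#' leukodystrophies, each with a sex- and age-matched control) and
#' converts the printed onset ages, disease durations and biopsy ages to
#' years (`"6 m"` becomes 0.5, `"10 d"` becomes 10/365, `"At birth"`
#' becomes 0, `"NA"` becomes missing).
#'
#' @param path fixture path; defaults to the file shipped with the
#'   package.
#' @return data frame with columns `patient_id`, `disease_type`, `group`
#'   (`ERD` or `OL`), `onset_age`, `duration`, `gender`, `biopsy_age`
#'   (ages in years).
#' @export
load_cohort_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cohort_table1.tsv",
                        package = "specifex")
  if (!nzchar(path) || !file.exists(path))
    stop("cohort fixture not found")
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("patient_id", "disease_type", "onset_age", "duration",
            "gender", "biopsy_age")
  if (!all(need %in% names(raw)))
    stop("malformed cohort fixture: missing column(s) ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  data.frame(
    patient_id = raw$patient_id,
    disease_type = raw$disease_type,
    group = ifelse(raw$disease_type == "ERD", "ERD", "OL"),
    onset_age = .parse_age_years(raw$onset_age),
    duration = .parse_age_years(raw$duration),
    gender = raw$gender,
    biopsy_age = .parse_age_years(raw$biopsy_age),
    stringsAsFactors = FALSE
  )
}

#' Descriptive summary of a cohort field
#'
#' Arithmetic mean, sample standard deviation and range of a numeric
#' field within a cohort group, excluding missing values.
#'
#' @param table a cohort table from [load_cohort_fixture()].
#' @param group `"ERD"` or `"OL"`.
#' @param field numeric column name (e.g. `"onset_age"`).
#' @return named list `mean`, `sd`, `min`, `max`, `n`.
#' @export
summarize_cohort <- function(table, group, field) {
  x <- table[[field]][table$group == group]
  x <- x[!is.na(x)]
  if (length(x) < 2)
    stop("insufficient data: fewer than 2 non-missing values")
  list(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
       n = length(x))
}

# ---- TSV interface --------------------------------------------------------

#' Write a simulation bundle to TSV files
#'
#' Writes `intensities_G.tsv`, `intensities_R.tsv` (gene_id plus one
#' column per array), `design.tsv` and `truth.tsv` under `dir`.
#'
#' @param bundle a `microarray_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(M, f) {
    df <- data.frame(gene_id = rownames(M), M, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wm(bundle$G, "intensities_G.tsv")
  wm(bundle$R, "intensities_R.tsv")
  utils::write.table(bundle$design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an intensity matrix written by [write_bundle()]
#'
#' @param path TSV with a `gene_id` column followed by array columns.
#' @return numeric matrix with gene ids as row names.
#' @export
read_intensity_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}
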