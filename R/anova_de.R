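# Gene-wise multi-factor additive ANOVA, FDR control, expression rates
# and dual-cohort specificity selection.

#' Gene-wise additive ANOVA
#'
#' Fits, for every gene at once, the additive (no-interaction) fixed
#' effects model over the declared factors and returns per-factor sums
#' of squares, F statistics and p-values. For a balanced complete design
#' the factor subspaces are orthogonal, so each factor's sum of squares
#' is computed from its level means
#' (`SS_f = sum_l n_l (mean_l - grand_mean)^2`) and the residual is the
#' total minus the factor sums. Unbalanced designs are rejected unless
#' `allow_unbalanced = TRUE`, in which case Type-I (sequential) sums of
#' squares in the order of `factors` are used.
#'
#' Genes with zero variance across arrays are reported with `F = 0`,
#' `p = 1` for every factor (conservative convention, counted in a
#' message). A factor effect sitting on a zero residual yields
#' `F = Inf`, `p = 0`.
#'
#' @param C gene-by-array matrix of corrected log values.
#' @param factors data frame with one row per array (aligned with the
#'   columns of `C`) and one column per factor.
#' @param allow_unbalanced fall back to sequential sums of squares for
#'   unbalanced designs.
#' @return data frame with one row per gene: `gene`, then for each
#'   factor `ss_<f>`, `F_<f>`, `p_<f>`, plus `ss_resid`. Degrees of
#'   freedom are attached as attribute `df`.
#' @export
genewise_anova <- function(C, factors, allow_unbalanced = FALSE) {
  if (!is.matrix(C)) C <- as.matrix(C)
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (nrow(factors) != ncol(C))
    stop("factors must have one row per array")
  factors[] <- lapply(factors, function(x) factor(as.character(x)))
  n <- ncol(C)
  counts <- table(do.call(interaction, c(factors, drop = FALSE)))
  balanced <- length(unique(as.integer(counts))) == 1 && all(counts > 0)
  if (!balanced && !allow_unbalanced)
    stop("design is not balanced/complete; set allow_unbalanced = TRUE ",
         "for Type-I sequential sums of squares")

  gm <- rowMeans(C)
  total_ss <- rowSums((C - gm)^2)
  fnames <- names(factors)
  df_f <- vapply(factors, function(f) nlevels(f) - 1L, integer(1))
  df_res <- n - 1L - sum(df_f)
  if (df_res <= 0) stop("no residual degrees of freedom")

  ss <- matrix(NA_real_, nrow(C), length(fnames),
               dimnames = list(NULL, fnames))
  if (balanced) {
    for (f in fnames) {
      Z <- stats::model.matrix(~ 0 + factors[[f]])
      nl <- colSums(Z)
      Mns <- (C %*% Z) / matrix(nl, nrow(C), length(nl), byrow = TRUE)
      ss[, f] <- rowSums(sweep((Mns - gm)^2, 2, nl, "*"))
    }
  } else {
    message("genewise_anova: unbalanced design, using Type-I sequential ",
            "sums of squares in factor order ",
            paste(fnames, collapse = ", "))
    rss_prev <- total_ss
    dat <- factors
    for (k in seq_along(fnames)) {
      X <- stats::model.matrix(
        stats::reformulate(fnames[seq_len(k)]), dat)
      qrX <- qr(X)
      rss_k <- colSums(qr.resid(qrX, t(C))^2)
      ss[, k] <- rss_prev - rss_k
      rss_prev <- rss_k
    }
    df_res <- n - qr(stats::model.matrix(
      stats::reformulate(fnames), dat))$rank
  }
  ss_resid <- pmax(total_ss - rowSums(ss), 0)
  # clamp floating-point dust to exact zero so that effects that are
  # zero up to rounding never produce spurious F ratios
  ss_floor <- n * (1e-9 * pmax(rowMeans(abs(C)), 1))^2
  ss[ss < ss_floor] <- 0
  ss_resid[ss_resid < ss_floor] <- 0
  neg <- total_ss - rowSums(ss) < -1e-8 * pmax(total_ss, 1)
  if (any(neg))
    warning("additive decomposition exceeded total SS for ", sum(neg),
            " gene(s)")

  zerovar <- total_ss <= 1e-12 * pmax(abs(gm), 1)^2
  if (any(zerovar))
    message("genewise_anova: ", sum(zerovar),
            " zero-variance gene(s) reported as F = 0, p = 1")

  out <- data.frame(gene = rownames(C) %||% seq_len(nrow(C)),
                    stringsAsFactors = FALSE)
  ms_res <- ss_resid / df_res
  for (f in fnames) {
    Fv <- (ss[, f] / df_f[[f]]) / ms_res
    Fv[ms_res == 0 & ss[, f] > 0] <- Inf
    Fv[ms_res == 0 & ss[, f] <= 0] <- 0
    Fv[zerovar] <- 0
    p <- stats::pf(Fv, df_f[[f]], df_res, lower.tail = FALSE)
    p[zerovar] <- 1
    out[[paste0("ss_", f)]] <- ss[, f]
    out[[paste0("F_", f)]] <- Fv
    out[[paste0("p_", f)]] <- p
  }
  out$ss_resid <- ss_resid
  attr(out, "df") <- c(as.list(df_f), list(resid = df_res))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate q-values; a thin, order-preserving
#' wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
fdr_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Case-versus-control ANOVA for one cohort
#'
#' Convenience wrapper: subsets the arrays of one cohort and runs the
#' three-factor model (disease status, couple, treatment), then appends
#' BH q-values for the status factor as `q_status`.
#'
#' @param C corrected gene-by-array matrix.
#' @param design design sheet (see [generate_microarray()]).
#' @param cohort cohort label, e.g. `"EIF2B"` or `"OL"`.
#' @return [genewise_anova()] table with an extra `q_status` column.
#' @export
anova_case_control <- function(C, design, cohort) {
  keep <- design$cohort == cohort
  if (!any(keep)) stop("no arrays in cohort ", cohort)
  tab <- genewise_anova(
    C[, design$sample_id[keep], drop = FALSE],
    data.frame(status = design$role[keep],
               couple = design$couple_id[keep],
               treatment = design$treatment[keep]))
  tab$q_status <- fdr_adjust(tab$p_status)
  tab
}

#' Cross-cohort ANOVA over patient arrays
#'
#' Two-factor model (cohort membership, treatment) fitted on the patient
#' arrays of both cohorts; couple-to-couple variability is absorbed into
#' the residual. Appends BH q-values for the cohort factor as
#' `q_cohort`.
#'
#' @inheritParams anova_case_control
#' @return [genewise_anova()] table with an extra `q_cohort` column.
#' @export
anova_cross_cohort <- function(C, design) {
  keep <- design$role == "patient"
  tab <- genewise_anova(
    C[, design$sample_id[keep], drop = FALSE],
    data.frame(cohort = design$cohort[keep],
               treatment = design$treatment[keep]))
  tab$q_cohort <- fdr_adjust(tab$p_cohort)
  tab
}

#' Per-gene expression rates over matched couples
#'
#' For every gene: within each couple and treatment, the ratio of the
#' patient's corrected log value to the matched control's; the two
#' treatment conditions are averaged per couple, then couples are
#' averaged into the mean expression rate. Direction is `under` for
#' rate < 1, `over` for rate > 1, `neutral` at 1.
#'
#' @param C corrected gene-by-array matrix.
#' @param design design sheet.
#' @param cohort optional cohort restriction.
#' @return data frame `gene`, `rate`, `direction`, `n_couples`; the
#'   per-couple rate matrix is attached as attribute `per_couple`.
#' @export
expression_rate <- function(C, design, cohort = NULL) {
  if (!is.null(cohort)) design <- design[design$cohort == cohort, ]
  couples <- unique(design$couple_id)
  treatments <- unique(design$treatment)
  per_couple <- matrix(NA_real_, nrow(C), length(couples),
                       dimnames = list(rownames(C), couples))
  dropped <- character(0)
  for (cp in couples) {
    acc <- matrix(NA_real_, nrow(C), length(treatments))
    for (ti in seq_along(treatments)) {
      pat <- design$sample_id[design$couple_id == cp &
                                design$role == "patient" &
                                design$treatment == treatments[ti]]
      ctl <- design$sample_id[design$couple_id == cp &
                                design$role == "control" &
                                design$treatment == treatments[ti]]
      if (length(pat) != 1 || length(ctl) != 1)
        stop("couple ", cp, " is incomplete for treatment ",
             treatments[ti])
      denom <- C[, ctl]
      if (any(denom == 0)) dropped <- c(dropped, cp)
      acc[, ti] <- ifelse(denom == 0, NA_real_, C[, pat] / denom)
    }
    per_couple[, cp] <- rowMeans(acc)
  }
  if (length(dropped))
    warning("zero control corrected value: couple rate(s) excluded for ",
            paste(unique(dropped), collapse = ", "))
  rate <- rowMeans(per_couple, na.rm = TRUE)
  direction <- ifelse(abs(rate - 1) < 1e-12, "neutral",
                      ifelse(rate < 1, "under", "over"))
  out <- data.frame(gene = rownames(C) %||% seq_len(nrow(C)),
                    rate = rate, direction = direction,
                    n_couples = rowSums(!is.na(per_couple)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_couple") <- per_couple
  out
}

#' Select disease-specific genes
#'
#' Intersects the three filters defining the disease-specific set:
#' case-versus-control significance (`q_status <= fdr`), cross-cohort
#' significance (`q_cohort <= cross_fdr`), and an expression-rate
#' threshold (`rate <= rate_low` or `rate >= rate_high`). Counts at each
#' filter stage and the under/over split are attached as attribute
#' `counts`.
#'
#' @param de [anova_case_control()] table for the disease cohort.
#' @param cross [anova_cross_cohort()] table.
#' @param rates [expression_rate()] table for the disease cohort.
#' @param fdr,cross_fdr FDR thresholds (default 0.12\%).
#' @param rate_low,rate_high expression-rate thresholds.
#' @return data frame of class `specific_gene_set` with columns `gene`,
#'   `q_de`, `q_cross`, `rate`, `direction`.
#' @export
select_specific <- function(de, cross, rates,
                            fdr = 0.0012, cross_fdr = 0.0012,
                            rate_low = 0.9, rate_high = 1.05) {
  if (!identical(de$gene, cross$gene) ||
      !identical(de$gene, rates$gene)) {
    off <- union(setdiff(de$gene, cross$gene),
                 setdiff(de$gene, rates$gene))
    stop("tables are not aligned on genes",
         if (length(off)) paste0(": ", paste(utils::head(off, 5),
                                             collapse = ", ")))
  }
  pass_de <- de$q_status <= fdr
  pass_cross <- cross$q_cohort <= cross_fdr
  pass_rate <- rates$rate <= rate_low | rates$rate >= rate_high
  sel <- pass_de & pass_cross & pass_rate
  out <- data.frame(gene = de$gene[sel],
                    q_de = de$q_status[sel],
                    q_cross = cross$q_cohort[sel],
                    rate = rates$rate[sel],
                    direction = rates$direction[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(out$rate), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- list(
    n_genes = length(sel),
    n_de = sum(pass_de),
    n_de_and_cross = sum(pass_de & pass_cross),
    n_selected = sum(sel),
    n_under = sum(out$direction == "under"),
    n_over = sum(out$direction == "over")
  )
  attr(out, "thresholds") <- list(fdr = fdr, cross_fdr = cross_fdr,
                                  rate_low = rate_low,
                                  rate_high = rate_high)
  class(out) <- c("specific_gene_set", "data.frame")
  out
}

#' @export
print.specific_gene_set <- function(x, ...) {
  cnt <- attr(x, "counts")
  thr <- attr(x, "thresholds")
  cat(sprintf(
    "Disease-specific gene set: %d genes (of %d DE at FDR <= %.4g)\n",
    cnt$n_selected, cnt$n_de, thr$fdr))
  if (cnt$n_selected > 0)
    cat(sprintf("  %d under-expressed (%.0f%%), %d over-expressed\n",
                cnt$n_under, 100 * cnt$n_under / cnt$n_selected,
                cnt$n_over))
  NextMethod()
}
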