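# Replicate-level Ct processing, delta-Ct / delta-delta-Ct
# quantification and nonparametric group comparison.

#' Collapse qPCR replicates to mean Ct
#'
#' Averages the uncensored replicate Cts (across RT batches and PCR
#' duplicates) for every `(sample, gene)` pair. Pairs whose replicates
#' are all censored yield a censored record with `mean_ct` at the
#' censoring limit. A replicate spread above `qc_spread` cycles sets a
#' QC flag (the mean is still returned).
#'
#' Metadata columns (`cohort`, `couple_id`, `role`, `treatment`,
#' `group`, `stage`) are carried through when present.
#'
#' @param tab long-format Ct table with columns `sample_id`, `gene`,
#'   `ct`, `censored` (see [generate_qpcr_panel()]).
#' @param qc_spread spread threshold in cycles.
#' @return data frame with `sample_id`, `gene`, metadata, `mean_ct`,
#'   `n_replicates`, `censored`, `qc_flag`.
#' @export
collapse_replicates <- function(tab, qc_spread = 0.5) {
  need <- c("sample_id", "gene", "ct", "censored")
  if (!all(need %in% names(tab)))
    stop("table must have columns ", paste(need, collapse = ", "))
  key <- paste(tab$sample_id, tab$gene, sep = "\r")
  meta_cols <- intersect(c("cohort", "couple_id", "role", "treatment",
                           "group", "stage"), names(tab))
  first <- !duplicated(key)
  out <- tab[first, c("sample_id", "gene", meta_cols), drop = FALSE]
  grp <- match(key, key[first])
  ct_ok <- ifelse(tab$censored, NA_real_, tab$ct)
  mean_ct <- tapply(ct_ok, grp, mean, na.rm = TRUE)
  n_unc <- tapply(!tab$censored, grp, sum)
  spread <- tapply(ct_ok, grp, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else max(x) - min(x)
  })
  all_cens <- n_unc == 0
  cens_ct <- tapply(tab$ct, grp, max)
  out$mean_ct <- as.numeric(ifelse(all_cens, cens_ct, mean_ct))
  out$n_replicates <- as.integer(tapply(tab$ct, grp, length))
  out$censored <- as.logical(all_cens)
  out$qc_flag <- as.numeric(spread) > qc_spread
  if (any(out$qc_flag))
    message("collapse_replicates: ", sum(out$qc_flag),
            " (sample, gene) pair(s) with replicate spread > ",
            qc_spread, " cycles")
  rownames(out) <- NULL
  out
}

#' Delta-Ct against reference gene(s)
#'
#' Computes, per sample, `delta_ct = mean_ct(gene) - reference Ct`. A
#' single reference gene is used directly; multiple references are
#' combined by the arithmetic mean of their Cts (equivalent to
#' normalizing expression by the geometric mean of the reference
#' expressions). Samples whose reference is censored are excluded with
#' a warning. Censored targets keep `censored = TRUE` and a missing
#' `delta_ct`.
#'
#' @param mean_ct output of [collapse_replicates()].
#' @param reference_genes character vector of reference gene names.
#' @return data frame of target genes with `delta_ct` added and the
#'   reference recorded in attribute `reference`.
#' @export
delta_ct <- function(mean_ct, reference_genes = "B2M") {
  samples <- unique(mean_ct$sample_id)
  out <- list()
  for (s in samples) {
    rows <- mean_ct[mean_ct$sample_id == s, , drop = FALSE]
    ref <- rows[rows$gene %in% reference_genes, , drop = FALSE]
    if (nrow(ref) < length(reference_genes))
      stop("reference gene(s) missing for sample ", s)
    if (any(ref$censored)) {
      warning("censored reference for sample ", s, "; sample excluded")
      next
    }
    ref_ct <- mean(ref$mean_ct)
    tgt <- rows[!rows$gene %in% reference_genes, , drop = FALSE]
    tgt$delta_ct <- ifelse(tgt$censored, NA_real_,
                           tgt$mean_ct - ref_ct)
    out[[s]] <- tgt
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(NULL)  # every sample excluded
  rownames(out) <- NULL
  attr(out, "reference") <- reference_genes
  out
}

#' Per-gene expression rate over matched couples (qPCR)
#'
#' Per couple and treatment the relative rate is
#' `2^-(delta_ct_patient - delta_ct_control)`; the treatment conditions
#' are averaged per couple, then couples are averaged into the mean
#' rate. Couples with a censored member are skipped for that gene.
#'
#' @param d a [delta_ct()] table carrying `couple_id`, `role` and
#'   (optionally) `treatment` columns.
#' @return data frame `gene`, `rate`, `n_couples`; per-couple rates are
#'   attached as attribute `per_couple` and per-couple delta-delta-Ct
#'   values (treatment-averaged) as attribute `per_couple_ddct`.
#' @export
couple_expression_rate <- function(d) {
  need <- c("gene", "couple_id", "role", "delta_ct")
  if (!all(need %in% names(d)))
    stop("table must have columns ", paste(need, collapse = ", "))
  if (!"treatment" %in% names(d)) d$treatment <- "all"
  genes <- unique(d$gene)
  couples <- unique(d$couple_id)
  per_couple <- matrix(NA_real_, length(genes), length(couples),
                       dimnames = list(genes, couples))
  per_ddct <- per_couple
  for (g in genes) {
    dg <- d[d$gene == g, , drop = FALSE]
    for (cp in couples) {
      dc <- dg[dg$couple_id == cp, , drop = FALSE]
      vals <- c()
      ddcts <- c()
      for (tr in unique(dc$treatment)) {
        dp <- dc$delta_ct[dc$role == "patient" & dc$treatment == tr]
        dl <- dc$delta_ct[dc$role == "control" & dc$treatment == tr]
        if (length(dp) != 1 || length(dl) != 1 ||
            is.na(dp) || is.na(dl)) next
        ddct <- dp - dl
        vals <- c(vals, 2^(-ddct))
        ddcts <- c(ddcts, ddct)
      }
      if (length(vals)) {
        per_couple[g, cp] <- mean(vals)
        per_ddct[g, cp] <- mean(ddcts)
      }
    }
  }
  skipped <- sum(is.na(per_couple))
  if (skipped > 0)
    message("couple_expression_rate: ", skipped,
            " (gene, couple) rate(s) unavailable (censored or missing)")
  out <- data.frame(gene = genes,
                    rate = rowMeans(per_couple, na.rm = TRUE),
                    n_couples = rowSums(!is.na(per_couple)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "per_couple") <- per_couple
  attr(out, "per_couple_ddct") <- per_ddct
  out
}

#' Per-sample relative expression
#'
#' `2^-delta_ct` per sample; censored (undetectable) targets are
#' reported as expression 0 with the censored flag kept.
#'
#' @param d a [delta_ct()] table.
#' @return input with an `expression` column added.
#' @export
relative_expression <- function(d) {
  d$expression <- ifelse(is.na(d$delta_ct) | d$censored, 0,
                         2^(-d$delta_ct))
  d
}

#' Two-sided Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()]: the exact null distribution is used
#' when both groups are small (`min(n) <= 8`) and there are no ties,
#' otherwise the normal approximation with tie correction. The method
#' used is recorded in the result.
#'
#' @param a,b numeric vectors (each non-empty).
#' @return list `U`, `p`, `method`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("empty group")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && min(length(a), length(b)) <= 8
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approximation")
}
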