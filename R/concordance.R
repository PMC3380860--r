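# Cross-platform validation: per-gene microarray/qPCR correlation,
# discordant-couple exclusion, Fisher-Z comparison of correlations.

#' Correlation between microarray and qPCR per-couple measurements
#'
#' Pearson correlation between the per-couple microarray log ratios
#' (patient/control) and the per-couple qPCR delta-delta-Ct values,
#' aligned on couple identifiers. By default each couple contributes
#' one point (treatment conditions averaged upstream); the chosen
#' convention for `N` is whatever the inputs encode and is the number
#' of aligned pairs.
#'
#' @param micro named numeric vector of per-couple microarray log
#'   ratios.
#' @param qpcr named numeric vector of per-couple delta-delta-Ct
#'   values.
#' @param min_n minimum number of paired observations (default 4, the
#'   smallest N usable by the Fisher-Z comparison).
#' @return list `R`, `R2`, `N`, `zero_variance` (flag; `R` reported as
#'   0 when either vector is constant).
#' @export
cross_platform_correlation <- function(micro, qpcr, min_n = 4) {
  common <- intersect(names(micro), names(qpcr))
  x <- micro[common]
  y <- qpcr[common]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_n)
    stop("fewer than ", min_n, " paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(R = 0, R2 = 0, N = length(x), zero_variance = TRUE))
  R <- stats::cor(x, y)
  list(R = R, R2 = R^2, N = length(x), zero_variance = FALSE)
}

#' Flag couples discordant between platforms
#'
#' A couple is discordant for a gene when the direction of its
#' microarray log ratio disagrees with the direction implied by qPCR
#' (the sign of `-delta_delta_ct`). Couples discordant for at least
#' `k_threshold` of the panel genes are excluded from the global
#' correlation analysis; exclusions are reported, never silent.
#'
#' @param micro_lr gene-by-couple matrix of microarray log ratios.
#' @param qpcr_ddct gene-by-couple matrix of delta-delta-Ct values,
#'   aligned with `micro_lr`.
#' @param k_threshold number of discordant panel genes that triggers
#'   exclusion (default 8).
#' @return character vector of excluded couple ids; per-couple
#'   discordance counts attached as attribute `n_discordant`.
#' @export
flag_discordant_couples <- function(micro_lr, qpcr_ddct,
                                    k_threshold = 8) {
  if (!identical(dim(micro_lr), dim(qpcr_ddct)))
    stop("matrices must be aligned")
  if (k_threshold > nrow(micro_lr))
    stop("k_threshold exceeds the panel size (", nrow(micro_lr), ")")
  disc <- sign(micro_lr) != sign(-qpcr_ddct)
  n_disc <- colSums(disc, na.rm = TRUE)
  excluded <- colnames(micro_lr)[n_disc >= k_threshold]
  if (length(excluded))
    message("flag_discordant_couples: excluding ",
            paste(excluded, collapse = ", "),
            " (discordant for >= ", k_threshold, " panel genes)")
  attr(excluded, "n_discordant") <- n_disc
  excluded
}

#' Fisher-Z comparison of two correlation coefficients
#'
#' Transforms each correlation with `Zf = 1/2 ln((1+R)/(1-R))` and
#' compares them with
#' `z = (Zf1 - Zf2) / sqrt(1/(N1-3) + 1/(N2-3))`, which is
#' approximately standard normal under equal true correlations; the
#' two-sided p-value is `2 (1 - Phi(|z|))`.
#'
#' @param R1,R2 correlation coefficients with `|R| < 1`. When only
#'   coefficients of determination are available, pass `R = sqrt(R2)`
#'   (positive root).
#' @param N1,N2 numbers of paired observations behind each
#'   correlation; both must exceed 3.
#' @return list `Zf1`, `Zf2`, `z`, `p`.
#' @export
fisher_z_compare <- function(R1, N1, R2, N2) {
  if (abs(R1) >= 1 || abs(R2) >= 1)
    stop("|R| = 1 gives an infinite Fisher transform; ",
         "consider capping R based on N")
  if (N1 <= 3 || N2 <= 3) stop("N1 and N2 must exceed 3")
  zf <- function(r) 0.5 * log((1 + r) / (1 - r))
  Zf1 <- zf(R1)
  Zf2 <- zf(R2)
  z <- (Zf1 - Zf2) / sqrt(1 / (N1 - 3) + 1 / (N2 - 3))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(Zf1 = Zf1, Zf2 = Zf2, z = z, p = p)
}

#' Per-couple microarray log ratios for a gene panel
#'
#' Helper feeding [cross_platform_correlation()]: per couple and
#' treatment the difference of corrected log values
#' (patient - control), averaged over treatments.
#'
#' @param C corrected gene-by-array matrix.
#' @param design design sheet.
#' @param cohort cohort restriction.
#' @param genes panel gene identifiers (rows of `C`).
#' @return gene-by-couple matrix of log ratios.
#' @export
couple_log_ratios <- function(C, design, cohort, genes) {
  design <- design[design$cohort == cohort, , drop = FALSE]
  couples <- unique(design$couple_id)
  treatments <- unique(design$treatment)
  out <- matrix(NA_real_, length(genes), length(couples),
                dimnames = list(genes, couples))
  for (cp in couples) {
    acc <- matrix(NA_real_, length(genes), length(treatments))
    for (ti in seq_along(treatments)) {
      pat <- design$sample_id[design$couple_id == cp &
                                design$role == "patient" &
                                design$treatment == treatments[ti]]
      ctl <- design$sample_id[design$couple_id == cp &
                                design$role == "control" &
                                design$treatment == treatments[ti]]
      acc[, ti] <- C[genes, pat] - C[genes, ctl]
    }
    out[, cp] <- rowMeans(acc)
  }
  out
}
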