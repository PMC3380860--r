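# Splice-isoform ratio analysis: PLP/DM20 and GFAP pan/alpha/delta
# across developmental stages and disease groups.

.expr_from_dct <- function(d, gene) {
  rows <- d[d$gene == gene, , drop = FALSE]
  e <- ifelse(rows$censored | is.na(rows$delta_ct), 0,
              2^(-rows$delta_ct))
  cens <- rows$censored | is.na(rows$delta_ct)
  list(expr = stats::setNames(e, rows$sample_id),
       censored = stats::setNames(cens, rows$sample_id))
}

.sample_meta <- function(d) {
  meta_cols <- intersect(c("group", "stage"), names(d))
  unique(d[, c("sample_id", meta_cols), drop = FALSE])
}

#' PLP/DM20 isoform metrics
#'
#' Per brain sample: relative expressions (`2^-delta_ct`) of the
#' PLP-specific assay and the common PLP+DM20 assay, the extrapolated
#' DM20 expression `(PLP+DM20) - PLP`, and the ratios `PLP+DM20/PLP`
#' and `DM20/(PLP+DM20)`. Samples with a censored target have
#' expression 0 and flagged (missing) ratios; a negative extrapolated
#' DM20 is flagged (`qc_negative_dm20`) and its ratios withheld, never
#' silently clipped.
#'
#' @param d a [delta_ct()] table containing genes `PLP` and `PLP_DM20`
#'   with `group`/`stage` metadata.
#' @return per-sample data frame of expressions, ratios and flags.
#' @export
plp_metrics <- function(d) {
  meta <- .sample_meta(d)
  plp <- .expr_from_dct(d, "PLP")
  both <- .expr_from_dct(d, "PLP_DM20")
  sid <- meta$sample_id
  out <- meta
  out$PLP <- unname(plp$expr[sid])
  out$PLP_DM20 <- unname(both$expr[sid])
  cens <- plp$censored[sid] | both$censored[sid]
  out$censored <- unname(cens)
  out$DM20 <- out$PLP_DM20 - out$PLP
  out$qc_negative_dm20 <- !cens & out$DM20 < 0
  ok <- !cens & !out$qc_negative_dm20 & out$PLP > 0 & out$PLP_DM20 > 0
  out$ratio_plpdm20_plp <- ifelse(ok, out$PLP_DM20 / out$PLP, NA_real_)
  out$dm20_fraction <- ifelse(ok, out$DM20 / out$PLP_DM20, NA_real_)
  if (any(out$qc_negative_dm20))
    message("plp_metrics: negative extrapolated DM20 in ",
            sum(out$qc_negative_dm20), " sample(s); ratios withheld")
  rownames(out) <- NULL
  out
}

#' GFAP isoform metrics
#'
#' Per brain sample: relative expressions of pan-GFAP and the alpha and
#' delta isoforms, and the ratios pan/alpha, pan/delta and alpha/delta.
#' Censored targets give expression 0 and missing ratios.
#'
#' @param d a [delta_ct()] table containing genes `GFAP_pan`,
#'   `GFAP_alpha` and `GFAP_delta`.
#' @return per-sample data frame of expressions and ratios.
#' @export
gfap_metrics <- function(d) {
  meta <- .sample_meta(d)
  pan <- .expr_from_dct(d, "GFAP_pan")
  alpha <- .expr_from_dct(d, "GFAP_alpha")
  delta <- .expr_from_dct(d, "GFAP_delta")
  sid <- meta$sample_id
  out <- meta
  out$GFAP_pan <- unname(pan$expr[sid])
  out$GFAP_alpha <- unname(alpha$expr[sid])
  out$GFAP_delta <- unname(delta$expr[sid])
  cens <- pan$censored[sid] | alpha$censored[sid] | delta$censored[sid]
  out$censored <- unname(cens)
  ok <- !cens
  out$ratio_pan_alpha <- ifelse(ok & out$GFAP_alpha > 0,
                                out$GFAP_pan / out$GFAP_alpha, NA_real_)
  out$ratio_pan_delta <- ifelse(ok & out$GFAP_delta > 0,
                                out$GFAP_pan / out$GFAP_delta, NA_real_)
  out$ratio_alpha_delta <- ifelse(ok & out$GFAP_delta > 0,
                                  out$GFAP_alpha / out$GFAP_delta,
                                  NA_real_)
  rownames(out) <- NULL
  out
}

#' Stage-wise group comparison of an isoform metric
#'
#' For one developmental stage: the mutated/control fold of group means
#' of the chosen metric, and a two-sided Mann-Whitney test between the
#' groups. With fewer than two samples in either group the p-value is
#' reported as not computable (`NA`); the fold is still returned.
#'
#' @param metrics per-sample metric table ([plp_metrics()],
#'   [gfap_metrics()], or any table with `group`, `stage` and the
#'   metric column).
#' @param metric column name to compare.
#' @param stage developmental stage (`"foetus"`, `"child"`, `"adult"`).
#' @return one-row data frame `stage`, `metric`, `n_mutated`,
#'   `n_control`, `fold`, `U`, `p`.
#' @export
stage_group_analysis <- function(metrics, metric, stage) {
  rows <- metrics[metrics$stage == stage, , drop = FALSE]
  m <- rows[[metric]][rows$group == "mutated"]
  ctl <- rows[[metric]][rows$group == "control"]
  m <- m[!is.na(m)]
  ctl <- ctl[!is.na(ctl)]
  if (length(m) < 1 || length(ctl) < 1)
    stop("need at least one sample per group at stage ", stage)
  fold <- if (mean(ctl) == 0) NA_real_ else mean(m) / mean(ctl)
  if (mean(ctl) == 0)
    message("stage_group_analysis: control mean is 0 at stage ", stage,
            "; fold undefined")
  if (min(length(m), length(ctl)) >= 2) {
    mw <- mann_whitney(m, ctl)
    U <- mw$U; p <- mw$p
  } else {
    U <- NA_real_; p <- NA_real_
  }
  data.frame(stage = stage, metric = metric,
             n_mutated = length(m), n_control = length(ctl),
             fold = fold, U = U, p = p, stringsAsFactors = FALSE)
}
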