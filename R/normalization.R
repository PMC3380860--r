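# Two-channel normalization: log transform, optional standardization,
# reference-channel correction, characterized-gene filter.

#' Log-transform (and optionally standardize) an intensity matrix
#'
#' Natural-log transform of a positive gene-by-array intensity matrix.
#' Standardization is off by default: the reference correction already
#' removes array- and reference-level effects, so scaling each array to
#' mean 0 / sd 1 is offered only as an explicit mode. The log base and
#' standardization mode are recorded in a `provenance` attribute.
#'
#' @param M gene-by-array matrix of positive intensities.
#' @param mode `"none"` (log only) or `"per_array"` (each array column
#'   centred and scaled after the log transform).
#' @param base log base (default natural log).
#' @return log-scale matrix with a `provenance` attribute.
#' @export
log_standardize <- function(M, mode = c("none", "per_array"),
                            base = exp(1)) {
  mode <- match.arg(mode)
  if (!is.matrix(M)) M <- as.matrix(M)
  bad <- which(!is.finite(M) | M <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    g <- if (!is.null(rownames(M))) rownames(M)[bad[1, 1]] else bad[1, 1]
    a <- if (!is.null(colnames(M))) colnames(M)[bad[1, 2]] else bad[1, 2]
    stop(sprintf("non-positive intensity at gene %s, array %s", g, a))
  }
  L <- log(M, base = base)
  if (mode == "per_array")
    L <- scale(L, center = TRUE, scale = TRUE)[, , drop = FALSE]
  attr(L, "provenance") <- list(log_base = base, standardization = mode)
  L
}

#' Reference-channel correction
#'
#' Applies the correction
#' `corrected_i = G_log_i - R_log_i + mean(R_log_i)`, where the gene-wise
#' mean of the reference log values is taken over all arrays of the
#' experiment. The subtraction removes array- and spot-level effects
#' shared by the two channels; adding back the gene's mean reference
#' level keeps the corrected values on the absolute log-intensity scale.
#'
#' @param G,R log-scale matrices (from [log_standardize()]) aligned on
#'   genes (rows) and arrays (columns).
#' @return corrected gene-by-array matrix with a `provenance` attribute.
#' @export
reference_correct <- function(G, R) {
  if (!identical(dim(G), dim(R)))
    stop("G and R must share dimensions")
  if (!is.null(rownames(G)) && !is.null(rownames(R)) &&
      !identical(rownames(G), rownames(R))) {
    off <- union(setdiff(rownames(G), rownames(R)),
                 setdiff(rownames(R), rownames(G)))
    stop("gene identifiers differ between channels: ",
         paste(utils::head(off, 5), collapse = ", "))
  }
  if (!is.null(colnames(G)) && !is.null(colnames(R)) &&
      !identical(colnames(G), colnames(R)))
    stop("array identifiers differ between channels")
  C <- G - R + rowMeans(R)
  attr(C, "provenance") <- c(attr(G, "provenance"),
                             list(correction = "reference_channel"))
  C
}

#' Filter to characterized genes
#'
#' Retains characterized genes, dropping ESTs and chromosomal-location
#' (LOC) entries from the analysis set.
#'
#' @param genes character vector of gene identifiers.
#' @param annotation named character vector (or vector aligned with
#'   `genes`) with values in `characterized`, `EST`, `LOC`.
#' @param lenient keep unannotated genes with a warning instead of
#'   erroring.
#' @return retained gene identifiers; removal counts per class are
#'   attached as attribute `removed` and reported via [message()].
#' @export
filter_characterized <- function(genes, annotation, lenient = FALSE) {
  ann <- if (!is.null(names(annotation)))
    annotation[genes] else annotation
  missing <- is.na(ann)
  if (any(missing)) {
    if (!lenient)
      stop("unannotated gene(s): ",
           paste(utils::head(genes[missing], 5), collapse = ", "))
    warning(sum(missing), " unannotated gene(s) kept (lenient mode)")
    ann[missing] <- "characterized"
  }
  bad_class <- !ann %in% c("characterized", "EST", "LOC")
  if (any(bad_class))
    stop("unknown annotation class: ",
         paste(unique(ann[bad_class]), collapse = ", "))
  keep <- ann == "characterized"
  removed <- table(factor(ann[!keep], levels = c("EST", "LOC")))
  message(sprintf("filter_characterized: removed %d EST, %d LOC; %d retained",
                  removed[["EST"]], removed[["LOC"]], sum(keep)))
  out <- genes[keep]
  attr(out, "removed") <- as.list(removed)
  out
}
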