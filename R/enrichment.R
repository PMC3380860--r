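# Z-score over-representation of gene categories (GMT input).

#' Parse a GMT gene-set file
#'
#' Standard GMT: one category per line, tab-separated
#' `name<TAB>description<TAB>member...`. Duplicate members within a
#' category are collapsed; members absent from the supplied universe are
#' dropped (with a reported count).
#'
#' @param path GMT file path.
#' @param universe character vector of gene identifiers defining the
#'   annotation universe (an explicit required input; typically the
#'   analysed gene complement of the array).
#' @return list of class `category_map` with elements `sets` (named list
#'   of member vectors) and `universe`.
#' @export
parse_gmt <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no categories in GMT file ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  n_dropped <- 0L
  sets <- lapply(sets, function(s) {
    kept <- intersect(s, universe)
    n_dropped <<- n_dropped + length(s) - length(kept)
    kept
  })
  empty <- lengths(sets) == 0
  if (n_dropped > 0)
    message("parse_gmt: dropped ", n_dropped,
            " member(s) absent from the universe")
  if (any(empty)) {
    message("parse_gmt: dropped ", sum(empty), " empty categorie(s)")
    sets <- sets[!empty]
  }
  if (length(sets) == 0) stop("no categories left after harmonization")
  structure(list(sets = sets, universe = unique(universe)),
            class = "category_map")
}

#' Hypergeometric z-score enrichment
#'
#' For each category, the observed hit count `k` is standardized against
#' the hypergeometric expectation of drawing `n` genes from a universe
#' of `N` containing `K` category members:
#' `mu = n K / N`, `sigma^2 = n (K/N) (1 - K/N) (N - n)/(N - 1)`,
#' `z = (k - mu)/sigma`. The z-score expresses the divergence of the
#' observed overlap from chance as a number of standard deviations; a
#' category is flagged significant when `z > z_sig` (default 3). A
#' binomial-approximation mode (`sigma^2 = n p (1 - p)`) is available
#' for sensitivity analysis. No multiple-testing adjustment is applied
#' to z.
#'
#' @param hits character vector of selected genes (must be a subset of
#'   the map's universe).
#' @param map a [parse_gmt()] `category_map`.
#' @param mode `"hypergeometric"` (default) or `"binomial"`.
#' @param z_sig significance threshold on z.
#' @return data frame sorted by decreasing z with columns `category`,
#'   `N`, `K`, `n`, `k`, `z`, `significant`. Degenerate categories
#'   (sigma = 0) are skipped with a warning.
#' @export
zscore_enrichment <- function(hits, map,
                              mode = c("hypergeometric", "binomial"),
                              z_sig = 3) {
  mode <- match.arg(mode)
  if (!inherits(map, "category_map"))
    stop("map must be a category_map from parse_gmt()")
  hits <- unique(hits)
  outside <- setdiff(hits, map$universe)
  if (length(outside))
    stop("hit(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(map$universe)
  n <- length(hits)
  rows <- lapply(names(map$sets), function(nm) {
    members <- map$sets[[nm]]
    K <- length(members)
    k <- length(intersect(hits, members))
    p <- K / N
    mu <- n * p
    v <- if (mode == "hypergeometric")
      n * p * (1 - p) * (N - n) / (N - 1) else n * p * (1 - p)
    if (v <= 0) {
      warning("category ", nm, " skipped (zero variance)")
      return(NULL)
    }
    z <- (k - mu) / sqrt(v)
    data.frame(category = nm, N = N, K = K, n = n, k = k, z = z,
               significant = z > z_sig, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(category = character(0), N = integer(0),
                      K = integer(0), n = integer(0), k = integer(0),
                      z = numeric(0), significant = logical(0)))
  out <- out[order(-out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}
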