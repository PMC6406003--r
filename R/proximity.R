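# Distance-resolved Fisher enrichment of gene sets near binding
# regions, and the ranked sliding-window fraction statistic.

#' Distance from each TSS to the nearest region summit
#'
#' Absolute bp from the TSS to the nearest summit on the same
#' chromosome; 0 if the TSS lies inside a region; `Inf` for genes on
#' chromosomes without regions.
#'
#' @param genes Gene table with `chrom` and `tss` (and optionally
#'   `gene_id`).
#' @param regions Region data.frame with `summit` (and optionally
#'   `start`/`end` for the containment rule), or a data.frame with
#'   `chrom` and `pos` columns of summit positions.
#' @return Named numeric vector of distances (bp).
#' @export
nearest_distance <- function(genes, regions) {
  if (!nrow(regions)) stop("empty region set", call. = FALSE)
  summit <- if ("summit" %in% names(regions)) regions$summit else regions$pos
  if (any(is.na(summit))) stop("regions need summits", call. = FALSE)
  dist <- rep(Inf, nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    ri <- which(regions$chrom == ch)
    if (!length(ri)) next
    s <- sort(summit[ri])
    tss <- genes$tss[gi]
    # nearest in a sorted vector via findInterval
    idx <- findInterval(tss, s)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(s))
    dist[gi] <- pmin(abs(tss - s[lo]), abs(tss - s[hi]))
  }
  if (all(c("start", "end") %in% names(regions))) {
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$tss + 1L, width = 1L))
    inside <- suppressWarnings(
      GenomicRanges::countOverlaps(gg, intervals_to_granges(regions))) > 0
    dist[inside] <- 0
  }
  names(dist) <- genes$gene_id %||% NULL
  dist
}

#' Default log-spaced distance grid
#'
#' @param n Number of thresholds.
#' @param from,to Range (bp).
#' @return Numeric vector of thresholds, ascending.
#' @export
distance_grid <- function(n = 50L, from = 1, to = 1e8) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Distance-resolved Fisher enrichment curve
#'
#' At each distance threshold x, the 2x2 table (responsive within x,
#' responsive beyond, non-responsive within, non-responsive beyond) is
#' tested one-sided for enrichment of responsive genes among genes
#' within x of a region (hypergeometric tail, identical to the
#' one-sided Fisher exact test).
#'
#' @param responsive Character vector of responsive gene ids (a proper
#'   non-empty subset of `universe`).
#' @param universe Character vector of all tested gene ids.
#' @param distances Named distances from [nearest_distance()] covering
#'   the universe.
#' @param grid Ascending distance thresholds; default
#'   [distance_grid()].
#' @return data.frame: `x`, table cells `a`,`b`,`c`,`d`, `odds_ratio`,
#'   `pvalue`, `neg_log10_p`.
#' @export
fisher_curve <- function(responsive, universe, distances,
                         grid = distance_grid()) {
  if (!length(responsive)) stop("responsive set is empty", call. = FALSE)
  if (!all(responsive %in% universe)) {
    stop("responsive set must be a subset of the universe", call. = FALSE)
  }
  if (length(unique(responsive)) == length(unique(universe))) {
    stop("responsive set equals the universe", call. = FALSE)
  }
  if (is.unsorted(grid)) stop("grid thresholds must ascend", call. = FALSE)
  d <- distances[universe]
  if (anyNA(d)) stop("distances missing for some universe genes", call. = FALSE)
  is_resp <- universe %in% responsive
  n_resp <- sum(is_resp)
  N <- length(universe)
  rows <- lapply(grid, function(x) {
    within <- d <= x
    a <- sum(is_resp & within)
    b <- n_resp - a
    cc <- sum(within) - a
    dd <- N - a - b - cc
    # one-sided enrichment p: P(X >= a), X ~ Hypergeom(drawn = within)
    p <- stats::phyper(a - 1, m = a + cc, n = b + dd, k = n_resp,
                       lower.tail = FALSE)
    or <- (a * dd) / (b * cc)
    data.frame(x = x, a = a, b = b, c = cc, d = dd, odds_ratio = or,
               pvalue = p, neg_log10_p = -log10(p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sliding-window fraction of positive labels along a ranked list
#'
#' @param labels Logical (or 0/1) vector in ranked order.
#' @param window Window size (genes); must not exceed the list length.
#' @param step Step between window starts.
#' @return data.frame: `position` (window start index) and `fraction`.
#' @export
sliding_window_fraction <- function(labels, window = 500L, step = 1L) {
  labels <- as.numeric(labels)
  n <- length(labels)
  if (window > n) stop("window larger than the list", call. = FALSE)
  cs <- c(0, cumsum(labels))
  starts <- seq(1L, n - window + 1L, by = step)
  frac <- (cs[starts + window] - cs[starts]) / window
  data.frame(position = starts, fraction = frac)
}
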