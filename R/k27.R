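# Broad histone-domain assembly, replicate QC, dynamics clustering and
# gene-to-domain assignment.

#' Merge broad peaks into domains across samples
#'
#' Pools all samples' peaks, transitively merges intervals whose gap is
#' at most `gap_bp` (inclusive), computes support as the number of
#' distinct samples overlapping the merged interval by >= 1 bp, and
#' drops domains with support below `min_support`.
#'
#' @param peak_sets Named list of broad-peak data.frames (one per
#'   sample) or a single data.frame with a `sample_id` column.
#' @param gap_bp Maximum inter-peak gap merged (bp).
#' @param min_support Minimum number of supporting samples.
#' @return data.frame of sorted, non-overlapping domains: `chrom`,
#'   `start`, `end`, `name`, `support`.
#' @export
merge_domains <- function(peak_sets, gap_bp = 3000L, min_support = 8L) {
  if (gap_bp < 0) stop("gap_bp must be >= 0", call. = FALSE)
  if (is.data.frame(peak_sets)) {
    peak_sets <- split(peak_sets, peak_sets$sample_id)
  }
  if (length(peak_sets) < min_support) {
    stop("need at least min_support samples", call. = FALSE)
  }
  lapply(peak_sets, check_intervals, context = "broad peak set")
  pooled <- do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end")]))
  if (!nrow(pooled)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      support = integer(0), stringsAsFactors = FALSE))
  }
  # reduce() merges ranges whose gap < min.gapwidth, so gap <= gap_bp
  # requires min.gapwidth = gap_bp + 1
  merged <- GenomicRanges::reduce(intervals_to_granges(pooled),
                                  min.gapwidth = gap_bp + 1L)
  support <- Reduce(`+`, lapply(peak_sets, function(p) {
    if (!nrow(p)) return(integer(length(merged)))
    as.integer(GenomicRanges::countOverlaps(
      merged, intervals_to_granges(p)) > 0)
  }))
  keep <- support >= min_support
  out <- granges_to_intervals(merged[keep])
  sup <- support[keep]
  o <- order(out$chrom, out$start)
  out <- out[o, , drop = FALSE]
  out$name <- sprintf("domain_%04d", seq_len(nrow(out)))
  out$support <- sup[o]
  rownames(out) <- NULL
  out
}

#' Count read starts per domain and sample
#'
#' A read counts toward a domain iff its start position lies within the
#' half-open interval `[start, end)`.
#'
#' @param tracks Named list of [read_track()]s or read-start
#'   data.frames (`chrom`, `pos`), one per sample.
#' @param domains Domain data.frame.
#' @return Integer matrix, domains x samples.
#' @export
count_reads_in_domains <- function(tracks, domains) {
  gr <- intervals_to_granges(domains)
  counts <- vapply(tracks, function(t) {
    t <- as_read_track(t)
    rd <- t$reads
    if (!nrow(rd)) return(integer(length(gr)))
    GenomicRanges::countOverlaps(
      gr, GenomicRanges::GRanges(rd$chrom,
                                 IRanges::IRanges(rd$pos + 1L, width = 1L)))
  }, integer(length(gr)))
  if (length(gr) == 1L) counts <- matrix(counts, nrow = 1L,
                                         dimnames = list(NULL, names(tracks)))
  rownames(counts) <- domains$name
  counts
}

#' Flag outlier replicates that dominate within their condition
#'
#' For each sample, the fraction of domains where its count is the
#' strict maximum among its condition's replicates (ties count for no
#' sample); a sample is excluded iff that fraction reaches
#' `frac_threshold`.
#'
#' @param counts Domain x sample count matrix.
#' @param conditions Factor or character vector of condition labels,
#'   one per column of `counts`; every condition needs >= 2 replicates.
#' @param frac_threshold Exclusion threshold on the fraction.
#' @return data.frame: `sample`, `condition`, `frac_max`, `excluded`.
#' @export
flag_outlier_replicates <- function(counts, conditions, frac_threshold = 0.6) {
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == ncol(counts))
  if (any(table(conditions) < 2)) {
    stop("every condition needs >= 2 replicates", call. = FALSE)
  }
  n_dom <- nrow(counts)
  frac <- numeric(ncol(counts))
  for (cond in unique(conditions)) {
    cols <- which(conditions == cond)
    sub <- counts[, cols, drop = FALSE]
    mx <- apply(sub, 1, max)
    is_max <- sub == mx
    strict <- rowSums(is_max) == 1
    for (j in seq_along(cols)) {
      frac[cols[j]] <- sum(is_max[, j] & strict) / n_dom
    }
  }
  data.frame(sample = colnames(counts) %||% as.character(seq_len(ncol(counts))),
             condition = conditions, frac_max = frac,
             excluded = frac >= frac_threshold,
             stringsAsFactors = FALSE)
}

#' Cluster domain dynamics across conditions
#'
#' Per domain, condition-mean counts (over retained replicates) are
#' divided by their maximum over conditions; the max-normalised
#' profiles are clustered with k-means (k = 3 by default).  Clusters
#' are labelled by centroid shape: the centroid whose -LIF mean is
#' lowest relative to +LIF is `lif_loss`, the highest `lif_gain`, the
#' remainder `stable`.
#'
#' @param counts Domain x sample count matrix (outliers already
#'   removed).
#' @param conditions Condition label per column of `counts`.
#' @param lif Named vector mapping each condition to `"+"` or `"-"`.
#' @param k Number of dynamics classes.
#' @param seed Integer RNG seed.
#' @return list with `classes` (named character per domain), `model`
#'   (the `cluster_model`), `centroid_labels` and `profiles` (the
#'   max-normalised condition means).
#' @export
cluster_domain_dynamics <- function(counts, conditions, lif, k = 3L,
                                    seed = 1L) {
  if (nrow(counts) < k) stop("need at least k domains", call. = FALSE)
  conditions <- as.character(conditions)
  conds <- unique(conditions)
  means <- vapply(conds, function(cond)
    rowMeans(counts[, conditions == cond, drop = FALSE]),
    numeric(nrow(counts)))
  if (nrow(counts) == 1L) means <- matrix(means, nrow = 1L,
                                          dimnames = list(NULL, conds))
  mx <- apply(means, 1, max)
  if (any(mx <= 0)) stop("all-zero domain", call. = FALSE)
  prof <- means / mx
  rownames(prof) <- rownames(counts)
  model <- kmeans_cluster(prof, k = k, seed = seed)
  cent <- model$centroids
  lif_minus <- conds[lif[conds] == "-"]
  lif_plus <- conds[lif[conds] == "+"]
  diff <- rowMeans(cent[, match(lif_minus, conds), drop = FALSE]) -
    rowMeans(cent[, match(lif_plus, conds), drop = FALSE])
  labels <- rep("stable", k)
  labels[which.min(diff)] <- "lif_loss"
  labels[which.max(diff)] <- "lif_gain"
  classes <- stats::setNames(labels[model$assignment],
                             names(model$assignment))
  list(classes = classes, model = model,
       centroid_labels = labels, profiles = prof)
}

#' Assign genes to broad domains
#'
#' A gene is embedded iff its body overlaps a domain by >= 1 bp, or a
#' domain lies within `tss_window` of its TSS and that domain overlaps
#' no gene at all (so a promoter-proximal domain is not borrowed from
#' a neighbouring gene).
#'
#' @param genes Gene table with `chrom`, `start`, `end`, `tss`.
#' @param domains Domain data.frame.
#' @param tss_window Maximum TSS-to-domain distance (bp).
#' @return data.frame: `gene_id`, `embedded`, `domain` (name of the
#'   responsible domain or `NA`).
#' @export
assign_genes_to_domains <- function(genes, domains, tss_window = 4000L) {
  gg <- intervals_to_granges(genes)
  dg <- intervals_to_granges(domains)
  n <- nrow(genes)
  embedded <- logical(n)
  via <- rep(NA_character_, n)
  if (nrow(domains)) {
    ov <- suppressWarnings(GenomicRanges::findOverlaps(gg, dg))
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov)
      embedded[q] <- TRUE
      via[q] <- domains$name[S4Vectors::subjectHits(ov)]
    }
    # promoter-proximal rule: domain within tss_window of the TSS and
    # overlapping no gene
    dom_touches_gene <- suppressWarnings(GenomicRanges::countOverlaps(dg, gg)) > 0
    free <- which(!dom_touches_gene)
    if (length(free)) {
      tss_gr <- GenomicRanges::GRanges(
        genes$chrom, IRanges::IRanges(genes$tss + 1L, width = 1L))
      hits <- suppressWarnings(GenomicRanges::findOverlaps(
        tss_gr, dg[free], maxgap = tss_window))
      if (length(hits)) {
        q <- S4Vectors::queryHits(hits)
        newly <- !embedded[q]
        embedded[q] <- TRUE
        via[q[newly]] <- domains$name[free][S4Vectors::subjectHits(hits)[newly]]
      }
    }
  }
  data.frame(gene_id = genes$gene_id, embedded = embedded, domain = via,
             stringsAsFactors = FALSE)
}
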