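# Multi-factor binding traces at consensus regions: quantification,
# solo/co-binding split, occupancy and max normalisation, k-means with
# Rand-index stability selection.

#' Quantify per-factor, per-condition binding traces around summits
#'
#' For each region a `window_bp` window centred on the summit is binned
#' at `bin_bp`; per replicate, read-start counts per bin are scaled to
#' rpm and replicates of a condition are averaged.  Regions whose
#' window would cross a chromosome edge are dropped with a warning.
#'
#' @param regions Region data.frame with a filled `summit` column.
#' @param reads Nested list: `reads[[factor]][[condition]]` is a list
#'   of [read_track()]s (replicates).
#' @param window_bp Window width (bp), an even multiple of `bin_bp`.
#' @param bin_bp Bin width (bp).
#' @param chrom_lengths Optional named chromosome lengths used for
#'   edge-truncation checks.
#' @return A `signal_matrix`: list with array `h` of dim
#'   `[factor, condition, region, bin]` (rpm per bin), `regions`,
#'   `window_bp`, `bin_bp`.
#' @export
quantify_traces <- function(regions, reads, window_bp = 1000L, bin_bp = 10L,
                            chrom_lengths = NULL) {
  if (window_bp %% (2L * bin_bp) != 0) {
    stop("window_bp must be an even multiple of bin_bp", call. = FALSE)
  }
  if (any(is.na(regions$summit))) stop("every region needs a summit", call. = FALSE)
  half <- window_bp %/% 2L
  w_start <- regions$summit - half
  w_end <- regions$summit + half
  ok <- w_start >= 0
  if (!is.null(chrom_lengths)) {
    ok <- ok & w_end <= chrom_lengths[regions$chrom]
  }
  if (any(!ok)) {
    warning(sum(!ok), " region(s) truncated at chromosome edges were dropped")
    regions <- regions[ok, , drop = FALSE]
    w_start <- w_start[ok]
  }
  n_reg <- nrow(regions)
  m <- window_bp %/% bin_bp
  factors <- names(reads)
  conds <- unique(unlist(lapply(reads, names)))
  h <- array(0, dim = c(length(factors), length(conds), n_reg, m),
             dimnames = list(factors, conds, regions$name, NULL))
  windows <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(w_start + 1L, width = window_bp))
  for (fi in seq_along(factors)) {
    fac <- factors[fi]
    if (!length(reads[[fac]])) stop("no reads for factor ", fac, call. = FALSE)
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      reps <- reads[[fac]][[cond]]
      if (is.null(reps)) next
      acc <- matrix(0, n_reg, m)
      for (t in reps) {
        t <- as_read_track(t)
        rd <- t$reads
        if (nrow(rd)) {
          hits <- GenomicRanges::findOverlaps(
            GenomicRanges::GRanges(rd$chrom,
                                   IRanges::IRanges(rd$pos + 1L, width = 1L)),
            windows)
          if (length(hits)) {
            q <- S4Vectors::queryHits(hits)
            s <- S4Vectors::subjectHits(hits)
            bin <- (rd$pos[q] - w_start[s]) %/% bin_bp + 1L
            cnt <- matrix(0, n_reg, m)
            idx <- cbind(s, bin)
            tab <- rowsum(rep(1, nrow(idx)), group = (s - 1) * m + bin)
            lin <- as.integer(rownames(tab))
            cnt[cbind((lin - 1L) %/% m + 1L, (lin - 1L) %% m + 1L)] <- tab[, 1]
            acc <- acc + cnt * (1e6 / t$library_size)
          }
        }
      }
      h[fi, ci, , ] <- acc / max(length(reps), 1L)
    }
  }
  structure(list(h = h, regions = regions, window_bp = window_bp,
                 bin_bp = bin_bp), class = "signal_matrix")
}

#' Restrict a signal matrix to a subset of regions
#'
#' @param sm A `signal_matrix`.
#' @param ids Region names to keep.
#' @return A `signal_matrix` over the subset.
#' @export
subset_regions <- function(sm, ids) {
  keep <- match(ids, sm$regions$name)
  if (anyNA(keep)) stop("unknown region id(s)", call. = FALSE)
  structure(list(h = sm$h[, , keep, , drop = FALSE],
                 regions = sm$regions[keep, , drop = FALSE],
                 window_bp = sm$window_bp, bin_bp = sm$bin_bp),
            class = "signal_matrix")
}

#' Split regions into solo and co-binding sets
#'
#' A region is co-binding iff its maximum bin value reaches
#' `threshold_rpm` (inclusive) for at least one factor in at least one
#' condition; otherwise it is solo (bound by the anchoring factor
#' alone).  The anchoring factor itself (e.g. `"Nanog"`) should not be
#' among the matrix's factors, or be excluded via `factors`.
#'
#' @param sm A `signal_matrix`.
#' @param threshold_rpm Peak-height threshold in rpm.
#' @param factors Factors considered (default: all in `sm`).
#' @return list with character vectors `solo` and `cobinding`.
#' @export
split_solo_cobinding <- function(sm, threshold_rpm = 2.7, factors = NULL) {
  if (threshold_rpm <= 0) stop("threshold must be > 0", call. = FALSE)
  factors <- factors %||% dimnames(sm$h)[[1]]
  hh <- sm$h[factors, , , , drop = FALSE]
  mx <- apply(hh, 3, max)
  ids <- sm$regions$name
  list(solo = ids[mx < threshold_rpm], cobinding = ids[mx >= threshold_rpm])
}

#' Occupancy-scale and max-normalise traces for clustering
#'
#' Restricts the window to +/- `flank_bp` around the summit, computes
#' the per-factor +Dox occupancy score `sigma_i` (sum of the +Dox
#' signal over all regions and positions), scales each factor's
#' concatenated +/-Dox trace by `sigma_i`, and divides each region's
#' concatenated vector by its own maximum, so every clustered region's
#' feature vector has maximum exactly 1.
#'
#' @param sm A `signal_matrix` (already restricted to the regions to
#'   cluster, e.g. the co-binding set).
#' @param factors Factors entering the feature space.
#' @param flank_bp Half-width of the clustered window (bp).
#' @param plus_condition Name of the +Dox condition in `sm`.
#' @return A `trace_set`: list with `tau_bar` (region x feature
#'   matrix), `sigma`, `region_ids`, `excluded` (regions with all-zero
#'   traces, not clustered), and the feature layout.
#' @export
normalize_traces <- function(sm, factors = NULL, flank_bp = 250L,
                             plus_condition = "plus") {
  factors <- factors %||% dimnames(sm$h)[[1]]
  conds <- dimnames(sm$h)[[2]]
  if (!plus_condition %in% conds) {
    stop("plus_condition not found in signal matrix", call. = FALSE)
  }
  m <- dim(sm$h)[4]
  half_bins <- flank_bp %/% sm$bin_bp
  centre <- m %/% 2L
  bins <- (centre - half_bins + 1L):(centre + half_bins)
  sigma <- vapply(factors, function(f)
    sum(sm$h[f, plus_condition, , bins]), 0)
  zero <- names(sigma)[sigma <= 0]
  if (length(zero)) {
    stop("occupancy score sigma is zero for factor: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  # feature layout: factor-major, then condition (+Dox first), then bin
  cond_order <- c(plus_condition, setdiff(conds, plus_condition))
  n_reg <- dim(sm$h)[3]
  blocks <- list()
  for (f in factors) {
    for (cond in cond_order) {
      blocks[[paste(f, cond, sep = ".")]] <-
        matrix(sm$h[f, cond, , bins, drop = FALSE], nrow = n_reg) / sigma[[f]]
    }
  }
  tau <- do.call(cbind, blocks)
  rownames(tau) <- sm$regions$name
  mx <- apply(tau, 1, max)
  excluded <- rownames(tau)[mx <= 0]
  keep <- mx > 0
  tau_bar <- tau[keep, , drop = FALSE] / mx[keep]
  structure(list(tau_bar = tau_bar, sigma = sigma,
                 region_ids = rownames(tau_bar), excluded = excluded,
                 factors = factors, conditions = cond_order,
                 bins_per_block = length(bins)),
            class = "trace_set")
}

#' k-means clustering with k-means++ initialisation
#'
#' Lloyd's algorithm with k-means++ seeding, best of `n_init` restarts
#' by within-cluster sum of squares (inertia); an emptied cluster is
#' reseeded from the point farthest from its centroid.  Deterministic
#' given `seed`.
#'
#' @param x A `trace_set` or a numeric matrix (rows = observations).
#' @param k Number of clusters (`2 <= k <= nrow(x)`).
#' @param seed Integer RNG seed.
#' @param n_init Number of random restarts.
#' @param max_iter Maximum Lloyd iterations.
#' @param tol Relative inertia change declaring convergence.
#' @return A `cluster_model`: list with `k`, `centroids`, `assignment`
#'   (named integer vector), `inertia`, `seed`, `iterations`.
#' @export
kmeans_cluster <- function(x, k, seed = 1L, n_init = 10L, max_iter = 300L,
                           tol = 1e-6) {
  if (inherits(x, "trace_set")) x <- x$tau_bar
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n) stop("require 1 <= k <= number of observations", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    for (init in seq_len(n_init)) {
      fit <- .lloyd(x, k, max_iter, tol)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    structure(list(k = k, centroids = best$centroids,
                   assignment = stats::setNames(best$assignment, rownames(x)),
                   inertia = best$inertia, seed = seed,
                   iterations = best$iterations,
                   inertia_trace = best$inertia_trace),
              class = "cluster_model")
  })
}

.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- .row_dist2(x, centers[1, , drop = FALSE])[, 1]
  if (k > 1) for (j in 2:k) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, .row_dist2(x, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

# squared Euclidean distances between rows of x and rows of c
.row_dist2 <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, `+`) - 2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

.lloyd <- function(x, k, max_iter, tol) {
  centers <- .kmeanspp_init(x, k)
  n <- nrow(x)
  inertia_trace <- numeric(0)
  assign_old <- rep(0L, n)
  inertia <- Inf
  for (iter in seq_len(max_iter)) {
    d2 <- .row_dist2(x, centers)
    assign_new <- max.col(-d2, ties.method = "first")
    # repair empty clusters: reseed from the farthest point (a point at
    # positive distance in a cluster of size >= 2); with exact
    # duplicates there may be nothing to repair and the effective k is
    # smaller
    repeat {
      sizes <- tabulate(assign_new, k)
      empty <- which(sizes == 0L)
      if (!length(empty)) break
      mind2 <- d2[cbind(seq_len(n), assign_new)]
      eligible <- which(sizes[assign_new] >= 2L & mind2 > 0)
      if (!length(eligible)) break
      far <- eligible[which.max(mind2[eligible])]
      centers[empty[1], ] <- x[far, ]
      d2[, empty[1]] <- .row_dist2(x, centers[empty[1], , drop = FALSE])[, 1]
      better <- d2[, empty[1]] < mind2
      assign_new[better] <- empty[1L]
      assign_new[far] <- empty[1L]
    }
    new_inertia <- sum(d2[cbind(seq_len(n), assign_new)])
    inertia_trace <- c(inertia_trace, new_inertia)
    for (j in seq_len(k)) {
      if (any(assign_new == j)) {
        centers[j, ] <- colMeans(x[assign_new == j, , drop = FALSE])
      }
    }
    if (identical(assign_new, assign_old) ||
        (is.finite(inertia) &&
         abs(inertia - new_inertia) <= tol * max(inertia, 1e-12))) {
      inertia <- new_inertia
      assign_old <- assign_new
      break
    }
    inertia <- new_inertia
    assign_old <- assign_new
  }
  # final inertia against updated centroids
  d2 <- .row_dist2(x, centers)
  assign_final <- max.col(-d2, ties.method = "first")
  list(centroids = centers, assignment = assign_final,
       inertia = sum(d2[cbind(seq_len(n), assign_final)]),
       iterations = length(inertia_trace), inertia_trace = inertia_trace)
}

#' Rand index between two partitions
#'
#' Fraction of object pairs on which the partitions agree: pairs
#' together in both plus pairs apart in both, over `choose(n, 2)`.
#'
#' @param a,b Cluster assignments over the same objects (named vectors
#'   are aligned by name).
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      stop("mismatched region sets", call. = FALSE)
    }
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop("mismatched region sets", call. = FALSE)
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * sum_ij - sum_i - sum_j) / total
}

#' Select k by Rand-index stability between k and k + 1
#'
#' Clusters at every k in `k_range` (and `max(k_range) + 1`) with the
#' same seed policy, and reports the Rand index between the
#' assignments at k and k + 1.  The recommended k is the smallest k
#' whose `RI(k, k+1)` reaches `stability_threshold`; the final choice
#' is left to the user.
#'
#' @param x A `trace_set` or numeric matrix.
#' @param k_range Integer vector `c(min_k, max_k)`.
#' @param seed Integer RNG seed (shared across k).
#' @param stability_threshold Rand-index threshold.
#' @param ... Passed to [kmeans_cluster()].
#' @return A `k_selection` report: list with `table` (data.frame `k`,
#'   `rand_next`), `recommended_k` and the fitted models.
#' @export
select_k <- function(x, k_range = c(2L, 20L), seed = 1L,
                     stability_threshold = 0.9, ...) {
  if (inherits(x, "trace_set")) x <- x$tau_bar
  ks <- seq(k_range[1], k_range[2])
  if (k_range[1] < 2 || k_range[2] + 1 > nrow(x) || k_range[2] < k_range[1]) {
    stop("degenerate k range", call. = FALSE)
  }
  models <- lapply(c(ks, max(ks) + 1L), function(k)
    kmeans_cluster(x, k, seed = seed, ...))
  names(models) <- as.character(c(ks, max(ks) + 1L))
  ri <- vapply(seq_along(ks), function(i)
    rand_index(models[[i]]$assignment, models[[i + 1]]$assignment), 0)
  tab <- data.frame(k = ks, rand_next = ri)
  rec <- ks[ri >= stability_threshold]
  structure(list(table = tab,
                 recommended_k = if (length(rec)) rec[1] else NA_integer_,
                 stability_threshold = stability_threshold,
                 models = models),
            class = "k_selection")
}

#' Per-cluster mean binding profiles
#'
#' For each cluster, factor and condition, the mean rpm trace over the
#' cluster's regions; regions are ordered by cluster then by
#' descending signal of `order_factor` (total signal if absent).
#'
#' @param model A `cluster_model`.
#' @param sm The `signal_matrix` the clustering was built from.
#' @param order_factor Factor used to order regions within a cluster.
#' @return list with `profiles` (long data.frame: cluster, factor,
#'   condition, bin, mean) and `region_order`.
#' @export
cluster_summary <- function(model, sm, order_factor = "Nanog") {
  ids <- names(model$assignment)
  sm <- subset_regions(sm, ids)
  factors <- dimnames(sm$h)[[1]]
  conds <- dimnames(sm$h)[[2]]
  m <- dim(sm$h)[4]
  rows <- list()
  for (cl in sort(unique(model$assignment))) {
    members <- ids[model$assignment == cl]
    idx <- match(members, sm$regions$name)
    for (f in factors) for (cond in conds) {
      block <- sm$h[f, cond, idx, , drop = FALSE]
      mean_trace <- apply(array(block, dim = c(length(idx), m)), 2, mean)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, factor = f, condition = cond, bin = seq_len(m),
        mean = mean_trace, stringsAsFactors = FALSE)
    }
  }
  strength <- if (order_factor %in% factors) {
    apply(sm$h[order_factor, , , , drop = FALSE], 3, sum)
  } else {
    apply(sm$h, 3, sum)
  }
  o <- order(model$assignment[ids], -strength[match(ids, sm$regions$name)])
  list(profiles = do.call(rbind, rows), region_order = ids[o])
}
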