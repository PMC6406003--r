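# Negative-binomial GLM contrast testing and the three-contrast gene
# response taxonomy.
#
# The model is a per-gene NB log-link GLM fitted by IRLS with a
# method-of-moments dispersion (floor 1e-8) estimated on normalised
# counts within design cells -- no dispersion shrinkage, no independent
# filtering, no fold-change shrinkage.  Wald statistics are referred to
# the standard normal; BH adjustment is applied within each contrast.

#' Median-of-ratios size factors and expression filter
#'
#' Size factors follow the median-of-ratios scheme (geometric-mean
#' reference over genes with all-positive counts).  A gene is retained
#' iff there is at least one condition in which every replicate's
#' normalised count is at least `min_norm_count`.
#'
#' @param counts Gene x sample integer matrix.
#' @param samples Sample sheet with `sample_id` rows matching the
#'   columns of `counts`.
#' @param min_norm_count Expression filter threshold.
#' @param condition Optional condition label per sample; defaults to
#'   the interaction of the `cell_system`, `lif`, `dox`, `guide`
#'   columns present in `samples`.
#' @return list with `normalized` (matrix), `size_factors`,
#'   `retained` (character vector of gene ids) and `condition`.
#' @export
normalize_and_filter <- function(counts, samples, min_norm_count = 10,
                                 condition = NULL) {
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  stopifnot(identical(colnames(counts), samples$sample_id))
  if (is.null(condition)) {
    cols <- intersect(c("cell_system", "lif", "dox", "guide"), names(samples))
    if (!length(cols)) stop("no condition columns in sample sheet", call. = FALSE)
    condition <- do.call(paste, c(samples[cols], sep = ":"))
  }
  log_counts <- log(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("size factors undefined: no gene with all-positive counts",
         call. = FALSE)
  }
  log_geo <- rowMeans(log_counts[all_pos, , drop = FALSE])
  sf <- apply(log_counts[all_pos, , drop = FALSE], 2, function(lc)
    exp(stats::median(lc - log_geo)))
  normalized <- sweep(counts, 2, sf, "/")
  keep <- vapply(seq_len(nrow(counts)), function(g) {
    any(tapply(normalized[g, ], condition, function(v)
      all(v >= min_norm_count)))
  }, logical(1))
  list(normalized = normalized, size_factors = sf,
       retained = rownames(counts)[keep], condition = condition)
}

# dispersion per gene: fixed value, per-gene moments, or the common
# estimate pooling moment numerators and denominators over all genes
.dispersion_vector <- function(norm, cells, dispersion, method) {
  n_genes <- nrow(norm)
  if (!is.null(dispersion)) return(rep(max(dispersion, 1e-8), n_genes))
  nd <- vapply(seq_len(n_genes), function(g)
    .mom_parts(norm[g, ], cells), numeric(2))
  if (method == "per_gene") {
    pmax(ifelse(nd[2, ] > 0, nd[1, ] / nd[2, ], 0), 1e-8)
  } else {
    rep(max(sum(nd[1, ]) / max(sum(nd[2, ]), 1e-12), 1e-8), n_genes)
  }
}

# moment numerator/denominator of the NB dispersion for one gene on
# normalised counts, pooled over design cells
.mom_parts <- function(norm_row, cells) {
  num <- 0; den <- 0
  for (cell in unique(cells)) {
    v <- norm_row[cells == cell]
    if (length(v) < 2) next
    m <- mean(v)
    if (m <= 0) next
    num <- num + (length(v) - 1) * (stats::var(v) - m)
    den <- den + (length(v) - 1) * m^2
  }
  c(num, den)
}

# per-gene moments dispersion (floored); used directly in tests
.mom_dispersion <- function(norm_row, cells, floor = 1e-8) {
  nd <- .mom_parts(norm_row, cells)
  if (nd[2] <= 0) return(floor)
  max(nd[1] / nd[2], floor)
}

.fit_gene_nb <- function(y, X, offset, alpha) {
  fam <- MASS::negative.binomial(theta = 1 / alpha, link = "log")
  fit <- suppressWarnings(
    stats::glm.fit(x = X, y = y, family = fam, offset = offset))
  ok <- isTRUE(fit$converged) && !any(is.na(fit$coefficients))
  vc <- NULL
  if (ok) {
    W <- fit$weights
    vc <- tryCatch(solve(crossprod(X * sqrt(W))), error = function(e) NULL)
    if (is.null(vc)) ok <- FALSE
  }
  list(ok = ok, beta = fit$coefficients, vcov = vc,
       fitted = fit$fitted.values)
}

#' Fit per-gene NB GLMs and test Wald contrasts
#'
#' Fits `counts[g, ] ~ design` with a log link, size factors as
#' offsets and a per-gene moments dispersion, then tests each contrast
#' `c` with the Wald statistic `(c %*% beta) / sqrt(c' Sigma c)`
#' against the standard normal.  Log2 fold changes are reported (the
#' natural-log coefficients divided by `log(2)`).  BH adjustment is
#' applied per contrast over the converged genes; non-converged genes
#' are flagged and excluded from the FDR universe.
#'
#' @param counts Gene x sample integer matrix (already restricted to
#'   retained genes).
#' @param samples Sample sheet.
#' @param design Model formula over columns of `samples`, e.g.
#'   `~ lif * dox`.
#' @param contrasts Named list of numeric contrast vectors over the
#'   design-matrix columns.
#' @param size_factors Optional; computed by median-of-ratios when
#'   missing.
#' @param dispersion Optional fixed dispersion, overriding
#'   `dispersion_method`.
#' @param dispersion_method `"common"` (default): one dispersion for
#'   the whole matrix, the median of the per-gene moments estimates --
#'   stabler at small replicate numbers and closer in spirit to tools
#'   that pool dispersion information across genes; `"per_gene"`: each
#'   gene keeps its own moments estimate.  Both floored at 1e-8.
#' @return Named list of contrast results; each is a data.frame with
#'   `gene`, `log2fc`, `se`, `stat`, `pvalue`, `fdr`, `converged`.
#' @export
fit_nb_contrasts <- function(counts, samples, design, contrasts,
                             size_factors = NULL, dispersion = NULL,
                             dispersion_method = c("common", "per_gene")) {
  dispersion_method <- match.arg(dispersion_method)
  X <- stats::model.matrix(design, data = samples)
  if (qr(X)$rank < ncol(X)) stop("design matrix not full rank", call. = FALSE)
  if (nrow(X) - ncol(X) < 1) {
    stop("need >= 1 residual degree of freedom", call. = FALSE)
  }
  for (cn in names(contrasts)) {
    if (length(contrasts[[cn]]) != ncol(X)) {
      stop("contrast '", cn, "' length != number of design columns",
           call. = FALSE)
    }
  }
  if (is.null(size_factors)) {
    lc <- log(counts)
    all_pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(all_pos)) stop("size factors undefined", call. = FALSE)
    lg <- rowMeans(lc[all_pos, , drop = FALSE])
    size_factors <- apply(lc[all_pos, , drop = FALSE], 2, function(v)
      exp(stats::median(v - lg)))
  }
  offset <- log(size_factors)
  cells <- apply(X, 1, paste, collapse = ",")
  norm <- sweep(counts, 2, size_factors, "/")
  n_genes <- nrow(counts)
  genes <- rownames(counts) %||% as.character(seq_len(n_genes))

  res <- lapply(contrasts, function(cv)
    data.frame(gene = genes, log2fc = NA_real_, se = NA_real_,
               stat = NA_real_, pvalue = NA_real_, fdr = NA_real_,
               converged = FALSE, stringsAsFactors = FALSE))
  alphas <- .dispersion_vector(norm, cells, dispersion, dispersion_method)
  for (g in seq_len(n_genes)) {
    alpha <- alphas[g]
    fit <- .fit_gene_nb(counts[g, ], X, offset, alpha)
    if (!fit$ok) next
    for (cn in names(contrasts)) {
      cv <- contrasts[[cn]]
      est <- sum(cv * fit$beta)
      if (all(cv == 0)) {
        res[[cn]][g, c("log2fc", "se", "stat", "pvalue")] <-
          c(0, 0, 0, 1)
        res[[cn]]$converged[g] <- TRUE
        next
      }
      v <- drop(t(cv) %*% fit$vcov %*% cv)
      se <- sqrt(max(v, 0))
      z <- if (se > 0) est / se else 0
      res[[cn]][g, c("log2fc", "se", "stat", "pvalue")] <-
        c(est / log(2), se / log(2), z, 2 * stats::pnorm(-abs(z)))
      res[[cn]]$converged[g] <- TRUE
    }
  }
  n_fail <- sum(!res[[1]]$converged)
  if (n_fail > 0) {
    message(n_fail, " gene(s) failed to converge and were excluded from FDR")
  }
  for (cn in names(contrasts)) {
    ok <- res[[cn]]$converged
    res[[cn]]$fdr[ok] <- stats::p.adjust(res[[cn]]$pvalue[ok], method = "BH")
    attr(res[[cn]], "contrast") <- cn
  }
  res
}

.nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, size = 1 / alpha, mu = pmax(mu, 1e-12), log = TRUE))
}

#' Likelihood-ratio test between nested NB models
#'
#' Per gene, twice the log-likelihood difference between the full and
#' reduced model (same per-gene moments dispersion, estimated under
#' the full design's cells) is referred to a chi-square with df equal
#' to the difference in coefficient count.
#'
#' @param counts Gene x sample integer matrix.
#' @param samples Sample sheet.
#' @param full,reduced Nested model formulas (e.g.
#'   `~ cell_system * dox` over `~ cell_system`).
#' @param size_factors Optional size factors.
#' @inheritParams fit_nb_contrasts
#' @return data.frame: `gene`, `stat`, `df`, `pvalue`, `fdr`,
#'   `converged`.
#' @export
lrt_combined <- function(counts, samples, full, reduced,
                         size_factors = NULL, dispersion = NULL,
                         dispersion_method = c("common", "per_gene")) {
  dispersion_method <- match.arg(dispersion_method)
  Xf <- stats::model.matrix(full, data = samples)
  Xr <- stats::model.matrix(reduced, data = samples)
  df <- ncol(Xf) - ncol(Xr)
  if (df < 1) stop("reduced model not nested in full (no extra coefficients)",
                   call. = FALSE)
  comb <- qr(cbind(Xf, Xr))$rank
  if (comb > qr(Xf)$rank) {
    stop("reduced model not nested in full", call. = FALSE)
  }
  if (is.null(size_factors)) {
    lc <- log(counts)
    all_pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(all_pos)) stop("size factors undefined", call. = FALSE)
    lg <- rowMeans(lc[all_pos, , drop = FALSE])
    size_factors <- apply(lc[all_pos, , drop = FALSE], 2, function(v)
      exp(stats::median(v - lg)))
  }
  offset <- log(size_factors)
  cells <- apply(Xf, 1, paste, collapse = ",")
  norm <- sweep(counts, 2, size_factors, "/")
  genes <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  out <- data.frame(gene = genes, stat = NA_real_, df = df,
                    pvalue = NA_real_, fdr = NA_real_, converged = FALSE,
                    stringsAsFactors = FALSE)
  alphas <- .dispersion_vector(norm, cells, dispersion, dispersion_method)
  for (g in seq_len(nrow(counts))) {
    alpha <- alphas[g]
    ff <- .fit_gene_nb(counts[g, ], Xf, offset, alpha)
    fr <- .fit_gene_nb(counts[g, ], Xr, offset, alpha)
    if (!ff$ok || !fr$ok) next
    stat <- max(0, 2 * (.nb_loglik(counts[g, ], ff$fitted, alpha) -
                          .nb_loglik(counts[g, ], fr$fitted, alpha)))
    out$stat[g] <- stat
    out$pvalue[g] <- stats::pchisq(stat, df = df, lower.tail = FALSE)
    out$converged[g] <- TRUE
  }
  out$fdr[out$converged] <- stats::p.adjust(out$pvalue[out$converged],
                                            method = "BH")
  out
}

#' Union of responsive genes across tests
#'
#' A gene is responsive iff its FDR is below `fdr` in any of the
#' supplied tests; each selected gene carries provenance flags and its
#' direction (sign of the Wald log2 fold change; tests without a fold
#' change, such as the LRT, contribute no direction).  Opposite signs
#' between tests are flagged, not dropped.
#'
#' @param results Named list of contrast/LRT result data.frames
#'   sharing a gene universe.
#' @param fdr FDR threshold.
#' @return data.frame: `gene`, `selected_by` (comma-joined test
#'   names), `direction` (`1`, `-1`, `0` for none), `sign_conflict`.
#' @export
responsive_union <- function(results, fdr = 0.05) {
  stopifnot(length(results) >= 1)
  genes <- results[[1]]$gene
  if (!length(genes)) stop("empty gene universe", call. = FALSE)
  for (r in results) {
    if (!setequal(r$gene, genes)) stop("mismatched gene universes", call. = FALSE)
  }
  sel <- lapply(results, function(r) {
    r <- r[match(genes, r$gene), ]
    !is.na(r$fdr) & r$fdr < fdr
  })
  any_sel <- Reduce(`|`, sel)
  dirs <- lapply(names(results), function(nm) {
    r <- results[[nm]][match(genes, results[[nm]]$gene), ]
    if ("log2fc" %in% names(r)) sign(r$log2fc) * sel[[nm]] else rep(0, length(genes))
  })
  dir_mat <- do.call(cbind, dirs)
  direction <- apply(dir_mat, 1, function(v) {
    v <- v[v != 0 & !is.na(v)]
    if (!length(v)) 0 else sign(sum(sign(v)))
  })
  conflict <- apply(dir_mat, 1, function(v) {
    v <- v[v != 0 & !is.na(v)]
    length(unique(sign(v))) > 1
  })
  out <- data.frame(
    gene = genes,
    selected_by = vapply(seq_along(genes), function(i)
      paste(names(results)[vapply(sel, `[`, TRUE, i)], collapse = ","),
      character(1)),
    direction = direction, sign_conflict = conflict,
    stringsAsFactors = FALSE)
  out[any_sel, , drop = FALSE]
}

#' 3x3 concordance between two up/down/ns classifications
#'
#' Pearson chi-square (df = 4) without continuity correction,
#' Cramer's V, and a one-sided Fisher exact test on the 2x2
#' responsive-vs-not overlap.
#'
#' @param state_a,state_b Character vectors in `{up, down, ns}` over
#'   the same genes (aligned by names when present).
#' @return list: `table`, `chisq`, `df`, `pvalue`, `cramers_v`,
#'   `fisher_p`.  With a zero margin the chi-square is `NA`
#'   (not applicable).
#' @export
concordance_3x3 <- function(state_a, state_b) {
  if (!is.null(names(state_a)) && !is.null(names(state_b))) {
    if (!setequal(names(state_a), names(state_b))) {
      stop("mismatched gene universes", call. = FALSE)
    }
    state_b <- state_b[names(state_a)]
  }
  stopifnot(length(state_a) == length(state_b))
  lv <- c("up", "down", "ns")
  tab <- table(factor(state_a, levels = lv), factor(state_b, levels = lv))
  n <- sum(tab)
  chisq <- NA_real_; pval <- NA_real_; v <- NA_real_
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chisq <- unname(ct$statistic)
    pval <- ct$p.value
    v <- sqrt(chisq / (n * (min(dim(tab)) - 1)))
  }
  resp_a <- factor(state_a != "ns", levels = c(TRUE, FALSE))
  resp_b <- factor(state_b != "ns", levels = c(TRUE, FALSE))
  fisher_p <- stats::fisher.test(table(resp_a, resp_b),
                                 alternative = "greater")$p.value
  list(table = tab, chisq = chisq, df = 4L, pvalue = pval,
       cramers_v = v, fisher_p = fisher_p)
}

.classify_state <- function(res, fdr) {
  ifelse(is.na(res$fdr) | res$fdr >= fdr, "ns",
         ifelse(res$log2fc > 0, "up", "down"))
}

#' Classify genes into response-pattern triples
#'
#' Per gene, the triple of states over three contrasts -- the effect
#' of LIF withdrawal, the Dox effect in +LIF and the Dox effect in
#' -LIF -- each `up` (FDR < `fdr` and log2fc > 0), `down` (FDR <
#' `fdr` and log2fc < 0) or `ns`.  Sign convention: the LIF contrast
#' is the -LIF vs +LIF fold change, so `up` means higher expression
#' after LIF withdrawal.  Rescue categories: a LIF-responsive gene
#' whose Dox effect in -LIF opposes the withdrawal effect is rescued
#' (`rescued_up` when up on withdrawal and pushed down by induction);
#' LIF-responsive with no Dox effect in -LIF is `not_rescued_*`;
#' everything else is `other`.
#'
#' @param lif,dox_plus,dox_minus Contrast results from
#'   [fit_nb_contrasts()] over the same genes.
#' @param fdr FDR threshold.
#' @return list with `patterns` (data.frame: gene, three states,
#'   `pattern`, `rescue_category`) and `pattern_counts` (all 27
#'   triples, zeros included).
#' @export
classify_patterns <- function(lif, dox_plus, dox_minus, fdr = 0.05) {
  genes <- lif$gene
  if (!setequal(genes, dox_plus$gene) || !setequal(genes, dox_minus$gene)) {
    stop("mismatched gene universes", call. = FALSE)
  }
  dox_plus <- dox_plus[match(genes, dox_plus$gene), ]
  dox_minus <- dox_minus[match(genes, dox_minus$gene), ]
  s1 <- .classify_state(lif, fdr)
  s2 <- .classify_state(dox_plus, fdr)
  s3 <- .classify_state(dox_minus, fdr)
  pattern <- paste(s1, s2, s3, sep = ":")
  rescue <- rep("other", length(genes))
  rescue[s1 == "up" & s3 == "down"] <- "rescued_up"
  rescue[s1 == "down" & s3 == "up"] <- "rescued_down"
  rescue[s1 == "up" & s3 == "ns"] <- "not_rescued_up"
  rescue[s1 == "down" & s3 == "ns"] <- "not_rescued_down"
  all27 <- apply(expand.grid(.states, .states, .states), 1, paste,
                 collapse = ":")
  counts <- table(factor(pattern, levels = sort(all27)))
  list(patterns = data.frame(gene = genes, lif = s1, dox_plus_lif = s2,
                             dox_minus_lif = s3, pattern = pattern,
                             rescue_category = rescue,
                             stringsAsFactors = FALSE),
       pattern_counts = counts)
}

#' Compensation of induction effects by a second guide
#'
#' A gene is compensated iff it was an induction target in -LIF under
#' the first guide (non-ns Dox-in--LIF state) and under the dual guide
#' that state becomes `ns` or flips sign.
#'
#' @param patterns_a Pattern table (from [classify_patterns()]) for
#'   the single guide.
#' @param patterns_b Pattern table for the dual guide.
#' @return data.frame: `gene`, `state_a`, `state_b`, `compensated`.
#' @export
otx2_compensation <- function(patterns_a, patterns_b) {
  pa <- patterns_a$patterns %||% patterns_a
  pb <- patterns_b$patterns %||% patterns_b
  if (!setequal(pa$gene, pb$gene)) stop("mismatched gene universes", call. = FALSE)
  pb <- pb[match(pa$gene, pb$gene), ]
  a <- pa$dox_minus_lif
  b <- pb$dox_minus_lif
  target <- a != "ns"
  comp <- target & (b == "ns" | (b != "ns" & b != a))
  data.frame(gene = pa$gene, state_a = a, state_b = b,
             compensated = comp, stringsAsFactors = FALSE)
}

#' Between-guide difference test in +Dox -LIF
#'
#' Combines the two guides' samples and fits
#' `~ lif + dox_guide + lif:dox_guide`, where `dox_guide` encodes -Dox
#' versus +Dox with each guide, then Wald-tests the difference between
#' the two guides' +Dox effects in -LIF.
#'
#' @param counts Gene x sample matrix over both guides' samples.
#' @param samples Sample sheet with `lif`, `dox`, `guide` columns.
#' @param size_factors Optional size factors.
#' @return A contrast-result data.frame (`guide_difference`).
#' @export
guide_difference_test <- function(counts, samples, size_factors = NULL) {
  guides <- setdiff(unique(samples$guide), NA)
  if (length(guides) != 2) stop("need exactly two guides", call. = FALSE)
  samples$dox_guide <- factor(
    ifelse(samples$dox == "-", "noDox", paste0("Dox_", samples$guide)),
    levels = c("noDox", paste0("Dox_", guides)))
  samples$lif_minus <- factor(ifelse(samples$lif == "-", "minus", "plus"),
                              levels = c("plus", "minus"))
  design <- ~ lif_minus + dox_guide + lif_minus:dox_guide
  X <- stats::model.matrix(design, data = samples)
  cn <- colnames(X)
  g1 <- paste0("dox_guide", "Dox_", guides[1])
  g2 <- paste0("dox_guide", "Dox_", guides[2])
  cv <- stats::setNames(numeric(ncol(X)), cn)
  cv[g1] <- 1; cv[g2] <- -1
  cv[paste0("lif_minusminus:", g1)] <- 1
  cv[paste0("lif_minusminus:", g2)] <- -1
  fit_nb_contrasts(counts, samples, design,
                   contrasts = list(guide_difference = unname(cv)),
                   size_factors = size_factors)$guide_difference
}

#' Row z-scores of an expression matrix
#'
#' Per gene, `(x - row mean) / row sd` with the population (n)
#' denominator; constant rows are set to 0.
#'
#' @param mat Numeric matrix (genes x samples).
#' @param genes Optional subset of row names.
#' @return Matrix of z-scores.
#' @export
zscore_matrix <- function(mat, genes = NULL) {
  if (ncol(mat) < 2) stop("need >= 2 samples", call. = FALSE)
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  m <- rowMeans(mat)
  centred <- mat - m
  sd_n <- sqrt(rowMeans(centred^2))
  z <- centred / ifelse(sd_n > 0, sd_n, 1)
  z[sd_n == 0, ] <- 0
  z
}
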