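# Synthetic-data generators with planted ground truth.  Every generator
# is a pure function of (parameters, seed): the caller's RNG state is
# saved and restored.  Counts are negative binomial throughout, with a
# single dispersion parameter per generator (Var = mu + alpha * mu^2),
# matching the downstream differential-expression model.

#' Simulate a genome: gene models and random DNA sequence
#'
#' Genes are packed without overlap on evenly spaced slots, with
#' balanced strands; the TSS is the interval start on `+` and `end - 1`
#' on `-`.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_genes Total number of genes; requires
#'   `n_genes * 10 kb <= n_chrom * chrom_length`.
#' @param seed Integer RNG seed.
#' @param gene_length Range (bp) gene lengths are drawn from.
#' @return list with `genes` (data.frame: gene_id, chrom, start, end,
#'   strand, tss), `sequences` (named character) and `chrom_lengths`.
#' @export
simulate_genome <- function(n_chrom = 2L, chrom_length = 1e6, n_genes = 100L,
                            seed = 1L, gene_length = c(2000L, 8000L)) {
  if (n_genes * 1e4 > n_chrom * chrom_length) {
    stop("infeasible packing: n_genes * 10 kb exceeds total genome length",
         call. = FALSE)
  }
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(n_chrom))
    sequences <- vapply(chroms, function(ch) {
      paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
            collapse = "")
    }, character(1))
    genes <- NULL
    if (n_genes > 0) {
      per <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
      rows <- vector("list", n_chrom)
      gi <- 0L
      for (ci in seq_len(n_chrom)) {
        ng <- per[ci]
        if (ng == 0) next
        slot <- floor(chrom_length / ng)
        len <- sample(seq(gene_length[1], gene_length[2]), ng, replace = TRUE)
        len <- pmin(len, slot - 200L)
        start <- (seq_len(ng) - 1L) * slot +
          floor(stats::runif(ng, 0, pmax(slot - len - 100L, 1L)))
        strand <- sample(rep(c("+", "-"), length.out = ng))
        rows[[ci]] <- data.frame(
          gene_id = sprintf("gene_%05d", gi + seq_len(ng)),
          chrom = chroms[ci], start = as.integer(start),
          end = as.integer(start + len), strand = strand,
          stringsAsFactors = FALSE)
        gi <- gi + ng
      }
      genes <- do.call(rbind, rows)
      genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    } else {
      genes <- data.frame(gene_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), tss = integer(0))
    }
    list(genes = genes, sequences = sequences,
         chrom_lengths = stats::setNames(rep(chrom_length, n_chrom), chroms))
  })
}

#' Default co-binding archetype amplitude table
#'
#' Eight archetypes over four factors (Esrrb, Oct4, Sox2, Brg1) and two
#' conditions (`plus` = +Dox, `minus` = -Dox).  Amplitudes are expected
#' read counts in the summit bin per replicate at a 1e6 library (so
#' numerically rpm per 10 bp bin).  Archetypes 1-4 lose co-binding on
#' Dox withdrawal (induction-dependent recruitment); 5-8 are
#' Dox-independent.
#'
#' @param on Amplitude of a bound factor in its active condition.
#' @param lost Residual amplitude after Dox withdrawal for dependent
#'   archetypes.
#' @param off Amplitude of an unbound factor.
#' @return 3-d array `[archetype, factor, condition]`.
#' @export
default_archetypes <- function(on = 12, lost = 1, off = 0.2) {
  factors <- c("Esrrb", "Oct4", "Sox2", "Brg1")
  arch <- c("all_dep", "esrrb_dep", "oct4_dep", "oct4sox2_dep",
            "esrrb_indep", "all_indep", "oct4sox2_indep", "brg1_indep")
  a <- array(off, dim = c(8, 4, 2),
             dimnames = list(arch, factors, c("plus", "minus")))
  on_sets <- list(factors, "Esrrb", "Oct4", c("Oct4", "Sox2"),
                  "Esrrb", factors, c("Oct4", "Sox2"), "Brg1")
  for (i in 1:8) {
    a[i, on_sets[[i]], "plus"] <- on
    a[i, on_sets[[i]], "minus"] <- if (i <= 4) lost else on
  }
  a
}

#' Simulate multi-factor binding at planted regions
#'
#' Places `n_regions` summits on one synthetic chromosome.  A planted
#' fraction are "solo" (only the induced factor binds); the rest are
#' co-binding regions drawn from the archetype table.  Per factor,
#' condition and replicate, per-bin counts follow a negative binomial
#' around a Gaussian-shaped profile (sd = `window/8`) whose summit-bin
#' mean is the archetype amplitude, on top of a flat background.  Six
#' pseudo-Nanog peak-call samples each recall a random subset
#' (>= `recall`) of regions so consensus building is non-trivial.
#' Only on-region reads are materialised; each track's `library_size`
#' is `depth`, which the flat background and off-region genome are
#' considered to absorb.
#'
#' @param n_regions Number of planted regions.
#' @param archetypes Amplitude array from [default_archetypes()].
#' @param solo_fraction Fraction of regions planted as solo.
#' @param window Signal window width (bp) around the summit; the
#'   Gaussian profile has sd `window/8`.
#' @param depth Library size (reads) recorded per track.
#' @param nb_dispersion NB dispersion of per-bin counts.
#' @param n_replicates Replicates per factor and condition.
#' @param n_nanog_samples Number of pseudo-Nanog peak-call samples.
#' @param recall Minimum fraction of regions each pseudo-sample recalls.
#' @param bin_bp Bin width used to lay down reads.
#' @param background Flat per-bin background mean.
#' @param nanog_amp Amplitude of the induced factor's own signal.
#' @param seed Integer RNG seed.
#' @return list with `peak_sets` (named list of peak-call data.frames),
#'   `reads` (`reads[[factor]][[condition]]` = list of [read_track()]s;
#'   factors are the archetype factors plus `"Nanog"`), `regions`
#'   (planted intervals with summits) and `truth` (region_id, solo,
#'   archetype, recalled-by count).
#' @export
simulate_binding <- function(n_regions = 2000L,
                             archetypes = default_archetypes(),
                             solo_fraction = 0.49,
                             window = 500L,
                             depth = 1e6,
                             nb_dispersion = 0.1,
                             n_replicates = 2L,
                             n_nanog_samples = 6L,
                             recall = 0.8,
                             bin_bp = 10L,
                             background = 0.05,
                             nanog_amp = 15,
                             seed = 1L) {
  stopifnot(solo_fraction >= 0, solo_fraction <= 1)
  if (any(archetypes < 0)) stop("archetype amplitudes must be >= 0", call. = FALSE)
  if (depth <= 0) stop("zero depth", call. = FALSE)
  factors <- dimnames(archetypes)[[2]]
  n_arch <- dim(archetypes)[1]
  with_seed(seed, {
    chrom <- "chrB"
    spacing <- 3000L
    summits <- as.integer(spacing * seq_len(n_regions) +
                            sample(-300:300, n_regions, replace = TRUE))
    region_id <- sprintf("region_%05d", seq_len(n_regions))
    n_solo <- round(n_regions * solo_fraction)
    solo <- logical(n_regions)
    solo[sample(n_regions, n_solo)] <- TRUE
    arch_id <- rep(NA_character_, n_regions)
    arch_idx <- rep(NA_integer_, n_regions)
    if (any(!solo)) {
      arch_idx[!solo] <- sample(n_arch, sum(!solo), replace = TRUE)
      arch_id[!solo] <- dimnames(archetypes)[[1]][arch_idx[!solo]]
    }

    # bins spanning +/- window around the summit (signal lives in the
    # central +/- window/2; extra flanks carry background only)
    half <- as.integer(window)
    offsets <- seq(-half, half - bin_bp, by = bin_bp)
    centre <- offsets + bin_bp / 2
    sdv <- window / 8
    shape <- exp(-centre^2 / (2 * sdv^2))
    nb <- length(offsets)

    make_track <- function(fac) {
      amp <- numeric(n_regions)
      if (fac == "Nanog") {
        amp[] <- nanog_amp
        amp_minus <- amp
      } else {
        amp[] <- 0.2          # solo / unbound baseline
        amp[!solo] <- archetypes[cbind(arch_idx[!solo],
                                       match(fac, factors), 1L)]
        amp_minus <- numeric(n_regions)
        amp_minus[] <- 0.2
        amp_minus[!solo] <- archetypes[cbind(arch_idx[!solo],
                                             match(fac, factors), 2L)]
      }
      lapply(stats::setNames(c("plus", "minus"), c("plus", "minus")),
             function(cond) {
        a <- if (cond == "plus") amp else amp_minus
        mu <- outer(a, shape) + background     # regions x bins
        lapply(seq_len(n_replicates), function(r) {
          counts <- matrix(rnb(length(mu), as.vector(mu), nb_dispersion),
                           nrow = n_regions)
          tot <- sum(counts)
          if (tot == 0) {
            return(read_track(data.frame(chrom = character(0),
                                         pos = integer(0)), depth))
          }
          ridx <- rep(rep(seq_len(n_regions), nb), as.vector(counts))
          bidx <- rep(rep(seq_len(nb), each = n_regions), as.vector(counts))
          pos <- summits[ridx] + offsets[bidx] +
            sample.int(bin_bp, tot, replace = TRUE) - 1L
          read_track(data.frame(chrom = chrom, pos = as.integer(pos),
                                stringsAsFactors = FALSE), depth)
        })
      })
    }
    all_factors <- c(factors, "Nanog")
    reads <- lapply(stats::setNames(all_factors, all_factors), make_track)

    # pseudo-Nanog peak-call samples
    recalled <- matrix(FALSE, n_regions, n_nanog_samples)
    peak_sets <- lapply(seq_len(n_nanog_samples), function(s) {
      frac <- stats::runif(1, recall, min(1, recall + 0.15))
      keep <- sort(sample(n_regions, round(n_regions * frac)))
      recalled[keep, s] <<- TRUE
      lj <- sample(0:50, length(keep), replace = TRUE)
      rj <- sample(0:50, length(keep), replace = TRUE)
      start <- summits[keep] - 150L - lj
      end <- summits[keep] + 150L + rj
      data.frame(chrom = chrom, start = as.integer(start),
                 end = as.integer(end),
                 name = sprintf("peak_s%d_%05d", s, seq_along(keep)),
                 score = 0, strand = ".",
                 sample_id = sprintf("nanog_s%d", s),
                 summit_offset = as.integer(summits[keep] - start),
                 height = round(rnb(length(keep), 30, nb_dispersion)),
                 stringsAsFactors = FALSE)
    })
    names(peak_sets) <- sprintf("nanog_s%d", seq_len(n_nanog_samples))

    regions <- data.frame(chrom = chrom,
                          start = as.integer(summits - half),
                          end = as.integer(summits + half),
                          name = region_id, summit = summits,
                          stringsAsFactors = FALSE)
    truth <- data.frame(region_id = region_id, chrom = chrom,
                        summit = summits, solo = solo, archetype = arch_id,
                        n_recalled = rowSums(recalled),
                        stringsAsFactors = FALSE)
    list(peak_sets = peak_sets, reads = reads, regions = regions,
         truth = truth)
  })
}

#' Simulate broad H3K27me3 domains with planted dynamics classes
#'
#' Plants `n_domains` broad domains on one synthetic chromosome with a
#' dynamics class each: `stable` (constant across conditions),
#' `lif_loss` (mark lost on LIF withdrawal, partially retained under
#' Dox) or `lif_gain` (mark gained on LIF withdrawal).  Sixteen samples
#' (four conditions x four replicates) receive NB counts per domain;
#' one designated replicate is inflated to emulate an outlying sample.
#' Per-sample broad peak calls cover each domain in at least
#' `min_cover` samples, occasionally split in two with a sub-3 kb gap.
#'
#' @param n_domains Number of planted domains.
#' @param class_mixture Named proportions over
#'   `stable`, `lif_loss`, `lif_gain`; must sum to 1.
#' @param n_replicates_per_condition Replicates per condition.
#' @param outlier `NULL`, or `list(sample = <sample_id>, inflation = f)`
#'   with `f > 1`.
#' @param base_mean Median per-domain count at full signal.
#' @param nb_dispersion NB dispersion of domain counts.
#' @param peak_prob Probability a sample's peak caller reports a domain.
#' @param min_cover Minimum number of samples whose peaks cover a domain.
#' @param seed Integer RNG seed.
#' @return list with `peak_sets` (per-sample broadPeak data.frames),
#'   `counts` (domain x sample integer matrix), `samples` (sample
#'   sheet: sample_id, condition, lif, dox), `domains` (planted
#'   intervals) and `truth` (domain_id, class, outlier sample).
#' @export
simulate_k27 <- function(n_domains = 300L,
                         class_mixture = c(stable = 0.6, lif_loss = 0.25,
                                           lif_gain = 0.15),
                         n_replicates_per_condition = 4L,
                         outlier = list(sample = "plusLIF_minusDox_rep1",
                                        inflation = 3),
                         base_mean = 200,
                         nb_dispersion = 0.05,
                         peak_prob = 0.85,
                         min_cover = 8L,
                         seed = 1L) {
  if (abs(sum(class_mixture) - 1) > 1e-8) {
    stop("class mixture must sum to 1", call. = FALSE)
  }
  if (!is.null(outlier) && outlier$inflation <= 1) {
    stop("outlier inflation factor must be > 1", call. = FALSE)
  }
  classes <- c("stable", "lif_loss", "lif_gain")
  stopifnot(all(names(class_mixture) %in% classes))
  conds <- c("plusLIF_minusDox", "plusLIF_plusDox",
             "minusLIF_minusDox", "minusLIF_plusDox")
  # per-class multiplier per condition
  mult <- rbind(stable   = c(1, 1, 1, 1),
                lif_loss = c(1, 1, 0.25, 0.75),
                lif_gain = c(0.3, 0.3, 1, 1))
  colnames(mult) <- conds
  with_seed(seed, {
    chrom <- "chrK"
    len <- as.integer(round(stats::runif(n_domains, 5000, 15000)))
    gap <- as.integer(round(stats::runif(n_domains, 10000, 20000)))
    start <- cumsum(gap) + cumsum(c(0L, len[-n_domains]))
    end <- start + len
    domain_id <- sprintf("domain_%04d", seq_len(n_domains))

    cls_n <- round(n_domains * class_mixture[classes])
    cls_n[is.na(cls_n)] <- 0
    cls_n[1] <- n_domains - sum(cls_n[-1])
    cls <- sample(rep(classes, times = cls_n))

    nrep <- n_replicates_per_condition
    sample_id <- as.vector(t(outer(conds, seq_len(nrep),
                                   function(c, r) sprintf("%s_rep%d", c, r))))
    samples <- data.frame(
      sample_id = sample_id,
      condition = rep(conds, each = nrep),
      lif = rep(c("+", "+", "-", "-"), each = nrep),
      dox = rep(c("-", "+", "-", "+"), each = nrep),
      stringsAsFactors = FALSE)

    base <- exp(stats::rnorm(n_domains, log(base_mean), 0.5))
    mu <- base * mult[cls, samples$condition, drop = FALSE]
    counts <- matrix(rnb(length(mu), as.vector(mu), nb_dispersion),
                     nrow = n_domains,
                     dimnames = list(domain_id, samples$sample_id))
    if (!is.null(outlier)) {
      if (!outlier$sample %in% samples$sample_id) {
        stop("outlier sample not among simulated samples", call. = FALSE)
      }
      counts[, outlier$sample] <- as.integer(
        round(counts[, outlier$sample] * outlier$inflation))
    }

    ns <- nrow(samples)
    cover <- matrix(stats::runif(n_domains * ns) < peak_prob, n_domains, ns)
    short <- which(rowSums(cover) < min_cover)
    for (d in short) {
      need <- min_cover - sum(cover[d, ])
      cover[d, sample(which(!cover[d, ]), need)] <- TRUE
    }
    peak_sets <- lapply(seq_len(ns), function(s) {
      dd <- which(cover[, s])
      if (!length(dd)) return(.empty_peaks())
      js <- sample(0:400, length(dd), replace = TRUE)
      je <- sample(0:400, length(dd), replace = TRUE)
      ps <- pmax(start[dd] - js, 0L)
      pe <- end[dd] + je
      split <- stats::runif(length(dd)) < 0.3 & (pe - ps) > 6000
      rows <- data.frame(chrom = chrom, start = as.integer(ps),
                         end = as.integer(pe),
                         name = sprintf("bp_%s_%04d", samples$sample_id[s], dd),
                         score = 0, strand = ".",
                         sample_id = samples$sample_id[s],
                         summit_offset = NA_integer_,
                         height = 1, stringsAsFactors = FALSE)
      if (any(split)) {
        mid <- (rows$start[split] + rows$end[split]) %/% 2L
        g <- as.integer(stats::runif(sum(split), 200, 2000))
        left <- rows[split, ]; right <- rows[split, ]
        left$end <- mid - g %/% 2L
        right$start <- mid + g %/% 2L
        right$name <- paste0(right$name, "b")
        rows <- rbind(rows[!split, ], left, right)
      }
      rows[order(rows$start), ]
    })
    names(peak_sets) <- samples$sample_id

    domains <- data.frame(chrom = chrom, start = start, end = end,
                          name = domain_id, stringsAsFactors = FALSE)
    truth <- data.frame(domain_id = domain_id, class = cls,
                        stringsAsFactors = FALSE)
    list(peak_sets = peak_sets, counts = counts, samples = samples,
         domains = domains, truth = truth,
         outlier_sample = if (is.null(outlier)) NA_character_ else outlier$sample)
  })
}

#' Default mixture over the 27 response-pattern triples
#'
#' A triple is `(LIF-withdrawal effect, Dox effect in +LIF, Dox effect
#' in -LIF)`, each `up`, `down` or `ns`.  Proportions follow the
#' pattern frequencies reported for ES cells: about half the
#' transcriptome LIF-only responsive, a few percent rescued in each
#' direction, and a small remainder of Dox-only responses.
#'
#' @return Named numeric vector over `"s1:s2:s3"` triples, summing to 1.
#' @export
default_pattern_mixture <- function() {
  c("ns:ns:ns"     = 0.522,
    "up:ns:ns"     = 0.182,
    "down:ns:ns"   = 0.173,
    "down:ns:up"   = 0.047,   # repressed on LIF loss, rescued up by induction
    "up:ns:down"   = 0.034,   # activated on LIF loss, rescued down
    "ns:up:ns"     = 0.010,
    "ns:down:ns"   = 0.010,
    "up:ns:up"     = 0.005,
    "down:ns:down" = 0.005,
    "ns:ns:up"     = 0.006,
    "ns:ns:down"   = 0.006)
}

.states <- c("up", "down", "ns")

.state_sign <- function(s) c(up = 1, down = -1, ns = 0)[s]

#' Simulate RNA-seq counts under a 2x2 LIF x Dox design
#'
#' Counts are NB with mean
#' `baseline * 2^(L*lifMinus + D*dox + I*lifMinus*dox) * libfactor`
#' where the planted coefficients realise each gene's response-pattern
#' triple at `effect_size` log2 units: `L` is the LIF-withdrawal
#' effect, `D` the Dox effect in +LIF and `D + I` the Dox effect in
#' -LIF.  With `peak_link`, genes with a non-null Dox effect have their
#' TSS placed within `d0` of a planted summit and all other genes
#' farther than `10 * d0`.  With `otx2`, a second guide
#' (`NanogOtx2`) is simulated in which a planted fraction of the
#' Dox-responsive genes have their Dox effects cancelled
#' (compensation).
#'
#' @param n_genes Number of genes (ignored when `genes` is given).
#' @param genes Optional gene table (as from [simulate_genome()]).
#' @param pattern_mixture Named proportions over `"s1:s2:s3"` triples.
#' @param effect_size Planted |log2 fold change| for non-null states.
#' @param nb_dispersion NB dispersion.
#' @param n_replicates Replicates per condition (>= 2).
#' @param base_mean_log,base_mean_sd Log-normal baseline parameters.
#' @param peak_link `NULL` or `list(summits = data.frame(chrom, pos),
#'   d0 = bp)`.
#' @param otx2 `NULL` or `list(fraction = f)`: simulate paired
#'   `NanogOtx2` samples with a fraction `f` of Dox-responsive genes
#'   compensated.
#' @param seed Integer RNG seed.
#' @return list with `counts` (gene x sample integer matrix), `samples`
#'   (sample sheet), `genes` (possibly repositioned) and `truth`
#'   (per-gene planted triple, coefficients, linkage and compensation
#'   flags).
#' @export
simulate_expression <- function(n_genes = 2000L,
                                genes = NULL,
                                pattern_mixture = default_pattern_mixture(),
                                effect_size = 2,
                                nb_dispersion = 0.05,
                                n_replicates = 4L,
                                base_mean_log = log(300),
                                base_mean_sd = 0.8,
                                peak_link = NULL,
                                otx2 = NULL,
                                seed = 1L) {
  if (n_replicates < 2) stop("need >= 2 replicates per condition", call. = FALSE)
  if (abs(sum(pattern_mixture) - 1) > 1e-8) {
    stop("pattern mixture must sum to 1", call. = FALSE)
  }
  with_seed(seed, {
    if (is.null(genes)) {
      genes <- data.frame(
        gene_id = sprintf("gene_%05d", seq_len(n_genes)),
        chrom = "chrE",
        start = as.integer(seq_len(n_genes) * 50000L),
        end = as.integer(seq_len(n_genes) * 50000L + 2000L),
        strand = "+", stringsAsFactors = FALSE)
      genes$tss <- genes$start
    }
    n_genes <- nrow(genes)
    pat_n <- stats::rmultinom(1, n_genes, pattern_mixture)[, 1]
    drawn <- sample(rep(names(pattern_mixture), times = pat_n))
    sp <- do.call(rbind, strsplit(drawn, ":"))
    L <- .state_sign(sp[, 1]) * effect_size
    D <- .state_sign(sp[, 2]) * effect_size
    I <- .state_sign(sp[, 3]) * effect_size - D  # so D + I hits the drawn state
    # planted states follow the realised coefficients (all ns when
    # effect_size = 0)
    sgn <- function(v) c("down", "ns", "up")[sign(v) + 2]
    s1 <- sgn(L); s2 <- sgn(D); s3 <- sgn(D + I)
    pattern <- paste(s1, s2, s3, sep = ":")

    base <- exp(stats::rnorm(n_genes, base_mean_log, base_mean_sd))
    base <- pmax(base, 25)  # keep genes above the expression filter

    conds <- expand.grid(lif = c("+", "-"), dox = c("-", "+"),
                         stringsAsFactors = FALSE)
    guides <- "Nanog"
    compensated <- rep(FALSE, n_genes)
    if (!is.null(otx2)) {
      guides <- c("Nanog", "NanogOtx2")
      dox_resp <- which(s2 != "ns" | s3 != "ns")
      n_comp <- round(length(dox_resp) * otx2$fraction)
      compensated[sample(dox_resp, n_comp)] <- TRUE
    }
    sheets <- list(); mats <- list()
    for (g in guides) {
      Dg <- D; Ig <- I
      if (g == "NanogOtx2") { Dg[compensated] <- 0; Ig[compensated] <- 0 }
      for (ci in seq_len(nrow(conds))) {
        lm <- as.numeric(conds$lif[ci] == "-")
        dx <- as.numeric(conds$dox[ci] == "+")
        mu_g <- base * 2^(L * lm + Dg * dx + Ig * lm * dx)
        for (r in seq_len(n_replicates)) {
          lib <- stats::runif(1, 0.7, 1.3)
          sid <- sprintf("%s_%sLIF_%sDox_rep%d", g,
                         ifelse(conds$lif[ci] == "+", "plus", "minus"),
                         ifelse(conds$dox[ci] == "+", "plus", "minus"), r)
          sheets[[sid]] <- data.frame(
            sample_id = sid, cell_system = "SunTag", lif = conds$lif[ci],
            dox = conds$dox[ci], guide = g,
            library_factor = lib, stringsAsFactors = FALSE)
          mats[[sid]] <- rnb(n_genes, mu_g * lib, nb_dispersion)
        }
      }
    }
    counts <- do.call(cbind, mats)
    storage.mode(counts) <- "integer"
    rownames(counts) <- genes$gene_id
    samples <- do.call(rbind, sheets)
    rownames(samples) <- NULL

    linked <- rep(FALSE, n_genes)
    d0 <- NA_real_
    if (!is.null(peak_link)) {
      d0 <- peak_link$d0
      summ <- peak_link$summits
      linked <- s2 != "ns" | s3 != "ns"
      ch <- summ$chrom[1]
      pos_max <- max(summ$pos)
      n_link <- sum(linked)
      # place linked TSSs beyond the summit span so the planted
      # nearest-summit distance is exactly U(0, d0] (an interior
      # placement would sit next to a neighbouring summit instead)
      tss_link <- as.integer(pos_max + round(stats::runif(n_link, 1, d0)))
      far_start <- pos_max + 10 * d0
      tss_far <- as.integer(round(far_start + d0 +
                                    seq_len(sum(!linked)) * 5000))
      genes$chrom <- ch
      genes$tss[linked] <- tss_link
      genes$tss[!linked] <- tss_far
      genes$start <- genes$tss
      genes$end <- genes$tss + 2000L
    }

    truth <- data.frame(gene_id = genes$gene_id, s1 = s1, s2 = s2, s3 = s3,
                        pattern = pattern, L = L, D = D, I = I,
                        base_mean = base, linked = linked,
                        compensated = compensated, stringsAsFactors = FALSE)
    list(counts = counts, samples = samples, genes = genes, truth = truth,
         d0 = d0)
  })
}
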