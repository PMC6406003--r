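# Consensus binding-region construction and ATAC cut-site tracks.

#' Build consensus binding regions from multiple peak-call samples
#'
#' Peaks overlapping the blacklist by >= 1 bp or lying on excluded
#' chromosomes are removed; the remainder are union-merged across
#' samples (>= 1 bp overlap merges) and merged regions supported by
#' fewer than `min_support` distinct samples are dropped.
#'
#' @param peak_sets Named list of peak-call data.frames (one per
#'   sample, as from [read_intervals()]), or a single data.frame with a
#'   `sample_id` column.
#' @param blacklist Optional interval data.frame; peaks overlapping it
#'   are discarded before merging.
#' @param excluded_chroms Chromosomes to drop entirely.
#' @param min_support Minimum number of distinct supporting samples.
#' @return data.frame of non-overlapping, sorted regions with columns
#'   `chrom`, `start`, `end`, `name`, `support`, plus `summit` and
#'   `mean_height_rpm` (NA until [locate_summits()] /
#'   [height_filter()] run).
#' @export
build_consensus <- function(peak_sets, blacklist = NULL,
                            excluded_chroms = c("chrM", "chrY"),
                            min_support = 2L) {
  if (min_support < 1) stop("min_support must be >= 1", call. = FALSE)
  if (is.data.frame(peak_sets)) {
    peak_sets <- split(peak_sets, peak_sets$sample_id)
  }
  if (!length(peak_sets)) stop("need at least one peak set", call. = FALSE)
  peak_sets <- lapply(peak_sets, function(p) {
    check_intervals(p, "peak set")
    p <- p[!p$chrom %in% excluded_chroms, , drop = FALSE]
    if (!is.null(blacklist) && nrow(p)) {
      bl <- intervals_to_granges(check_intervals(blacklist, "blacklist"))
      hit <- GenomicRanges::countOverlaps(intervals_to_granges(p), bl) > 0
      p <- p[!hit, , drop = FALSE]
    }
    p
  })
  pooled <- do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end")]))
  if (!nrow(pooled)) return(.empty_consensus())
  merged <- GenomicRanges::reduce(intervals_to_granges(pooled))
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
  out$name <- sprintf("region_%05d", seq_len(nrow(out)))
  out$support <- sup[o]
  out$summit <- rep(NA_integer_, nrow(out))
  out$mean_height_rpm <- rep(NA_real_, nrow(out))
  rownames(out) <- NULL
  out
}

# sparse per-bp coverage of tracks within regions: returns a data.frame
# (region index, pos, value) where value is the rpm-weighted read-start
# count summed over tracks
.sparse_region_coverage <- function(regions, tracks) {
  gr <- intervals_to_granges(regions)
  parts <- lapply(tracks, function(t) {
    t <- as_read_track(t)
    rd <- t$reads
    if (!nrow(rd)) return(NULL)
    hits <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(rd$chrom,
                             IRanges::IRanges(rd$pos + 1L, width = 1L)), gr)
    if (!length(hits)) return(NULL)
    data.frame(reg = S4Vectors::subjectHits(hits),
               pos = rd$pos[S4Vectors::queryHits(hits)],
               w = 1e6 / t$library_size)
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts)) {
    return(data.frame(reg = integer(0), pos = integer(0), value = numeric(0)))
  }
  all <- do.call(rbind, parts)
  key <- all$reg * 2^31 + all$pos          # exact in doubles
  agg <- rowsum(all$w, group = key)
  k <- as.numeric(rownames(agg))
  data.frame(reg = as.integer(k %/% 2^31), pos = as.integer(k %% 2^31),
             value = agg[, 1])
}

.empty_consensus <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), support = integer(0),
             summit = integer(0), mean_height_rpm = numeric(0),
             stringsAsFactors = FALSE)
}

# max per-bp read-start count of one track within each region (raw reads)
.region_max_cov <- function(regions, track) {
  track <- as_read_track(track)
  raw <- read_track(track$reads, 1e6)  # unit weight per read
  cov <- .sparse_region_coverage(regions, list(raw))
  out <- numeric(nrow(regions))
  if (nrow(cov)) {
    mx <- tapply(cov$value, cov$reg, max)
    out[as.integer(names(mx))] <- mx
  }
  out
}

#' Filter consensus regions on mean peak height (rpm)
#'
#' Per-sample height is the maximum per-bp read-start count within the
#' region scaled to reads per million; regions whose mean height over
#' samples is below `min_rpm` are dropped (inclusive `>=` retains a
#' region exactly at threshold).
#'
#' @param regions Consensus region data.frame.
#' @param tracks Named list of [read_track()]s (or data.frames of read
#'   starts), one per sample.
#' @param library_sizes Optional numeric vector overriding each
#'   track's library size.
#' @param min_rpm Minimum mean height in reads per million.
#' @return The retained regions with `mean_height_rpm` populated.
#' @export
height_filter <- function(regions, tracks, library_sizes = NULL,
                          min_rpm = 1.0) {
  tracks <- lapply(tracks, as_read_track)
  if (!is.null(library_sizes)) {
    if (any(library_sizes <= 0)) stop("library_size must be > 0", call. = FALSE)
    tracks <- Map(function(t, l) read_track(t$reads, l), tracks, library_sizes)
  }
  if (any(vapply(tracks, function(t) t$library_size, 0) <= 0)) {
    stop("library_size must be > 0", call. = FALSE)
  }
  heights <- vapply(tracks, function(t)
    .region_max_cov(regions, t) * 1e6 / t$library_size,
    numeric(nrow(regions)))
  if (nrow(regions) == 1L) heights <- matrix(heights, nrow = 1L)
  mean_h <- rowMeans(heights)
  out <- regions[mean_h >= min_rpm, , drop = FALSE]
  out$mean_height_rpm <- mean_h[mean_h >= min_rpm]
  rownames(out) <- NULL
  out
}

#' Locate the summit of a region from a coverage vector
#'
#' The summit is the position of maximum coverage; ties break leftmost.
#'
#' @param region One-row interval data.frame (0-based half-open).
#' @param coverage Numeric vector of per-bp signal over the region
#'   (length `end - start`).
#' @return Absolute summit position (bp, 0-based).
#' @export
locate_summit <- function(region, coverage) {
  width <- region$end - region$start
  if (width < 1) stop("empty region", call. = FALSE)
  if (length(coverage) != width) {
    stop("coverage length must equal region width", call. = FALSE)
  }
  region$start + which.max(coverage) - 1L
}

#' Locate summits for all regions from averaged read coverage
#'
#' Builds the per-bp coverage of each region as the average of the
#' given tracks' rpm-scaled read-start counts, then places each summit
#' at the maximum (leftmost tie-break).
#'
#' @param regions Region data.frame.
#' @param tracks List of [read_track()]s whose averaged coverage
#'   defines the summit (typically the induced factor's samples).
#' @return `regions` with the `summit` column filled.
#' @export
locate_summits <- function(regions, tracks) {
  tracks <- lapply(tracks, as_read_track)
  cov <- .sparse_region_coverage(regions, tracks)
  regions$summit <- NA_integer_
  if (nrow(cov)) {
    # leftmost maximum: order by region, decreasing value, increasing pos
    o <- order(cov$reg, -cov$value, cov$pos)
    first <- !duplicated(cov$reg[o])
    regions$summit[cov$reg[o][first]] <- cov$pos[o][first]
  }
  regions$summit[is.na(regions$summit)] <-
    ((regions$start + regions$end) %/% 2L)[is.na(regions$summit)]
  regions
}

#' Build an ATAC cut-site track from paired-end fragments
#'
#' For a fragment `[s, e)` the Tn5 cut sites are `s + 4` and
#' `(e - 1) - 4` (both coordinates shifted 4 bp inwards); the cut-site
#' base and the two surrounding bases each receive +1.  The track is
#' scaled to rpm by the fragment count.  Use [average_cutsite_tracks()]
#' to average replicates.
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open); every fragment must be at least 9 bp so the two cut
#'   sites do not cross.
#' @param chrom_lengths Optional named lengths; defaults to the maximum
#'   marked coordinate + 1 per chromosome.
#' @param normalize Scale to rpm by fragment count (default); set
#'   `FALSE` for raw mark counts.
#' @return Named list (per chromosome) of per-bp numeric vectors
#'   (index i is base i-1), class `cutsite_track`.
#' @export
atac_cutsites <- function(fragments, chrom_lengths = NULL, normalize = TRUE) {
  check_intervals(fragments, "fragments")
  if (nrow(fragments) && any(fragments$end - fragments$start < 9)) {
    stop("fragment shorter than 9 bp: cut sites would cross", call. = FALSE)
  }
  left <- fragments$start + 4L
  right <- (fragments$end - 1L) - 4L
  marks <- data.frame(
    chrom = rep(fragments$chrom, times = 6),
    pos = c(left - 1L, left, left + 1L, right - 1L, right, right + 1L))
  marks <- marks[marks$pos >= 0, , drop = FALSE]
  chroms <- unique(fragments$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch)
      as.integer(max(marks$pos[marks$chrom == ch], 0) + 1), 0L)
  }
  scale <- if (normalize && nrow(fragments)) 1e6 / nrow(fragments) else 1
  track <- lapply(chroms, function(ch) {
    v <- numeric(chrom_lengths[[ch]])
    p <- marks$pos[marks$chrom == ch]
    p <- p[p < length(v)]
    tb <- tabulate(p + 1L, nbins = length(v))
    v + tb * scale
  })
  names(track) <- chroms
  structure(track, class = "cutsite_track")
}

#' Average cut-site tracks over replicates
#'
#' @param tracks List of `cutsite_track` objects over the same
#'   chromosomes (shorter vectors are zero-padded).
#' @return A `cutsite_track` of per-bp means.
#' @export
average_cutsite_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  chroms <- unique(unlist(lapply(tracks, names)))
  out <- lapply(chroms, function(ch) {
    vs <- lapply(tracks, function(t) t[[ch]] %||% numeric(0))
    len <- max(lengths(vs))
    vs <- lapply(vs, function(v) c(v, numeric(len - length(v))))
    Reduce(`+`, vs) / length(tracks)
  })
  names(out) <- chroms
  structure(out, class = "cutsite_track")
}
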