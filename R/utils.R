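# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a 0-based half-open interval table to a GRanges
#'
#' All internal coordinates are 0-based half-open (BED-native); GRanges
#' is 1-based closed, so the conversion happens only here and in
#' [granges_to_intervals()].
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return A [GenomicRanges::GRanges] object.
#' @keywords internal
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges   = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' @rdname intervals_to_granges
#' @param gr A GRanges object.
#' @keywords internal
granges_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so package functions never perturb the user's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Negative-binomial sampler parameterised by mean and dispersion alpha,
# with Var = mu + alpha * mu^2 (the convention used by the DE model).
# dispersion = 0 degenerates to Poisson.
rnb <- function(n, mu, dispersion) {
  stopifnot(all(mu >= 0), dispersion >= 0)
  if (dispersion == 0) {
    stats::rpois(n, lambda = mu)
  } else {
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
}

# Validate an interval table (0-based half-open).
check_intervals <- function(df, context = "interval table") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s lacks column(s): %s", context,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df)) {
    if (any(is.na(df$chrom)) || any(!nzchar(df$chrom))) {
      stop(sprintf("%s: empty chromosome name", context), call. = FALSE)
    }
    if (any(df$start < 0)) {
      stop(sprintf("%s: negative start coordinate", context), call. = FALSE)
    }
    if (any(df$start >= df$end)) {
      stop(sprintf("%s: start >= end", context), call. = FALSE)
    }
  }
  invisible(df)
}

# A read track: genomic read-start placements plus the library size used
# for rpm scaling.  `reads` has columns chrom, pos (0-based bp).
#' Construct a read track
#'
#' A read track couples read-start placements (0-based bp) with the
#' library size used for reads-per-million scaling.
#'
#' @param reads data.frame with columns `chrom` and `pos`.
#' @param library_size positive number of mapped reads in the library
#'   (may exceed `nrow(reads)` when only on-region reads are kept).
#' @return An object of class `read_track`.
#' @export
read_track <- function(reads, library_size) {
  stopifnot(is.data.frame(reads), all(c("chrom", "pos") %in% names(reads)))
  if (!is.numeric(library_size) || length(library_size) != 1 ||
      is.na(library_size) || library_size <= 0) {
    stop("library_size must be a single positive number", call. = FALSE)
  }
  structure(list(reads = reads, library_size = library_size),
            class = "read_track")
}

as_read_track <- function(x) {
  if (inherits(x, "read_track")) return(x)
  if (is.data.frame(x)) return(read_track(x, library_size = max(nrow(x), 1)))
  stop("expected a read_track or a data.frame of read starts", call. = FALSE)
}
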