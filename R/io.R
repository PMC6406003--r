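# Readers and writers for the BED-family formats, count matrices, sample
# sheets and FASTA.  All internal coordinates are 0-based half-open;
# conversion to and from 1-based coordinates happens only at format
# boundaries (GRanges construction).

.dialect_ncol <- c(BED3 = 3L, BED6 = 6L, narrowPeak = 10L, broadPeak = 9L)

#' Read peak calls from a BED-family file
#'
#' Supports BED3, BED6, ENCODE narrowPeak (10 columns) and broadPeak
#' (9 columns).  Comment (`#`), `track` and `browser` lines are skipped.
#' narrowPeak column 10 is parsed as the summit offset relative to the
#' interval start (`-1` means absent); broadPeak has no summit.
#'
#' @param path File path.
#' @param dialect One of `"BED3"`, `"BED6"`, `"narrowPeak"`,
#'   `"broadPeak"`.
#' @param sample_id Sample identifier attached to every record;
#'   defaults to the file name without extension.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `score`, `strand`, `sample_id`,
#'   `summit_offset` (`NA` when absent) and `height` (signalValue for
#'   narrowPeak/broadPeak, else the score).
#' @export
read_intervals <- function(path,
                           dialect = c("BED6", "BED3", "narrowPeak", "broadPeak"),
                           sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(.empty_peaks(sample_id))

  fields <- strsplit(lines[idx], "\t| +")
  ncols <- .dialect_ncol[[dialect]]
  nf <- lengths(fields)
  if (any(nf != ncols)) {
    bad <- idx[which(nf != ncols)[1]]
    stop(sprintf("parse error at line %d of %s: expected %d columns for %s, found %d",
                 bad, path, ncols, dialect, nf[which(nf != ncols)[1]]),
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1]]
    stop(sprintf("parse error at line %d of %s: non-integer coordinate", bad, path),
         call. = FALSE)
  }
  if (any(start < 0) || any(start >= end)) {
    bad <- idx[which(start < 0 | start >= end)[1]]
    stop(sprintf("validation error at line %d of %s: require 0 <= start < end",
                 bad, path), call. = FALSE)
  }
  name <- if (ncols >= 4) m[, 4] else rep(".", nrow(m))
  score <- if (ncols >= 5) suppressWarnings(as.numeric(m[, 5])) else numeric(nrow(m))
  strand <- if (ncols >= 6) m[, 6] else rep(".", nrow(m))
  if (any(!strand %in% c("+", "-", "."))) {
    bad <- idx[which(!strand %in% c("+", "-", "."))[1]]
    stop(sprintf("validation error at line %d of %s: strand must be +, - or .",
                 bad, path), call. = FALSE)
  }
  height <- if (ncols >= 7) suppressWarnings(as.numeric(m[, 7])) else score
  summit <- rep(NA_integer_, nrow(m))
  if (dialect == "narrowPeak") {
    summit <- suppressWarnings(as.integer(m[, 10]))
    summit[!is.na(summit) & summit < 0] <- NA_integer_
    bad_sum <- !is.na(summit) & summit >= (end - start)
    if (any(bad_sum)) {
      bad <- idx[which(bad_sum)[1]]
      stop(sprintf("validation error at line %d of %s: summit offset outside interval",
                   bad, path), call. = FALSE)
    }
  }
  data.frame(chrom = m[, 1], start = start, end = end, name = name,
             score = score, strand = strand, sample_id = sample_id,
             summit_offset = summit, height = height,
             stringsAsFactors = FALSE)
}

.empty_peaks <- function(sample_id = character(0)) {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), score = numeric(0), strand = character(0),
             sample_id = character(0), summit_offset = integer(0),
             height = numeric(0), stringsAsFactors = FALSE)
}

#' Write peak calls to a BED-family file
#'
#' Records are sorted by `(chrom, start)` before writing.  The fields a
#' dialect carries round-trip exactly through [read_intervals()].
#'
#' @param records data.frame as returned by [read_intervals()].
#' @param path Output path.
#' @inheritParams read_intervals
#' @return `path`, invisibly.
#' @export
write_intervals <- function(records, path,
                            dialect = c("BED6", "BED3", "narrowPeak", "broadPeak")) {
  dialect <- match.arg(dialect)
  check_intervals(records, "write_intervals input")
  records <- records[order(records$chrom, records$start, records$end), , drop = FALSE]
  n <- nrow(records)
  name <- records$name %||% rep(".", n)
  score <- records$score %||% numeric(n)
  strand <- records$strand %||% rep(".", n)
  height <- records$height %||% score
  summit <- records$summit_offset %||% rep(NA_integer_, n)
  cols <- switch(dialect,
    BED3 = list(records$chrom, records$start, records$end),
    BED6 = list(records$chrom, records$start, records$end, name, score, strand),
    broadPeak = list(records$chrom, records$start, records$end, name, score,
                     strand, height, rep(-1, n), rep(-1, n)),
    narrowPeak = list(records$chrom, records$start, records$end, name, score,
                      strand, height, rep(-1, n), rep(-1, n),
                      ifelse(is.na(summit), -1L, summit))
  )
  df <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an integer count matrix
#'
#' Expects a TSV with a header row of sample ids and gene ids in the
#' first column.  Real-valued entries (e.g. estimated counts) are
#' rounded half to even; negative values and duplicated gene ids are
#' errors.
#'
#' @param path TSV file path.
#' @return Integer matrix with gene ids as row names and sample ids as
#'   column names.
#' @export
read_count_matrix <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf[-1])) > 1 || (length(nf) > 1 && any(nf[-1] != nf[2]))) {
    stop("ragged rows in count matrix: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicated gene id in count matrix: ",
         genes[duplicated(genes)][1], call. = FALSE)
  }
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("non-numeric value in count matrix", call. = FALSE)
  if (any(mat < 0)) stop("negative count in count matrix", call. = FALSE)
  mat <- round(mat)  # round() is round-half-to-even
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes
  mat
}

#' Read a sample sheet
#'
#' TSV with at least a `sample_id` column; typical condition columns
#' are `cell_system`, `lif`, `dox`, `guide` and `library_size`.
#'
#' @param path TSV file path.
#' @return data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("sample sheet needs a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in sample sheet", call. = FALSE)
  }
  if ("library_size" %in% names(df) && any(df$library_size <= 0)) {
    stop("library_size must be positive", call. = FALSE)
  }
  df
}

#' Read DNA sequences from a FASTA file
#'
#' Sequences are uppercased and restricted to the alphabet ACGTN.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase DNA sequences (names are
#'   the first word of each header).
#' @export
read_fasta <- function(path) {
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("FASTA parse error in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(out))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    stop("non-nucleotide character (allowed: ACGTN) in FASTA record ",
         names(out)[bad][1], call. = FALSE)
  }
  out
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
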