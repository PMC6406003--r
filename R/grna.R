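# SpCas9 gRNA candidate enumeration, sequence filters and a
# mismatch-histogram off-target counter.  PAM semantics: "NGG" -- the
# first PAM base matches anything (including N), the two G positions
# must be literal G (an N in the subject never matches).

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.check_dna <- function(s, what = "sequence") {
  if (grepl("[^ACGTN]", s)) {
    stop(what, " contains characters outside ACGTN", call. = FALSE)
  }
  s
}

.gc_percent <- function(proto) {
  ch <- strsplit(proto, "")[[1]]
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

# + strand scan of one sequence: 0-based protospacer starts where a
# 20-mer is followed by NGG
.scan_plus <- function(chars) {
  L <- length(chars)
  if (L < 23) return(integer(0))
  starts <- seq_len(L - 22)               # 1-based protospacer start
  g1 <- chars[starts + 21] == "G"
  g2 <- chars[starts + 22] == "G"
  starts[g1 & g2] - 1L                    # 0-based
}

#' Enumerate SpCas9 guide candidates on both strands
#'
#' Every 20-mer immediately followed by an NGG PAM, on the + strand
#' and (as CCN + 20 nt on +) on the - strand.  No filters are applied.
#'
#' @param sequence DNA string (ACGTN), length >= 23.
#' @return data.frame: `protospacer` (20 nt, guide orientation),
#'   `strand`, `position` (0-based start of the protospacer on the +
#'   reference) and `gc_percent`.
#' @export
enumerate_guides <- function(sequence) {
  sequence <- toupper(sequence)
  .check_dna(sequence)
  L <- nchar(sequence)
  if (L < 23) stop("sequence shorter than 23 nt", call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  plus0 <- .scan_plus(chars)
  rc <- .revcomp(sequence)
  rchars <- strsplit(rc, "")[[1]]
  minus_rc0 <- .scan_plus(rchars)
  rows <- list()
  if (length(plus0)) {
    rows$plus <- data.frame(
      protospacer = substring(sequence, plus0 + 1, plus0 + 20),
      strand = "+", position = plus0, stringsAsFactors = FALSE)
  }
  if (length(minus_rc0)) {
    # protospacer occupies + interval [L - p - 20, L - p) for rc start p
    pos <- L - minus_rc0 - 20L
    rows$minus <- data.frame(
      protospacer = substring(rc, minus_rc0 + 1, minus_rc0 + 20),
      strand = "-", position = pos, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protospacer = character(0), strand = character(0),
               position = integer(0), stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  out$gc_percent <- vapply(out$protospacer, .gc_percent, 0, USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter guide candidates on GC content and homopolymer runs
#'
#' GC bounds are inclusive; a candidate fails the homopolymer filter
#' if any single base is repeated more than `max_homopolymer` times in
#' a row (a run of `max_homopolymer + 1` or more).
#'
#' @param candidates data.frame from [enumerate_guides()].
#' @param gc_range Inclusive GC bounds (percent).
#' @param max_homopolymer Longest allowed single-base run.
#' @return `candidates` with logical columns `gc_pass`,
#'   `homopolymer_pass` and `pass`.
#' @export
filter_guides <- function(candidates, gc_range = c(35, 85),
                          max_homopolymer = 3L) {
  gc <- candidates$gc_percent
  candidates$gc_pass <- gc >= gc_range[1] & gc <= gc_range[2]
  run_re <- sprintf("A{%d}|C{%d}|G{%d}|T{%d}",
                    max_homopolymer + 1L, max_homopolymer + 1L,
                    max_homopolymer + 1L, max_homopolymer + 1L)
  candidates$homopolymer_pass <- !grepl(run_re, candidates$protospacer)
  candidates$pass <- candidates$gc_pass & candidates$homopolymer_pass
  candidates
}

# mismatch counts of `guide` against all PAM-adjacent windows of a
# character vector (one strand); N in the subject never matches
.scan_offtargets <- function(guide_chars, chars, max_mismatches) {
  hits <- integer(max_mismatches + 1L)
  L <- length(chars)
  if (L < 23) return(hits)
  starts <- seq_len(L - 22)
  pam_ok <- chars[starts + 21] == "G" & chars[starts + 22] == "G"
  starts <- starts[pam_ok]
  if (!length(starts)) return(hits)
  mm <- integer(length(starts))
  for (j in 1:20) {
    sub <- chars[starts + j - 1L]
    mm <- mm + as.integer(sub != guide_chars[j] | sub == "N")
  }
  mm <- mm[mm <= max_mismatches]
  if (length(mm)) {
    tb <- tabulate(mm + 1L, nbins = max_mismatches + 1L)
    hits <- hits + tb
  }
  hits
}

#' Count PAM-adjacent off-target sites by mismatch number
#'
#' Slides the 20-nt guide over both strands of every subject sequence;
#' sites require an NGG PAM.  Returns the histogram of Hamming
#' mismatches 0..`max_mismatches` over the protospacer (an N in the
#' subject never matches).  The exclusion decision (e.g. any hit with
#' <= 2 mismatches beyond the intended site) is left to the caller.
#'
#' @param guide 20-nt protospacer (ACGT).
#' @param subjects Named character vector of subject sequences (ACGTN).
#' @param max_mismatches Largest mismatch count tallied.
#' @return Integer vector named `"0"` .. `"max_mismatches"`.
#' @export
count_offtargets <- function(guide, subjects, max_mismatches = 4L) {
  guide <- toupper(guide)
  if (nchar(guide) != 20) stop("guide length must be 20", call. = FALSE)
  .check_dna(guide, "guide")
  gch <- strsplit(guide, "")[[1]]
  hits <- integer(max_mismatches + 1L)
  for (s in subjects) {
    s <- toupper(s)
    .check_dna(s, "subject")
    hits <- hits + .scan_offtargets(gch, strsplit(s, "")[[1]], max_mismatches)
    hits <- hits + .scan_offtargets(gch, strsplit(.revcomp(s), "")[[1]],
                                    max_mismatches)
  }
  stats::setNames(hits, as.character(0:max_mismatches))
}
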