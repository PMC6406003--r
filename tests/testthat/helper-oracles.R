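# Independent oracles used across test files.  All are deliberately
# naive re-derivations, sharing no code with the implementation.

# naive interval merging by linear scan after sorting; gap <= `gap`
# merges transitively
naive_merge <- function(df, gap = 0L) {
  if (!nrow(df)) return(df[, c("chrom", "start", "end")])
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  cur <- df[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(df))[-1]) {
    r <- df[i, ]
    if (r$chrom == cur$chrom && r$start - cur$end <= gap) {
      cur$end <- max(cur$end, r$end)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- r[, c("chrom", "start", "end")]
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Rand index by exhaustive pair enumeration
rand_oracle <- function(a, b) {
  n <- length(a)
  agree <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      agree <- agree + as.integer((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

# Benjamini-Hochberg by sort and cumulative minimum
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# one-sided hypergeometric enrichment p by direct tail summation over
# the 2x2 table (a = responsive within, b = responsive beyond,
# c = non-responsive within, d = non-responsive beyond)
hyper_tail_oracle <- function(a, b, cc, d) {
  m <- a + cc
  n <- b + d
  k <- a + b
  hi <- min(m, k)
  sum(vapply(a:hi, function(x)
    choose(m, x) * choose(n, k - x), 0)) / choose(m + n, k)
}

# brute-force guide enumeration: scan every window on both strands
revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

enumerate_oracle <- function(seq) {
  L <- nchar(seq)
  rows <- list()
  for (i in seq_len(max(L - 22, 0))) {
    pam <- substr(seq, i + 20, i + 22)
    if (substr(pam, 2, 2) == "G" && substr(pam, 3, 3) == "G") {
      rows[[length(rows) + 1L]] <- data.frame(
        protospacer = substr(seq, i, i + 19), strand = "+",
        position = i - 1L, stringsAsFactors = FALSE)
    }
  }
  rc <- revcomp_chr(seq)
  for (i in seq_len(max(L - 22, 0))) {
    pam <- substr(rc, i + 20, i + 22)
    if (substr(pam, 2, 2) == "G" && substr(pam, 3, 3) == "G") {
      rows[[length(rows) + 1L]] <- data.frame(
        protospacer = substr(rc, i, i + 19), strand = "-",
        position = L - (i - 1L) - 20L, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$position, out$strand), ]
}

offtarget_oracle <- function(guide, subject, max_mm = 4L) {
  hits <- integer(max_mm + 1L)
  for (s in c(subject, revcomp_chr(subject))) {
    L <- nchar(s)
    for (i in seq_len(max(L - 22, 0))) {
      if (substr(s, i + 21, i + 21) != "G" ||
          substr(s, i + 22, i + 22) != "G") next
      win <- strsplit(substr(s, i, i + 19), "")[[1]]
      g <- strsplit(guide, "")[[1]]
      mm <- sum(win != g | win == "N")
      if (mm <= max_mm) hits[mm + 1L] <- hits[mm + 1L] + 1L
    }
  }
  hits
}

# random peak-call table for round-trip and merge tests
random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 100000L,
                         width = c(50L, 400L), sample_id = "s1") {
  start <- sample.int(max_pos, n, replace = TRUE)
  w <- sample(seq(width[1], width[2]), n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + w,
             name = sprintf("p%04d", seq_len(n)),
             score = round(runif(n, 0, 100), 2),
             strand = sample(c("+", "-", "."), n, replace = TRUE),
             sample_id = sample_id,
             summit_offset = as.integer(pmin(w - 1L, sample(0:49, n, TRUE))),
             height = round(runif(n, 1, 50), 3),
             stringsAsFactors = FALSE)
}

# map recovered consensus regions to planted truth by nearest summit
match_planted <- function(regions, truth) {
  vapply(regions$summit, function(s) which.min(abs(truth$summit - s)), 0L)
}
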