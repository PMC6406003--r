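# Broad-domain merging, read counting, replicate QC, dynamics
# clustering and gene embedding.

mkpeak <- function(chrom, start, end, sid) {
  data.frame(chrom = chrom, start = start, end = end, name = "p",
             score = 0, strand = ".", sample_id = sid,
             summit_offset = NA_integer_, height = 1,
             stringsAsFactors = FALSE)
}

test_that("merge_domains applies the gap rule and support threshold", {
  sets <- lapply(1:8, function(i)
    rbind(mkpeak("chr1", 1000, 2000, paste0("s", i)),
          mkpeak("chr1", 4999, 6000, paste0("s", i)),   # gap 2999 -> merge
          mkpeak("chr1", 9001 + 1, 9500, paste0("s", i))))  # gap 3001 -> split
  dom <- merge_domains(sets, gap_bp = 3000, min_support = 8)
  expect_equal(nrow(dom), 2L)
  expect_equal(dom$start, c(1000L, 9002L))
  expect_equal(dom$end, c(6000L, 9500L))
  # domain in only 7 of 16 samples is dropped at min_support 8
  sets16 <- lapply(1:16, function(i) {
    base <- mkpeak("chr1", 100, 5000, paste0("s", i))
    if (i <= 7) base <- rbind(base, mkpeak("chr2", 100, 5000, paste0("s", i)))
    base
  })
  dom2 <- merge_domains(sets16, min_support = 8)
  expect_equal(dom2$chrom, "chr1")
  expect_error(merge_domains(sets, gap_bp = -1), "gap_bp")
})

test_that("merge_domains equals the naive oracle and is idempotent", {
  set.seed(91)
  sets <- lapply(1:8, function(s) {
    n <- 38
    start <- sample.int(2e5, n)
    mkpeak(sample(c("chr1", "chr2"), n, replace = TRUE), start,
           start + sample(500:5000, n, replace = TRUE), paste0("s", s))
  })
  dom <- merge_domains(sets, gap_bp = 3000, min_support = 1)
  oracle <- naive_merge(do.call(rbind, sets), gap = 3000)
  expect_equal(dom$start, oracle$start)
  expect_equal(dom$end, oracle$end)
  dom$sample_id <- "m"
  again <- merge_domains(rep(list(dom), 8), gap_bp = 0, min_support = 1)
  expect_equal(again$start, dom$start)
  expect_equal(again$end, dom$end)
})

test_that("read counting into domains is half-open and matches a scan", {
  dom <- data.frame(chrom = "chr1", start = c(100L, 500L),
                    end = c(200L, 600L), name = c("d1", "d2"))
  tr <- read_track(data.frame(chrom = "chr1",
                              pos = c(100L, 199L, 200L, 599L, 600L)), 1e6)
  cnt <- count_reads_in_domains(list(s1 = tr), dom)
  expect_equal(unname(cnt[, 1]), c(2L, 1L))  # start included, end excluded
  empty <- read_track(data.frame(chrom = character(0), pos = integer(0)), 1e6)
  expect_true(all(count_reads_in_domains(list(s1 = empty), dom) == 0))
  set.seed(14)
  pos <- sample.int(1000, 300, replace = TRUE)
  trr <- read_track(data.frame(chrom = "chr1", pos = pos), 1e6)
  domr <- data.frame(chrom = "chr1", start = c(0L, 250L, 700L),
                     end = c(100L, 600L, 1000L),
                     name = c("a", "b", "c"))
  cnt <- count_reads_in_domains(list(s = trr), domr)
  naive <- vapply(seq_len(3), function(d)
    sum(pos >= domr$start[d] & pos < domr$end[d]), 0L)
  expect_equal(unname(cnt[, 1]), naive)
})

test_that("outlier QC flags strict within-condition dominance", {
  set.seed(8)
  n <- 100
  a <- rpois(n, 50); b <- a
  dominate <- sample(n, 70)
  a[dominate] <- a[dominate] + 5L
  b[-dominate] <- b[-dominate] + 5L
  counts <- cbind(A = a, B = b)
  qc <- flag_outlier_replicates(counts, c("c1", "c1"), frac_threshold = 0.6)
  expect_true(qc$excluded[qc$sample == "A"])
  expect_false(qc$excluded[qc$sample == "B"])
  expect_equal(qc$frac_max[qc$sample == "A"], 0.7)
  # all-tied counts: fractions 0, none excluded
  tied <- matrix(5L, 20, 4, dimnames = list(NULL, paste0("s", 1:4)))
  qct <- flag_outlier_replicates(tied, rep("c1", 4))
  expect_true(all(qct$frac_max == 0))
  expect_false(any(qct$excluded))
  # exchangeable replicates: fractions near 1/4, none excluded
  ex <- matrix(rnbinom(200 * 4, mu = 200, size = 20), 200, 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  qce <- flag_outlier_replicates(ex, rep("c1", 4))
  expect_true(all(abs(qce$frac_max - 0.25) < 0.12))
  expect_false(any(qce$excluded))
  expect_error(flag_outlier_replicates(counts, c("c1", "c2")), "replicates")
})

test_that("dynamics clustering labels planted classes", {
  sk <- simulate_k27(n_domains = 90, seed = 13)
  qc <- flag_outlier_replicates(sk$counts, sk$samples$condition)
  ret <- qc$sample[!qc$excluded]
  expect_true(sk$outlier_sample %in% qc$sample[qc$excluded])
  lif_map <- setNames(sk$samples$lif[!duplicated(sk$samples$condition)],
                      sk$samples$condition[!duplicated(sk$samples$condition)])
  dyn <- cluster_domain_dynamics(
    sk$counts[, ret, drop = FALSE],
    sk$samples$condition[match(ret, sk$samples$sample_id)],
    lif = lif_map, seed = 6)
  expect_gte(mclust::adjustedRandIndex(dyn$classes, sk$truth$class), 0.9)
  # label orientation: planted lif_loss domains mostly called lif_loss
  loss <- sk$truth$class == "lif_loss"
  expect_gt(mean(dyn$classes[loss] == "lif_loss"), 0.9)
  # equal condition means give a flat normalised profile
  flat <- matrix(100L, 10, 8,
                 dimnames = list(sprintf("d%02d", 1:10), paste0("s", 1:8)))
  flat[1, ] <- c(10L, 10L, 100L, 100L, 10L, 10L, 100L, 100L)
  dynf <- cluster_domain_dynamics(
    flat, rep(c("a", "b", "c", "d"), each = 2),
    lif = c(a = "+", b = "+", c = "-", d = "-"), k = 2, seed = 2)
  expect_true(all(dynf$profiles[2, ] == 1))
  expect_error(cluster_domain_dynamics(flat * 0L,
                                       rep(c("a", "b", "c", "d"), each = 2),
                                       lif = c(a = "+", b = "+", c = "-",
                                               d = "-"), k = 2),
               "all-zero")
})

test_that("gene embedding follows the overlap and free-promoter rules", {
  dom <- data.frame(chrom = "chr1", start = c(1000L, 20000L, 40000L),
                    end = c(5000L, 25000L, 45000L),
                    name = c("d1", "d2", "d3"))
  genes <- data.frame(
    gene_id = c("overlap1bp", "free_promoter", "blocked", "neighbour", "far"),
    chrom = "chr1",
    start = c(4999L, 28000L, 48000L, 44000L, 90000L),
    end = c(6000L, 30000L, 50000L, 46000L, 95000L),
    tss = c(4999L, 28500L, 48500L, 44000L, 90000L))
  out <- assign_genes_to_domains(genes, dom, tss_window = 4000)
  got <- setNames(out$embedded, out$gene_id)
  expect_true(got[["overlap1bp"]])      # 1 bp body overlap
  expect_true(got[["free_promoter"]])   # d2 within 3.5 kb, touching no gene
  # d3 overlaps gene "neighbour", so it cannot embed "blocked" by proximity
  expect_false(got[["blocked"]])
  expect_true(got[["neighbour"]])       # via its own body overlap
  expect_false(got[["far"]])
})
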