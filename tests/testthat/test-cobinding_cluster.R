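# Trace quantification, solo/co-binding split, normalisation, k-means,
# Rand index and k selection.

make_sm <- function(h, regions = NULL, bin_bp = 10L) {
  # h: array [factor, condition, region, bin]
  n_reg <- dim(h)[3]
  if (is.null(regions)) {
    regions <- data.frame(chrom = "chr1",
                          start = seq_len(n_reg) * 1000L,
                          end = seq_len(n_reg) * 1000L + dim(h)[4] * bin_bp,
                          name = sprintf("r%03d", seq_len(n_reg)),
                          summit = seq_len(n_reg) * 1000L + 500L)
  }
  structure(list(h = h, regions = regions,
                 window_bp = dim(h)[4] * bin_bp, bin_bp = bin_bp),
            class = "signal_matrix")
}

test_that("quantify_traces bins, rpm-scales and averages replicates", {
  reg <- data.frame(chrom = "chr1", start = 1000L, end = 2000L,
                    name = "r1", summit = 1500L)
  # 10 read starts in one bin with library 1e7 -> 1.0 rpm
  t1 <- read_track(data.frame(chrom = "chr1", pos = rep(1500L, 10)), 1e7)
  sm <- quantify_traces(reg, list(F1 = list(plus = list(t1))),
                        window_bp = 1000, bin_bp = 10)
  expect_equal(dim(sm$h), c(1, 1, 1, 100))
  expect_equal(sm$h[1, 1, 1, 51], 1.0)   # bin covering offset [500,510)
  expect_equal(sum(sm$h), 1.0)
  # two replicates with 1.0 and 3.0 rpm average to 2.0
  t3 <- read_track(data.frame(chrom = "chr1", pos = rep(1500L, 30)), 1e7)
  sm2 <- quantify_traces(reg, list(F1 = list(plus = list(t1, t3))),
                         window_bp = 1000, bin_bp = 10)
  expect_equal(sm2$h[1, 1, 1, 51], 2.0)
  # no reads anywhere -> all-zero matrix
  t0 <- read_track(data.frame(chrom = character(0), pos = integer(0)), 1e6)
  sm0 <- quantify_traces(reg, list(F1 = list(plus = list(t0))),
                         window_bp = 1000, bin_bp = 10)
  expect_true(all(sm0$h == 0))
  # region truncated at the chromosome edge is dropped with a warning
  reg_edge <- data.frame(chrom = "chr1", start = 0L, end = 300L,
                         name = "r0", summit = 100L)
  expect_warning(
    out <- quantify_traces(rbind(reg_edge, reg),
                           list(F1 = list(plus = list(t1))),
                           window_bp = 1000, bin_bp = 10),
    "dropped")
  expect_equal(dim(out$h)[3], 1L)
})

test_that("solo/co-binding split uses an inclusive rpm threshold", {
  h <- array(1.0, dim = c(2, 2, 3, 4),
             dimnames = list(c("Esrrb", "Oct4"), c("plus", "minus"),
                             NULL, NULL))
  h[1, 2, 2, 3] <- 3.0    # Esrrb max 3.0 rpm in -Dox only
  h[2, 1, 3, 1] <- 2.7    # exactly at threshold
  sm <- make_sm(h)
  sp <- split_solo_cobinding(sm, threshold_rpm = 2.7)
  expect_identical(sp$solo, "r001")
  expect_identical(sort(sp$cobinding), c("r002", "r003"))
  expect_error(split_solo_cobinding(sm, threshold_rpm = 0), "> 0")
})

test_that("trace normalisation fixes the max at 1 and is scale-invariant", {
  set.seed(21)
  h <- array(runif(2 * 2 * 30 * 50, 0, 5), dim = c(2, 2, 30, 50),
             dimnames = list(c("A", "B"), c("plus", "minus"), NULL, NULL))
  sm <- make_sm(h)
  ts <- normalize_traces(sm, flank_bp = 250)
  expect_true(all(abs(apply(ts$tau_bar, 1, max) - 1) == 0))
  expect_true(all(ts$tau_bar >= 0 & ts$tau_bar <= 1))
  # uniform trace for one factor -> tau_bar all 1
  hu <- array(3.7, dim = c(1, 2, 4, 50),
              dimnames = list("A", c("plus", "minus"), NULL, NULL))
  tsu <- normalize_traces(make_sm(hu), flank_bp = 250)
  expect_true(all(tsu$tau_bar == 1))
  # power-of-two global rescaling of one factor: bit-identical tau_bar
  h4 <- h
  h4[1, , , ] <- h[1, , , ] * 4
  ts4 <- normalize_traces(make_sm(h4), flank_bp = 250)
  expect_identical(ts4$tau_bar, ts$tau_bar)
  # arbitrary-scalar rescaling: equal within numerical tolerance
  h10 <- h
  h10[2, , , ] <- h[2, , , ] * 10
  ts10 <- normalize_traces(make_sm(h10), flank_bp = 250)
  expect_equal(ts10$tau_bar, ts$tau_bar, tolerance = 1e-12)
  # sigma = 0 names the factor
  hz <- h
  hz[1, 1, , ] <- 0
  expect_error(normalize_traces(make_sm(hz), flank_bp = 250), "A")
})

test_that("a hand-computed two-factor example matches step-by-step arithmetic", {
  # 2 factors, 2 regions, 2 positions, 2 conditions
  h <- array(0, dim = c(2, 2, 2, 2),
             dimnames = list(c("A", "B"), c("plus", "minus"), NULL, NULL))
  h["A", "plus", 1, ] <- c(2, 4); h["A", "minus", 1, ] <- c(1, 1)
  h["A", "plus", 2, ] <- c(6, 0); h["A", "minus", 2, ] <- c(2, 0)
  h["B", "plus", 1, ] <- c(10, 10); h["B", "minus", 1, ] <- c(5, 5)
  h["B", "plus", 2, ] <- c(0, 20); h["B", "minus", 2, ] <- c(0, 10)
  sm <- make_sm(h, bin_bp = 1L)
  ts <- normalize_traces(sm, flank_bp = 1L)
  sigA <- 2 + 4 + 6 + 0   # +Dox occupancy of A
  sigB <- 10 + 10 + 0 + 20
  tau1 <- c(2, 4, 1, 1) / sigA
  tau1 <- c(tau1, c(10, 10, 5, 5) / sigB)
  expect_equal(unname(ts$tau_bar[1, ]), tau1 / max(tau1))
  tau2 <- c(c(6, 0, 2, 0) / sigA, c(0, 20, 0, 10) / sigB)
  expect_equal(unname(ts$tau_bar[2, ]), tau2 / max(tau2))
  expect_equal(unname(ts$sigma), c(sigA, sigB))
})

test_that("k-means recovers separated clouds and behaves at the edges", {
  set.seed(33)
  x <- rbind(matrix(rnorm(50 * 4, 0, 0.1), ncol = 4),
             matrix(rnorm(50 * 4, 10, 0.1), ncol = 4))
  rownames(x) <- sprintf("p%03d", 1:100)
  km <- kmeans_cluster(x, 2, seed = 9)
  expect_equal(length(unique(km$assignment[1:50])), 1L)
  expect_equal(length(unique(km$assignment[51:100])), 1L)
  expect_false(km$assignment[1] == km$assignment[51])
  # k = n gives inertia 0
  xs <- x[1:8, ]
  expect_equal(kmeans_cluster(xs, 8, seed = 2)$inertia, 0)
  # inertia non-increasing along Lloyd iterations on random data
  xr <- matrix(rnorm(200 * 6), ncol = 6)
  km_r <- kmeans_cluster(xr, 5, seed = 4, n_init = 1)
  expect_true(all(diff(km_r$inertia_trace) <= 1e-9))
  expect_error(kmeans_cluster(xs, 20, seed = 1), "k <= ")
})

test_that("rand_index matches hand values and the pair-enumeration oracle", {
  expect_equal(rand_index(c(1, 1, 2), c(1, 1, 2)), 1.0)
  expect_equal(rand_index(c(1, 1, 2), c(1, 2, 2)), 1 / 3)
  expect_equal(rand_index(c(1, 1, 1), c(1, 2, 3)), 0.0)
  set.seed(55)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(rand_index(a, b), rand_oracle(a, b))
    expect_equal(rand_index(a, b), rand_index(b, a))
  }
  # 1 iff identical up to relabelling
  expect_equal(rand_index(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1.0)
  expect_error(rand_index(setNames(1:3, c("a", "b", "c")),
                          setNames(1:3, c("a", "b", "x"))), "mismatched")
})

test_that("select_k reports stability and recommends a small k on 3 clusters", {
  set.seed(66)
  x <- rbind(matrix(rnorm(40 * 5, 0, 0.2), ncol = 5),
             matrix(rnorm(40 * 5, 6, 0.2), ncol = 5),
             matrix(rnorm(40 * 5, -6, 0.2), ncol = 5))
  rownames(x) <- sprintf("r%03d", 1:120)
  rep3 <- select_k(x, k_range = c(2, 5), seed = 3)
  expect_true(all(rep3$table$rand_next >= 0 & rep3$table$rand_next <= 1))
  expect_gte(rep3$table$rand_next[rep3$table$k == 3], 0.9)
  expect_lte(rep3$recommended_k, 4)
  single <- select_k(x, k_range = c(2, 2), seed = 3)
  expect_equal(nrow(single$table), 1L)
  expect_equal(single$table$k, 2)
  # identical duplicated regions only: every RI is 1
  dup <- matrix(1, 30, 4)
  rownames(dup) <- sprintf("d%02d", 1:30)
  repd <- select_k(dup, k_range = c(2, 4), seed = 1)
  expect_true(all(repd$table$rand_next == 1))
  expect_error(select_k(x, k_range = c(2, 1)), "degenerate")
})

test_that("cluster summaries equal group-wise means", {
  set.seed(12)
  h <- array(runif(1 * 2 * 6 * 10), dim = c(1, 2, 6, 10),
             dimnames = list("A", c("plus", "minus"), NULL, NULL))
  sm <- make_sm(h)
  model <- structure(list(k = 2,
                          assignment = setNames(c(1, 1, 1, 2, 2, 2),
                                                sm$regions$name)),
                     class = "cluster_model")
  cs <- cluster_summary(model, sm, order_factor = "A")
  p1 <- cs$profiles[cs$profiles$cluster == 1 &
                      cs$profiles$condition == "plus", "mean"]
  expect_equal(p1, colMeans(matrix(h[1, 1, 1:3, ], nrow = 3)))
  p2 <- cs$profiles[cs$profiles$cluster == 2 &
                      cs$profiles$condition == "minus", "mean"]
  expect_equal(p2, colMeans(matrix(h[1, 2, 4:6, ], nrow = 3)))
  # a cluster of identical traces has its trace as the mean
  hsame <- h; hsame[1, , 1:3, ] <- hsame[1, , rep(1, 3), ]
  cs2 <- cluster_summary(model, make_sm(hsame))
  q1 <- cs2$profiles[cs2$profiles$cluster == 1 &
                       cs2$profiles$condition == "plus", "mean"]
  expect_equal(q1, unname(hsame[1, 1, 1, ]))
})
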