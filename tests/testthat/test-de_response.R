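# Normalisation, NB-GLM contrasts, LRT, concordance, response patterns,
# compensation and z-scores.

simple_sheet <- function(n_per = 4) {
  data.frame(sample_id = sprintf("s%02d", seq_len(2 * n_per)),
             cell_system = "SunTag",
             lif = "+",
             dox = rep(c("-", "+"), each = n_per),
             guide = "Nanog", stringsAsFactors = FALSE)
}

test_that("size factors are symmetric, scale-equivariant, and filter rules hold", {
  counts <- matrix(c(10L, 20L, 30L, 10L, 20L, 30L), ncol = 2,
                   dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sheet <- data.frame(sample_id = c("s1", "s2"), dox = c("-", "+"))
  nf <- normalize_and_filter(counts, sheet, condition = c("a", "b"))
  expect_equal(unname(nf$size_factors), c(1, 1))
  doubled <- counts; doubled[, 2] <- counts[, 2] * 2L
  nf2 <- normalize_and_filter(doubled, sheet, condition = c("a", "b"))
  expect_equal(unname(nf2$size_factors[2] / nf2$size_factors[1]), 2)
  # gene with normalised counts (12, 11, 10) in one condition is
  # retained; constant housekeeping rows pin the size factors at 1
  cc <- rbind(gA = c(12L, 11L, 10L, 1L, 1L, 1L),
              gB = c(5L, 5L, 5L, 5L, 5L, 5L),
              gC = c(50L, 50L, 50L, 50L, 50L, 50L),
              gD = c(200L, 200L, 200L, 200L, 200L, 200L))
  colnames(cc) <- sprintf("s%d", 1:6)
  sheet6 <- data.frame(sample_id = sprintf("s%d", 1:6),
                       dox = rep(c("-", "+"), each = 3))
  nf3 <- normalize_and_filter(cc, sheet6, condition = rep(c("x", "y"), each = 3))
  expect_equal(unname(nf3$size_factors), rep(1, 6))
  expect_true("gA" %in% nf3$retained)
  expect_false("gB" %in% nf3$retained)
  zero <- matrix(c(0L, 1L, 1L, 0L), 2)
  colnames(zero) <- c("s1", "s2")
  expect_error(normalize_and_filter(zero,
                                    data.frame(sample_id = c("s1", "s2")),
                                    condition = c("a", "b")),
               "all-positive")
})

test_that("NB GLM agrees with the Poisson GLM in the small-dispersion limit", {
  set.seed(31)
  sheet <- simple_sheet()
  sheet$dox_plus <- factor(sheet$dox, levels = c("-", "+"))
  X <- model.matrix(~ dox_plus, sheet)
  mu <- 100 * 2^(c(0, 1)[as.integer(sheet$dox_plus)] * 1.5)
  counts <- matrix(rpois(length(mu) * 30, rep(mu, each = 30)), nrow = 30)
  colnames(counts) <- sheet$sample_id
  rownames(counts) <- paste0("g", 1:30)
  res <- fit_nb_contrasts(counts, sheet, ~ dox_plus,
                          contrasts = list(dox = c(0, 1)),
                          size_factors = rep(1, 8), dispersion = 1e-10)
  for (g in sample(30, 5)) {
    pf <- glm(counts[g, ] ~ sheet$dox_plus, family = poisson())
    expect_equal(res$dox$log2fc[g], unname(coef(pf)[2]) / log(2),
                 tolerance = 1e-3)
  }
})

test_that("Wald machinery honours the zero contrast and flags convergence", {
  set.seed(32)
  sheet <- simple_sheet()
  sheet$dox_plus <- factor(sheet$dox, levels = c("-", "+"))
  counts <- matrix(rnbinom(8 * 10, mu = 50, size = 20), nrow = 10)
  colnames(counts) <- sheet$sample_id
  rownames(counts) <- paste0("g", 1:10)
  res <- fit_nb_contrasts(counts, sheet, ~ dox_plus,
                          contrasts = list(null = c(0, 0)),
                          size_factors = rep(1, 8))
  expect_true(all(res$null$stat == 0))
  expect_true(all(res$null$pvalue == 1))
  expect_error(fit_nb_contrasts(counts, sheet, ~ dox_plus,
                                contrasts = list(bad = c(0, 1, 0))),
               "length")
})

test_that("the LRT rejects planted effects and enforces nesting", {
  set.seed(33)
  n_per <- 4
  sheet <- data.frame(
    sample_id = sprintf("s%02d", 1:(4 * n_per)),
    cell_system = rep(c("SunTag", "i44"), each = 2 * n_per),
    dox = rep(rep(c("-", "+"), each = n_per), 2))
  sheet$cell <- factor(sheet$cell_system)
  sheet$dox_plus <- factor(sheet$dox, levels = c("-", "+"))
  mu <- 100 * 2^(2 * (sheet$dox_plus == "+"))
  strong <- matrix(rnbinom(16 * 20, mu = rep(mu, each = 20), size = 20),
                   nrow = 20)
  nullm <- matrix(rnbinom(16 * 20, mu = 100, size = 20), nrow = 20)
  counts <- rbind(strong, nullm)
  colnames(counts) <- sheet$sample_id
  rownames(counts) <- paste0("g", 1:40)
  lrt <- lrt_combined(counts, sheet, full = ~ cell + dox_plus + cell:dox_plus,
                      reduced = ~ cell, size_factors = rep(1, 16))
  expect_true(all(lrt$fdr[1:20] < 0.05))
  expect_equal(unique(lrt$df), 2)
  expect_error(lrt_combined(counts, sheet, full = ~ cell, reduced = ~ cell),
               "nested")
})

test_that("BH adjustment matches the sort-and-cummin oracle", {
  set.seed(34)
  for (i in 1:200) {
    p <- runif(sample(5:80, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_oracle(p))
  }
})

test_that("responsive_union tracks provenance and direction", {
  genes <- paste0("g", 1:12)
  mk <- function(sig, lfc = 1) {
    data.frame(gene = genes, log2fc = lfc,
               fdr = ifelse(genes %in% sig, 0.01, 0.5))
  }
  a <- mk(paste0("g", 1:3))
  b <- mk(paste0("g", 4:7), lfc = -1)
  lrt <- data.frame(gene = genes,
                    fdr = ifelse(genes %in% paste0("g", 8:12), 0.01, 0.9))
  u <- responsive_union(list(suntag = a, i44 = b, lrt = lrt))
  expect_equal(nrow(u), 12L)  # three disjoint sets of 3, 4, 5
  expect_equal(u$selected_by[u$gene == "g9"], "lrt")
  expect_equal(u$direction[u$gene == "g1"], 1)
  expect_equal(u$direction[u$gene == "g5"], -1)
  expect_equal(u$direction[u$gene == "g9"], 0)  # LRT carries no sign
  expect_false(any(u$sign_conflict))
})

test_that("3x3 concordance reproduces chi-square, Cramer's V and Fisher p", {
  # perfectly diagonal table
  a <- rep(c("up", "down", "ns"), times = c(5, 6, 7))
  co <- concordance_3x3(a, a)
  expect_equal(co$cramers_v, 1.0)
  expect_equal(co$df, 4L)
  # independence: expected-products table gives chi-square 0
  b <- rep(c("up", "down", "ns"), times = 6)[1:18]
  ind <- concordance_3x3(rep(c("up", "down", "ns"), each = 6), b)
  expect_lt(ind$chisq, 1e-10)
  # hand table vs direct summation
  tab <- matrix(c(10, 2, 3, 1, 12, 2, 4, 3, 20), 3, byrow = TRUE)
  sa <- rep(rep(c("up", "down", "ns"), times = 3),
            times = as.vector(t(tab)))
  sb <- rep(c("up", "down", "ns"), times = rowSums(matrix(
    as.vector(t(tab)), 3, byrow = TRUE)))
  sb <- unlist(lapply(1:3, function(i)
    rep(c("up", "down", "ns"), times = tab[i, ])))
  sa <- rep(c("up", "down", "ns"), times = rowSums(tab))
  co2 <- concordance_3x3(sa, sb)
  N <- sum(tab)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / N
  chi_hand <- sum((tab - exp_tab)^2 / exp_tab)
  expect_equal(co2$chisq, chi_hand)
  expect_equal(co2$cramers_v, sqrt(chi_hand / (N * 2)))
  # zero margin -> chi-square not applicable
  z <- concordance_3x3(rep("ns", 10), rep(c("up", "ns"), 5))
  expect_true(is.na(z$chisq))
  expect_false(is.na(z$fisher_p))
})

test_that("pattern classification applies state and rescue rules", {
  genes <- paste0("g", 1:4)
  mk <- function(lfc, fdr) data.frame(gene = genes, log2fc = lfc, fdr = fdr)
  lif <- mk(c(2, -2, 0.5, 2), c(0.01, 0.01, 0.5, 0.01))
  doxp <- mk(c(0, 0, 0, 0.3), c(0.9, 0.9, 0.9, 0.9))
  doxm <- mk(c(-2, 2, 1, 0.2), c(0.01, 0.01, 0.5, 0.6))
  cls <- classify_patterns(lif, doxp, doxm)
  p <- cls$patterns
  expect_equal(p$pattern, c("up:ns:down", "down:ns:up", "ns:ns:ns",
                            "up:ns:ns"))
  expect_equal(p$rescue_category,
               c("rescued_up", "rescued_down", "other", "not_rescued_up"))
  expect_equal(sum(cls$pattern_counts), 4L)
  expect_equal(length(cls$pattern_counts), 27L)
})

test_that("compensation calls flip or silence the induction state", {
  genes <- paste0("g", 1:3)
  pa <- data.frame(gene = genes, lif = "up", dox_plus_lif = "ns",
                   dox_minus_lif = c("down", "down", "ns"))
  pb <- data.frame(gene = genes, lif = "up", dox_plus_lif = "ns",
                   dox_minus_lif = c("ns", "down", "ns"))
  comp <- otx2_compensation(pa, pb)
  expect_equal(comp$compensated, c(TRUE, FALSE, FALSE))
})

test_that("z-scores use the population denominator", {
  m <- matrix(c(0, 2, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  z <- zscore_matrix(m)
  expect_equal(unname(z["a", ]), c(-1, 1))  # sd_n of (0,2) is 1
  expect_equal(unname(z["b", ]), c(0, 0))
  set.seed(35)
  r <- matrix(rnorm(50), 5, 10)
  zr <- zscore_matrix(r)
  expect_equal(unname(rowMeans(zr)), rep(0, 5))
  expect_equal(unname(sqrt(rowMeans(zr^2))), rep(1, 5))
})

test_that("planted guide compensation and guide-difference tests are recovered", {
  se <- simulate_expression(n_genes = 400, otx2 = list(fraction = 0.5),
                            seed = 44)
  fit_guide <- function(g) {
    keep <- se$samples$guide == g
    sheet <- se$samples[keep, ]
    counts <- se$counts[, sheet$sample_id]
    nf <- normalize_and_filter(counts, sheet)
    sheet$lif_minus <- factor(ifelse(sheet$lif == "-", "minus", "plus"),
                              levels = c("plus", "minus"))
    sheet$dox_plus <- factor(ifelse(sheet$dox == "+", "plus", "minus"),
                             levels = c("minus", "plus"))
    X <- model.matrix(~ lif_minus * dox_plus, sheet)
    cvec <- function(nm) {
      v <- setNames(numeric(ncol(X)), colnames(X)); v[nm] <- 1; unname(v)
    }
    de <- fit_nb_contrasts(
      counts[nf$retained, ], sheet, ~ lif_minus * dox_plus,
      contrasts = list(
        lif = cvec("lif_minusminus"),
        doxp = cvec("dox_plusplus"),
        doxm = cvec(c("dox_plusplus", "lif_minusminus:dox_plusplus"))),
      size_factors = nf$size_factors)
    classify_patterns(de$lif, de$doxp, de$doxm)
  }
  pn <- fit_guide("Nanog")
  pd <- fit_guide("NanogOtx2")
  comp <- otx2_compensation(pn, pd)
  tr <- se$truth[match(comp$gene, se$truth$gene_id), ]
  dox_resp <- tr$s3 != "ns"
  planted_frac <- mean(tr$compensated[dox_resp])
  got_frac <- mean(comp$compensated[dox_resp])
  expect_lt(abs(got_frac - planted_frac), 0.1)
  # the between-guide Wald contrast detects the compensated genes
  gd <- guide_difference_test(se$counts, se$samples)
  hit <- gd$fdr[match(tr$gene_id[dox_resp & tr$compensated], gd$gene)] < 0.05
  expect_gte(mean(hit, na.rm = TRUE), 0.8)
})
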