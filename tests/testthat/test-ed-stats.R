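test_that("base frequencies are depth ratios and reject zero-depth loci", {
  expect_equal(base_frequencies(c(30, 10, 0, 0)),
               c(A = 0.75, C = 0.25, G = 0, T = 0))
  expect_equal(base_frequencies(c(7, 0, 0, 0)), c(A = 1, C = 0, G = 0, T = 0))
  expect_error(base_frequencies(c(0, 0, 0, 0)), "zero total depth")
  expect_error(base_frequencies(c(-1, 2, 0, 0)), "negative")
  m <- random_depths(50)
  f <- base_frequencies(m)
  expect_equal(unname(rowSums(f)), rep(1, 50), tolerance = 1e-12)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("ED matches analytic values, is symmetric and bounded", {
  expect_identical(euclidean_distance(c(0.3, 0.3, 0.4, 0), c(0.3, 0.3, 0.4, 0)), 0)
  expect_equal(euclidean_distance(c(1, 0, 0, 0), c(0, 1, 0, 0)), sqrt(2))
  expect_equal(euclidean_distance(c(0.75, 0.25, 0, 0), c(0.25, 0.75, 0, 0)),
               sqrt(0.5))
  set.seed(11)
  f1 <- base_frequencies(random_depths(500))
  f2 <- base_frequencies(random_depths(500))
  ed <- euclidean_distance(f1, f2)
  expect_equal(ed, euclidean_distance(f2, f1))
  expect_true(all(ed >= 0 & ed <= sqrt(2)))
  expect_identical(euclidean_distance(f1, f1), rep(0, 500))
})

test_that("ed_power applies ed^k and preserves candidate rankings", {
  expect_identical(ed_power(0), 0)
  expect_identical(ed_power(1), 1)
  expect_equal(ed_power(sqrt(0.5)), 2^(-5 / 2), tolerance = 1e-12)
  expect_equal(ed_power(0.9, k = 2), 0.81)
  expect_error(ed_power(0.5, k = 0), "k must be")
  expect_error(ed_power(-0.1), "non-negative")
  set.seed(12)
  ed <- sort(runif(100, 0, sqrt(2)))
  for (k in c(1, 2, 5)) expect_false(is.unsorted(ed_power(ed, k)))
})

test_that("candidate classification is inclusive at the threshold", {
  expect_true(classify_candidate(0.74))
  expect_true(classify_candidate(sqrt(2)))
  expect_false(classify_candidate(0))
  expect_false(classify_candidate(0.7399999))
  expect_equal(classify_candidate(c(0.2, 0.8), threshold = 0.5), c(FALSE, TRUE))
  expect_error(classify_candidate(0.5, threshold = 0), "positive")
})

test_that("hypergeometric tail matches hand enumeration and phyper", {
  expect_equal(hypergeom_tail(2, 2, m_total = 10, k_assoc = 5), 10 / 45,
               tolerance = 1e-12)
  expect_identical(hypergeom_tail(3, 0, m_total = 10, k_assoc = 5), 1)
  # every locus associated: any y <= n is certain
  expect_equal(hypergeom_tail(c(4, 4, 4), c(0, 2, 4), m_total = 12,
                              k_assoc = 12), rep(1, 3))
  # independent cross-check against stats::phyper on assorted cases
  set.seed(13)
  for (i in 1:50) {
    m <- sample(5:200, 1)
    k <- sample(0:m, 1)
    n <- sample(1:m, 1)
    y <- sample(0:n, 1)
    expect_equal(hypergeom_tail(n, y, m, k),
                 max(stats::phyper(y - 1, k, m - k, n, lower.tail = FALSE),
                     .Machine$double.xmin),
                 tolerance = 1e-10)
  }
  expect_error(hypergeom_tail(5, 6, m_total = 10, k_assoc = 5), "<=")
  expect_error(hypergeom_tail(11, 1, m_total = 10, k_assoc = 5), "<=")
})

test_that("hypergeometric tail is 1 at y = 0, non-increasing in y, never 0", {
  for (k in c(0, 3, 9)) {
    p <- hypergeom_tail(rep(9, 10), 0:9, m_total = 20, k_assoc = k)
    expect_identical(p[1], 1)
    expect_true(all(diff(p) <= 1e-15))
    expect_true(all(p > 0))
  }
  # deep tail underflows to the smallest positive double, not to zero
  expect_gt(hypergeom_tail(50, 50, m_total = 5000, k_assoc = 50), 0)
})

test_that("BH adjustment matches the step-up definition and is equivariant", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(14)
  for (i in 1:25) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm], tolerance = 1e-15)
  }
})

test_that("significance screen keeps strict FDR subset in canonical order", {
  tab <- data.frame(unigene = c("u3", "u1", "u2"),
                    fdr = c(0.2, 0.005, 0.01))
  out <- screen_significant(tab, fdr_cutoff = 0.01)
  expect_identical(out$unigene, "u1")  # 0.01 excluded: strict cutoff
  expect_true(all(out$fdr < 0.01))
  expect_identical(nrow(screen_significant(tab[0, ])), 0L)
  tab$fdr <- 1
  expect_identical(nrow(screen_significant(tab)), 0L)
  tied <- data.frame(unigene = c("b", "a"), fdr = c(0.001, 0.001))
  expect_identical(screen_significant(tied)$unigene, c("a", "b"))
})
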