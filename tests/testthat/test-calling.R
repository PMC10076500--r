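# Destranding, coverage filtering, the binomial status caller and weighted
# methylation.

test_that("destranding merges CpG dyads and keeps orphans", {
  x <- tibble::tibble(
    contig = "c1", pos = c(10L, 11L), strand = c("+", "-"),
    m = c(3L, 2L), n = c(5L, 5L)
  )
  out <- destrand(x)
  expect_equal(nrow(out), 1L)
  expect_equal(out$pos, 10L)
  expect_equal(out$m, 5L)
  expect_equal(out$n, 10L)

  solo <- destrand(x[1, ])
  expect_equal(c(solo$pos, solo$m, solo$n), c(10L, 3L, 5L))

  # swapping the input rows changes nothing
  expect_equal(destrand(x[2:1, ]), out, ignore_attr = TRUE)

  # an orphan minus record becomes a site at pos - 1
  expect_message(orph <- destrand(x[2, ]), "no plus partner")
  expect_equal(orph$pos, 10L)
  expect_equal(attr(orph, "orphans"), 1L)
})

test_that("coverage filtering removes low and outlying sites", {
  base <- tibble::tibble(
    sample = "s1", contig = "c1", pos = 1:1000, m = 0L,
    n = rep(20L, 1000)
  )
  base$n[500] <- 200L  # one 10x outlier
  out <- filter_coverage(base)
  cut <- stats::quantile(base$n, 0.999, type = 7)
  expect_false(500 %in% out$pos)
  expect_equal(nrow(out), sum(base$n >= 10 & base$n <= cut))

  low <- tibble::tibble(sample = "s1", contig = "c1", pos = 1:100,
                        m = 0L, n = c(9L, rep(10L, 99)))
  kept <- filter_coverage(low)
  expect_equal(kept$pos, 2:100)  # n = 9 removed, n = 10 (boundary) kept

  allten <- tibble::tibble(sample = "s1", contig = "c1", pos = 1:50,
                           m = 0L, n = 10L)
  expect_equal(nrow(filter_coverage(allten)), 50L)
  expect_equal(nrow(filter_coverage(allten[0, ])), 0L)
})

test_that("status caller equals the exact binomial tail oracle", {
  grid <- expand.grid(n = 1:30, e = c(0.005, 0.05, 0.2))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]
    e <- grid$e[i]
    sites <- tibble::tibble(sample = "s", contig = "c1", pos = seq_len(n + 1),
                            m = 0:n, n = n)
    calls <- call_methylation(sites, error = e)
    oracle <- vapply(0:n, binom_tail_oracle, numeric(1), n = n, e = e)
    expect_equal(calls$p_value, oracle, tolerance = 1e-12)
    # monotone non-increasing in m
    expect_true(all(diff(calls$p_value) <= 1e-15))
  }
})

test_that("status caller edge cases and q-value contract", {
  sites <- tibble::tibble(sample = "s", contig = "c1", pos = 1:4,
                          m = c(0L, 3L, 5L, 0L), n = c(10L, 10L, 10L, 0L))
  calls <- call_methylation(sites, error = 0.05)
  expect_equal(nrow(calls), 3L)  # n = 0 skipped
  expect_equal(calls$p_value[calls$pos == 1], 1)
  expect_equal(calls$p_value[calls$pos == 2], binom_tail_oracle(3, 10, 0.05),
               tolerance = 1e-12)
  expect_equal(round(calls$p_value[calls$pos == 2], 4), 0.0115)
  expect_true(all(calls$q_value >= calls$p_value - 1e-15))
  expect_equal(calls$status == "methylated", calls$q_value < 0.05)
})

test_that("per-sample and global BH scopes differ when samples differ", {
  sites <- dplyr::bind_rows(
    tibble::tibble(sample = "a", contig = "c1", pos = 1:20, m = 5L, n = 10L),
    tibble::tibble(sample = "b", contig = "c1", pos = 1:2, m = 0L, n = 10L)
  )
  per <- call_methylation(sites, error = 0.05, scope = "sample")
  glob <- call_methylation(sites, error = 0.05, scope = "global")
  qa <- per$q_value[per$sample == "a"]
  qg <- glob$q_value[glob$sample == "a"]
  expect_false(isTRUE(all.equal(qa, qg)))
})

test_that("never-methylated sites are dropped from the analysis set", {
  sites <- dplyr::bind_rows(
    tibble::tibble(sample = c("a", "b"), contig = "c1", pos = 1L,
                   m = c(9L, 0L), n = 10L),
    tibble::tibble(sample = c("a", "b"), contig = "c1", pos = 2L,
                   m = 0L, n = 10L)
  )
  calls <- call_methylation(sites, error = 0.01)
  kept <- drop_never_methylated(calls)
  expect_setequal(unique(kept$pos), 1L)
  expect_equal(attr(kept, "dropped_sites"), 1L)
})

test_that("weighted methylation is the count-weighted pooled level", {
  feats <- tibble::tibble(feature_id = "f1", contig = "c1", start = 1,
                          end = 100)
  mk <- function(m, n) {
    tibble::tibble(sample = "s", contig = "c1", pos = seq_along(m),
                   m = m, n = n)
  }
  expect_equal(weighted_methylation(mk(c(10, 5), c(10, 5)), feats)$w, 1)
  expect_equal(weighted_methylation(mk(c(5, 0), c(10, 10)), feats)$w, 0.25)
  expect_equal(weighted_methylation(mk(0, 10), feats)$w, 0)
  # no covered CpG -> absent, not 0/0
  far <- tibble::tibble(sample = "s", contig = "c1", pos = 500L,
                        m = 1L, n = 2L)
  expect_equal(nrow(weighted_methylation(far, feats)), 0L)

  # pooling property: W of a concatenated feature equals count-weighted
  # pooling of its parts
  set.seed(42)
  sites <- tibble::tibble(
    sample = "s", contig = "c1", pos = sort(sample(1:200, 40)),
    n = rpois(40, 30) + 1L
  )
  sites$m <- rbinom(40, sites$n, 0.3)
  parts <- tibble::tibble(feature_id = c("p1", "p2"), contig = "c1",
                          start = c(1, 101), end = c(100, 200))
  whole <- tibble::tibble(feature_id = "all", contig = "c1", start = 1,
                          end = 200)
  wp <- weighted_methylation(sites, parts)
  ww <- weighted_methylation(sites, whole)
  t1 <- dplyr::summarise(dplyr::filter(sites, pos <= 100),
                         m = sum(m), n = sum(n))
  t2 <- dplyr::summarise(dplyr::filter(sites, pos >= 101),
                         m = sum(m), n = sum(n))
  expect_equal(wp$w[wp$feature_id == "p1"], t1$m / t1$n)
  expect_equal(wp$w[wp$feature_id == "p2"], t2$m / t2$n)
  expect_equal(ww$w, (t1$m + t2$m) / (t1$n + t2$n))
})

test_that("gene methylation bins follow the floor and edges", {
  w <- c(0.75, 0.04, 0.3, 0.7, 0.05, 0.2, NA, 0.71)
  bins <- bin_methylation(w)
  expect_equal(as.character(bins),
               c("high", "unmethylated", "medium", "medium", "unmethylated",
                 "low", NA, "high"))
})
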