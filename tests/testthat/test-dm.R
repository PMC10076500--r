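# Per-CpG logistic regression, DM calling rules, the goodness-of-fit test
# and gene-set overlaps.

mk_counts <- function(m1, m2, n1 = 10L, n2 = 10L, pos = 1L) {
  tibble::tibble(
    sample = c(paste0("q", seq_along(m1)), paste0("m", seq_along(m2))),
    contig = "c1", pos = pos, m = c(m1, m2),
    n = c(rep_len(n1, length(m1)), rep_len(n2, length(m2)))
  )
}

mk_sheet <- function(n1 = 4, n2 = 4, subspecies = NULL) {
  tibble::tibble(
    sample = c(paste0("q", seq_len(n1)), paste0("m", seq_len(n2))),
    group = c(rep("queen", n1), rep("male", n2)),
    subspecies = subspecies %||% rep(c("A", "B"), length.out = n1 + n2)
  )
}

test_that("identical group proportions give a null fit", {
  fits <- dm_test_cpgs(mk_counts(rep(5L, 4), rep(5L, 4)), mk_sheet(),
                       c("queen", "male"))
  expect_equal(fits$meth_diff, 0)
  expect_equal(fits$statistic, 0, tolerance = 1e-8)
  expect_gt(fits$p_value, 0.99)
})

test_that("the LRT statistic matches a direct likelihood maximisation", {
  d <- mk_counts(rep(9L, 4), rep(1L, 4))
  sheet <- mk_sheet()
  fits <- dm_test_cpgs(d, sheet, c("queen", "male"))
  dd <- dplyr::inner_join(d, sheet, by = "sample")
  oracle <- glm_lrt_oracle(dd, c("queen", "male"), "subspecies")
  expect_equal(fits$statistic, oracle, tolerance = 1e-6)
  expect_equal(fits$meth_diff, 100 * (36 / 40 - 4 / 40))
})

test_that("a covariate confounded with group makes the design untestable", {
  sheet <- mk_sheet(subspecies = c(rep("A", 4), rep("B", 4)))
  expect_warning(
    fits <- dm_test_cpgs(mk_counts(rep(8L, 4), rep(1L, 4)), sheet,
                         c("queen", "male")),
    "confounded"
  )
  expect_equal(nrow(fits), 0L)
})

test_that("sites without full per-group coverage are not tested by default", {
  d <- mk_counts(rep(5L, 4), rep(5L, 4))
  d$n[1] <- 0L
  fits <- dm_test_cpgs(d, mk_sheet(), c("queen", "male"))
  expect_equal(nrow(fits), 0L)
  relaxed <- dm_test_cpgs(d, mk_sheet(), c("queen", "male"),
                          min_per_group = 3)
  expect_equal(nrow(relaxed), 1L)
})

test_that("DM-CpG calling applies BH and both thresholds", {
  fits <- tibble::tibble(
    contig = "c1", pos = 1:4, comparison = "queen_vs_male",
    group1 = "queen", group2 = "male", n_samples = 8L,
    prop_g1 = 0.5, prop_g2 = 0.2,
    meth_diff = c(30, 25, 8, -25),
    statistic = 10, p_value = c(0.01, 0.02, 0.03, 0.04)
  )
  out <- call_dm_cpgs(fits)
  expect_equal(out$q_value, rep(0.04, 4))  # BH hand computation
  expect_false(any(out$dm))  # q = 0.04 >= 0.01 everywhere

  fits$p_value <- c(1e-5, 0.02, 1e-6, 1e-6)
  out2 <- call_dm_cpgs(fits)
  # pos 3: large q is fine but diff of 8 points fails the 10-point rule
  expect_equal(out2$dm, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(out2$hyper_in, c("queen", "queen", "queen", "male"))
})

test_that("DM-gene rules: two CpGs on an exon and a >15 point difference", {
  exons <- tibble::tibble(
    feature_id = c("g1_e1", "g2_e1", "g3_e1", "g3_e2"),
    gene_id = c("g1", "g2", "g3", "g3"),
    contig = "c1", start = c(1, 101, 201, 301), end = c(100, 200, 300, 400)
  )
  mk_dm <- function(pos) {
    tibble::tibble(
      contig = "c1", pos = pos, comparison = "queen_vs_male",
      group1 = "queen", group2 = "male", dm = TRUE,
      meth_diff = 20, q_value = 1e-4, hyper_in = "queen"
    )
  }
  exon_w <- tibble::tibble(
    feature_id = rep(c("g1_e1", "g2_e1", "g3_e1", "g3_e2"), each = 2),
    group = rep(c("queen", "male"), 4),
    w = c(0.50, 0.30,   # g1: dW = 0.20 -> qualifies
          0.40, 0.30,   # g2: dW = 0.10 -> fails
          0.50, 0.30,   # g3 e1: +0.20
          0.10, 0.30)   # g3 e2: -0.20
  )
  # g1: 2 DM CpGs, dW 0.20 -> DM
  out1 <- call_dm_genes(mk_dm(c(10, 20)), exons, exon_w)
  expect_equal(out1$gene_id, "g1")
  expect_true(out1$dm)

  # g2: 3 DM CpGs but dW 0.10 -> not DM
  out2 <- call_dm_genes(mk_dm(c(110, 120, 130)), exons, exon_w)
  expect_false("g2" %in% out2$gene_id)

  # one DM CpG only -> not DM
  out3 <- call_dm_genes(mk_dm(10), exons, exon_w)
  expect_false("g1" %in% out3$gene_id)

  # g3: qualifying exons in both directions -> DM with mixed pattern
  out4 <- call_dm_genes(mk_dm(c(210, 220, 310, 320)), exons, exon_w)
  expect_equal(out4$gene_id, "g3")
  expect_equal(out4$direction_pattern, "mixed")
  expect_equal(out4$n_qualifying_exons, 2L)

  # an exon lacking a weighted level in one group is skipped
  exon_w_missing <- dplyr::filter(exon_w,
                                  !(feature_id == "g1_e1" & group == "male"))
  expect_message(out5 <- call_dm_genes(mk_dm(c(10, 20)), exons,
                                       exon_w_missing),
                 "skipped")
  expect_equal(nrow(out5), 0L)
})

test_that("a dyad CpG at an exon edge counts for the exon", {
  exons <- tibble::tibble(feature_id = "g1_e1", gene_id = "g1",
                          contig = "c1", start = 11, end = 100)
  dm <- tibble::tibble(
    contig = "c1", pos = c(10L, 50L), comparison = "x", group1 = "queen",
    group2 = "male", dm = TRUE, meth_diff = 20, q_value = 1e-4,
    hyper_in = "queen"
  )
  exon_w <- tibble::tibble(feature_id = "g1_e1",
                           group = c("queen", "male"), w = c(0.5, 0.2))
  # the C at 10 is outside but its G partner at 11 is inside
  out <- call_dm_genes(dm, exons, exon_w)
  expect_equal(out$gene_id, "g1")
})

test_that("goodness of fit on hypermethylated counts", {
  gof <- gof_hypermethylated(463, 571)
  expect_equal(round(gof$statistic, 2), 11.28)
  expect_equal(gof$df, 1)
  expect_lt(gof$p_value, 0.01)

  expect_equal(gof_hypermethylated(500, 500)$statistic, 0)
  expect_equal(gof_hypermethylated(100, 0)$statistic, 100)
  expect_error(gof_hypermethylated(0, 0), "zero")
})

test_that("upset-style overlaps produce exclusive counts that conserve", {
  out <- overlap_dm_gene_sets(list(A = c("a", "b", "c"),
                                   B = c("b", "c", "d")))
  expect_equal(out$n[out$sets == "A&B"], 2L)
  expect_equal(out$n[out$sets == "A"], 1L)
  expect_equal(out$n[out$sets == "B"], 1L)

  ident <- overlap_dm_gene_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(ident$sets, "A&B")
  expect_equal(ident$n, 2L)

  disj <- overlap_dm_gene_sets(list(A = "a", B = "b", C = "c"))
  expect_true(all(disj$degree == 1L))

  # conservation against brute force over random membership patterns
  set.seed(7)
  genes <- paste0("g", 1:40)
  sets <- lapply(1:4, function(i) sample(genes, sample(5:25, 1)))
  names(sets) <- LETTERS[1:4]
  out2 <- overlap_dm_gene_sets(sets)
  for (nm in names(sets)) {
    in_set <- out2$n[stringr::str_detect(out2$sets,
                                         paste0("(^|&)", nm, "(&|$)"))]
    expect_equal(sum(in_set), length(unique(sets[[nm]])))
  }
})

test_that("BH never lowers a p-value and is monotone in p", {
  set.seed(13)
  for (i in 1:5) {
    p <- runif(50)^2
    fits <- tibble::tibble(
      contig = "c1", pos = seq_along(p), comparison = "x",
      group1 = "queen", group2 = "male", n_samples = 8L,
      prop_g1 = 0.5, prop_g2 = 0.2, meth_diff = 30, statistic = 1,
      p_value = p
    )
    out <- call_dm_cpgs(fits)
    expect_true(all(out$q_value >= out$p_value - 1e-12))
    ord <- order(out$p_value)
    expect_true(all(diff(out$q_value[ord]) >= -1e-12))
  }
})

test_that("permuted group labels produce essentially no DM CpGs", {
  # null data: one shared proportion, 8 samples, modest site count
  set.seed(23)
  n_sites <- 60
  samples <- c(paste0("q", 1:4), paste0("m", 1:4))
  counts <- tidyr::crossing(sample = samples, pos = seq_len(n_sites)) |>
    dplyr::mutate(contig = "c1", n = rpois(dplyr::n(), 30) + 10L,
                  m = rbinom(dplyr::n(), n, 0.3))
  hits <- integer(5)
  for (i in 1:5) {
    sheet <- tibble::tibble(
      sample = sample(samples),
      group = c(rep("queen", 4), rep("male", 4)),
      subspecies = rep(c("A", "B"), 4)
    )
    fits <- dm_test_cpgs(counts, sheet, c("queen", "male"))
    dm <- call_dm_cpgs(fits)
    hits[i] <- sum(dm$dm)
  }
  expect_gte(sum(hits == 0), 4)
})
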