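# Codon fold degeneracy, its intersection with methylation calls, bin
# enrichment and the beta regression.

test_that("degeneracy labels match brute-force enumeration for key codons", {
  tab <- codon_degeneracy_table()
  pick <- function(codon, pos) {
    tab$syn_count[tab$codon == codon & tab$codon_pos == pos]
  }
  expect_equal(pick("GGA", 3), 3)  # Gly third position: four-fold
  expect_equal(pick("TGG", 1), 0)  # Trp: every substitution changes it
  expect_equal(pick("TGG", 2), 0)
  expect_equal(pick("TGG", 3), 0)
  expect_equal(pick("ATT", 3), 2)  # Ile: ATC/ATA synonymous, ATG not
  # full table agrees with independent enumeration
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$syn_count[i],
                 brute_syn_count(tab$codon[i], tab$codon_pos[i]))
  }
  expect_false(any(c("TAA", "TAG", "TGA") %in% tab$codon))
})

test_that("label_degeneracy covers the CDS minus its stop codon", {
  cds <- "ATGGGATTTTGA"
  lab <- label_degeneracy(cds, gene_id = "g")
  expect_equal(nrow(lab), 9L)  # 12 bases minus the 3 of the stop
  expect_equal(lab$cds_index, 1:9)
  expect_equal(lab$codon[1:3], rep("ATG", 3))
  expect_equal(lab$syn_count[lab$codon == "GGA" & lab$codon_pos == 3], 3)
  expect_equal(as.character(
    lab$fold_class[lab$codon == "GGA" & lab$codon_pos == 3]), "four")

  # untypeable codon (N) is skipped with a message and attribute
  expect_message(
    labN <- label_degeneracy("ATGGGNTTTTGA", gene_id = "g"),
    "untypeable"
  )
  expect_equal(nrow(labN), 6L)
  expect_equal(attr(labN, "skipped_codons"), 1L)

  expect_error(label_degeneracy("ATGTAAGGGTGA", gene_id = "g"),
               "internal stop")
})

test_that("labels carry the coordinate map through strand", {
  cds <- "ATGGGATTTTGA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  g <- Biostrings::DNAStringSet(c(c1 = paste0("AA", rc, "CC")))
  m <- toy_gene_models(list(c(3, 14)), strand = "-")
  ext <- extract_cds(g, m, "gX")
  lab <- label_degeneracy(ext$seq, ext$map, gene_id = "gX")
  expect_equal(lab$pos, 14:6)  # descending genomic positions, stop excluded
  expect_equal(unique(lab$strand), "-")
})

test_that("fold/methylation join equals a naive per-site oracle", {
  set.seed(5)
  deg <- tibble::tibble(
    sample = rep(c("s1", "s2"), each = 12),
    gene_id = "g1", contig = "c1",
    pos = rep(1:12, 2),
    strand = rep(c("+", "-"), 12),
    cds_index = rep(1:12, 2), codon = "GCT",
    codon_pos = rep(1:3, 8),
    syn_count = sample(0:3, 24, replace = TRUE)
  ) |>
    dplyr::mutate(fold_class = factor(
      c("zero", "two", "three", "four")[syn_count + 1],
      levels = c("zero", "two", "three", "four")
    ))
  calls <- tidyr::crossing(sample = c("s1", "s2"), pos = 0:12) |>
    dplyr::mutate(contig = "c1",
                  status = sample(c("methylated", "unmethylated"),
                                  dplyr::n(), replace = TRUE))
  got <- fold_methylation_proportions(deg, calls)
  # naive loop oracle
  oracle <- list()
  for (i in seq_len(nrow(deg))) {
    key <- if (deg$strand[i] == "-") deg$pos[i] - 1L else deg$pos[i]
    hit <- calls$status[calls$sample == deg$sample[i] & calls$pos == key]
    if (length(hit) == 1) {
      oracle[[length(oracle) + 1]] <- tibble::tibble(
        sample = deg$sample[i], fold_class = deg$fold_class[i],
        meth = hit == "methylated"
      )
    }
  }
  oracle <- dplyr::bind_rows(oracle) |>
    dplyr::group_by(sample, fold_class) |>
    dplyr::summarise(n_sites = dplyr::n(), n_methylated = sum(meth),
                     .groups = "drop")
  joined <- dplyr::inner_join(got, oracle, by = c("sample", "fold_class"),
                              suffix = c("", "_o"))
  expect_equal(nrow(joined), nrow(got))
  expect_equal(joined$n_sites, joined$n_sites_o)
  expect_equal(joined$n_methylated, joined$n_methylated_o)
  expect_equal(got$proportion, got$n_methylated / got$n_sites)
})

test_that("bin enrichment matches exact combinatorics", {
  bins <- tibble::tibble(
    gene_id = paste0("g", 1:10),
    bin = rep(c("medium", "low"), each = 5)
  )
  study <- paste0("g", 1:4)  # all four in the medium bin
  res <- fold_bin_enrichment(study, bins)
  med <- res[res$bin == "medium", ]
  expect_equal(med$p_value, 5 / 210, tolerance = 1e-12)
  expect_equal(med$p_value,
               hyper_tail_oracle(k = 4, K = 5, N = 10, s = 4),
               tolerance = 1e-12)
  # disjoint study and bin -> upper tail 1
  low <- res[res$bin == "low", ]
  expect_equal(low$p_value, 1)
  # study == bin == universe
  all_in <- fold_bin_enrichment(paste0("g", 1:5),
                                bins[1:5, ])
  expect_equal(all_in$p_value, 1)
  expect_error(fold_bin_enrichment("g1", bins[0, ]), "empty universe")
})

test_that("DM-by-fold counts include a non-CDS residual row", {
  deg <- tibble::tibble(
    sample = "s1", gene_id = "g1", contig = "c1", pos = c(10L, 11L),
    strand = "+", cds_index = 1:2, codon = "GGA", codon_pos = c(1L, 2L),
    syn_count = c(0L, 0L),
    fold_class = factor("zero", levels = c("zero", "two", "three", "four"))
  )
  dm <- tibble::tibble(contig = "c1", pos = c(10L, 500L), dm = TRUE)
  bg <- tibble::tibble(contig = "c1", pos = c(10L, 11L, 500L, 600L))
  out <- dm_sites_by_fold(dm, deg, bg)
  expect_equal(out$n_dm[out$fold_class == "zero"], 1L)
  expect_equal(out$n_dm[out$fold_class == "non_CDS"], 1L)
  expect_equal(out$n_methylated_background[out$fold_class == "non_CDS"], 2L)
  none <- dm_sites_by_fold(dm[0, ], deg, bg)
  expect_true(all(none$n_dm == 0L))
})

test_that("beta regression maximises the same likelihood as an
           independent optimiser", {
  set.seed(77)
  n <- 120
  x <- sample(c(0, 2, 3, 4), n, replace = TRUE)
  sex <- rbinom(n, 1, 0.5)
  mu <- plogis(0.5 - 0.4 * x + 0.3 * sex)
  y <- rbeta(n, mu * 40, (1 - mu) * 40)
  d <- tibble::tibble(proportion = y, fold = x, sex = sex)
  fit <- fit_beta_regression(proportion ~ fold + sex, d)

  X <- stats::model.matrix(~ fold + sex, d)
  o <- stats::optim(c(0, 0, 0, log(10)), beta_negll, X = X, y = y,
                    method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(fit$logLik, -o$value, tolerance = 1e-5)
  expect_equal(unname(fit$coefficients), o$par[1:3], tolerance = 1e-3)
  # recovery of the generating coefficient within 3 standard errors
  expect_lt(abs(fit$coefficients[["fold"]] - (-0.4)), 3 * fit$se[["fold"]])
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "fold", "sex"))
  expect_equal(glance(fit)$nobs, n)
})

test_that("boundary proportions are shrunk before fitting", {
  y <- c(0, 0.2, 0.5, 0.9, 1, 0.4, 0.1, 0.6)
  d <- tibble::tibble(proportion = y, x = seq_along(y))
  expect_silent(fit <- fit_beta_regression(proportion ~ x, d))
  expect_true(is.finite(fit$logLik))
  ys <- shrink_proportions(y)
  expect_true(all(ys > 0 & ys < 1))
})
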