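# SNP filtering, masking, alternate references, the feature map and CDS
# extraction.

snp_row <- function(ref = "A", alt = "G", qual = 30, depth = 20,
                    gt_mother = "1/1", gt_father = "0", pos = 100) {
  tibble::tibble(contig = "chr1", pos = pos, ref = ref, alt = alt,
                 qual = qual, depth = depth, gt_mother = gt_mother,
                 gt_father = gt_father)
}

test_that("parental SNP filter applies every rule", {
  v <- dplyr::bind_rows(
    snp_row(pos = 1),                                   # keep, mother
    snp_row(pos = 2, ref = "C", alt = "T"),             # C->T removed
    snp_row(pos = 3, ref = "T", alt = "C"),             # T->C removed
    snp_row(pos = 4, gt_mother = "1/1", gt_father = "1"),  # shared
    snp_row(pos = 5, gt_mother = "0/1"),                # het
    snp_row(pos = 6, qual = 10),                        # low qual
    snp_row(pos = 7, depth = 5),                        # low depth
    snp_row(pos = 8, alt = "G,T"),                      # multiallelic
    snp_row(pos = 9, gt_mother = "./."),                # missing -> skipped
    snp_row(pos = 10, gt_mother = "0/0", gt_father = "1")  # keep, father
  )
  out <- filter_parent_snps(v)
  expect_equal(out$pos, c(1, 10))
  expect_equal(out$parent, c("mother", "father"))
  log <- attr(out, "log")
  expect_equal(unname(log["c_t_snp"]), 2)
  expect_equal(unname(log["missing_genotype"]), 1)
  expect_equal(unname(log["not_biallelic_snv"]), 1)
  expect_equal(unname(log["low_qual"]), 1)
  expect_equal(unname(log["low_depth"]), 1)
  expect_equal(unname(log["not_unique_hom_alt"]), 2)
})

test_that("haploid father alt counts as homozygous-alternative", {
  out <- filter_parent_snps(snp_row(gt_mother = "0/0", gt_father = "1"))
  expect_equal(out$parent, "father")
  # but a haploid alt father with an alt-hom mother is not unique
  out2 <- filter_parent_snps(snp_row(gt_mother = "1/1", gt_father = "1"))
  expect_equal(nrow(out2), 0L)
})

test_that("masking replaces exactly the SNP positions with N", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  snps <- tibble::tibble(contig = "chr1", pos = 3L)
  masked <- mask_genome(g, snps)
  expect_equal(as.character(masked[["chr1"]]), "ACNTACGT")
  expect_identical(as.character(mask_genome(g, snps[0, ])),
                   as.character(g))
  two <- mask_genome(g, tibble::tibble(contig = "chr1", pos = c(2L, 7L)))
  expect_equal(Biostrings::countPattern("N", two[["chr1"]]), 2)
  expect_equal(Biostrings::width(two), Biostrings::width(g))
  # idempotent
  expect_identical(as.character(mask_genome(masked, snps)),
                   as.character(masked))
  expect_error(
    mask_genome(g, tibble::tibble(contig = "chr1", pos = 99L)),
    "chr1:99"
  )
})

test_that("alternate-reference substitution and its round trip", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
  snps <- tibble::tibble(contig = "chr1", pos = 2L, ref = "C", alt = "A")
  alt <- build_alternate_reference(g, snps)
  expect_equal(as.character(alt[["chr1"]]), "AAGT")
  expect_identical(as.character(build_alternate_reference(g, snps[0, ])),
                   as.character(g))
  # idempotent on an already-substituted genome
  expect_identical(as.character(build_alternate_reference(alt, snps)),
                   as.character(alt))
  expect_error(
    build_alternate_reference(
      g, tibble::tibble(contig = "chr1", pos = 2L, ref = "G", alt = "A")
    ),
    "mismatch"
  )

  # substituting then re-calling differences recovers the SNP set
  set.seed(99)
  big <- Biostrings::DNAStringSet(c(c1 = random_dna(500)))
  pos <- sort(sample(500, 12))
  ref <- unlist(strsplit(as.character(big[[1]]), ""))[pos]
  alt_allele <- vapply(ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  snps2 <- tibble::tibble(contig = "c1", pos = pos, ref = ref,
                          alt = alt_allele)
  sub <- build_alternate_reference(big, snps2)
  diff_pos <- which(unlist(strsplit(as.character(sub[[1]]), "")) !=
                      unlist(strsplit(as.character(big[[1]]), "")))
  expect_equal(diff_pos, pos)
})

test_that("promoters are placed, clipped and truncated as defined", {
  mk_gene <- function(gene_id, start, end, strand = "+") {
    dplyr::bind_rows(
      tibble::tibble(contig = "c1", type = "gene", start = start, end = end,
                     strand = strand, phase = NA_integer_, gene_id = gene_id,
                     exon_rank = NA_integer_),
      tibble::tibble(contig = "c1", type = c("exon", "CDS"), start = start,
                     end = end, strand = strand, phase = c(NA_integer_, 0L),
                     gene_id = gene_id, exon_rank = 1L)
    )
  }
  # isolated + strand gene at 1001-2000 -> promoter 501-1000
  fm <- build_feature_map(mk_gene("g1", 1001, 2000), c(c1 = 3000))
  prom <- dplyr::filter(fm, feature == "promoter")
  expect_equal(c(prom$start, prom$end), c(501, 1000))

  # gene starting at 201 -> promoter clipped to 1-200
  fm2 <- build_feature_map(mk_gene("g1", 201, 900), c(c1 = 3000))
  prom2 <- dplyr::filter(fm2, feature == "promoter")
  expect_equal(c(prom2$start, prom2$end), c(1, 200))

  # neighbouring gene ending 300 bp upstream truncates the promoter
  fm3 <- build_feature_map(
    dplyr::bind_rows(mk_gene("g1", 1001, 2000), mk_gene("g0", 1, 700)),
    c(c1 = 3000)
  )
  prom3 <- dplyr::filter(fm3, feature == "promoter", start > 700)
  expect_equal(c(prom3$start, prom3$end), c(701, 1000))

  # minus-strand promoter sits downstream in genome coordinates
  fm4 <- build_feature_map(mk_gene("g1", 1001, 2000, strand = "-"),
                           c(c1 = 3000))
  prom4 <- dplyr::filter(fm4, feature == "promoter")
  expect_equal(c(prom4$start, prom4$end), c(2001, 2500))

  expect_error(build_feature_map(mk_gene("g1", 2900, 3100), c(c1 = 3000)),
               "extends past")
})

test_that("feature labels partition every contig", {
  study <- tiny_study()
  fm <- build_feature_map(study$annotation, study$genome)
  widths <- setNames(Biostrings::width(study$genome), names(study$genome))
  per_contig <- tapply(fm$end - fm$start + 1, fm$contig, sum)
  expect_equal(unname(per_contig[names(widths)]), unname(widths))
  # no overlaps: total distinct bp equals total labelled bp
  for (ct in names(widths)) {
    f <- dplyr::filter(fm, contig == ct) |> dplyr::arrange(start)
    expect_true(all(f$start[-1] > f$end[-nrow(f)]))
  }
  # introns exist in the multi-exon simulated genes
  expect_true("intron" %in% fm$feature)
})

test_that("CDS extraction handles strand, splicing and phase", {
  cds <- "ATGAAATTTCCCGGGTAA"
  # plus strand, single segment
  g <- Biostrings::DNAStringSet(c(c1 = paste0("TTTT", cds, "GGGG")))
  m <- toy_gene_models(list(c(5, 22)))
  got <- extract_cds(g, m, "gX")
  expect_equal(got$seq, cds)
  expect_equal(got$map$pos, 5:22)
  expect_false(got$internal_stop)

  # minus strand: plant the reverse complement
  g2 <- Biostrings::DNAStringSet(c(c1 = paste0(
    "TT", as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds))), "AA"
  )))
  m2 <- toy_gene_models(list(c(3, 20)), strand = "-")
  got2 <- extract_cds(g2, m2, "gX")
  expect_equal(got2$seq, cds)
  expect_equal(got2$map$pos, 20:3)
  expect_equal(unique(got2$map$strand), "-")

  # spliced two-segment CDS equals the per-base oracle
  chr <- paste0("AACC", substr(cds, 1, 9), "GTTTAG", substr(cds, 10, 18),
                "CCAA")
  g3 <- Biostrings::DNAStringSet(c(c1 = chr))
  m3 <- toy_gene_models(list(c(5, 13), c(20, 28)))
  got3 <- extract_cds(g3, m3, "gX")
  oracle <- paste0(
    paste(strsplit(chr, "")[[1]][5:13], collapse = ""),
    paste(strsplit(chr, "")[[1]][20:28], collapse = "")
  )
  expect_equal(got3$seq, oracle)
  expect_equal(got3$seq, cds)

  # non-zero phase on the first segment drops leading bases
  # (segments of 8 + 9 bases; phase 2 leaves 15, a codon multiple)
  m4 <- toy_gene_models(list(c(5, 12), c(20, 28)), phase = c(2L, 0L))
  got4 <- extract_cds(g3, m4, "gX")
  expect_equal(got4$seq, paste0(substr(cds, 3, 8), substr(cds, 10, 18)))
  expect_equal(got4$map$pos[1], 7)

  # minus-strand extraction equals its mirrored plus-strand construction
  rc_chr <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chr)))
  L <- nchar(chr)
  g5 <- Biostrings::DNAStringSet(c(c1 = rc_chr))
  m5 <- toy_gene_models(list(c(L - 28 + 1, L - 20 + 1), c(L - 13 + 1, L - 5 + 1)),
                        strand = "-")
  got5 <- extract_cds(g5, m5, "gX")
  expect_equal(got5$seq, got3$seq)

  # internal stop is flagged and excluded by the bulk extractor
  bad <- "ATGTAAAAATAA"
  g6 <- Biostrings::DNAStringSet(c(c1 = paste0("GG", bad, "GG")))
  m6 <- toy_gene_models(list(c(3, 14)))
  expect_true(extract_cds(g6, m6, "gX")$internal_stop)
  expect_message(res <- extract_all_cds(g6, m6), "internal stop")
  expect_length(res, 0)
  expect_equal(attr(res, "dropped"), "gX")
})
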