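# Parental SNP filtering, N-masking and individualised (alternate)
# reference construction.

#' Merge a mother/father pair of variant call tables
#'
#' Joins per-parent call tables on position. A site present in only one
#' parent's file is treated as implied homozygous reference in the other
#' parent when `missing_as_homref = TRUE` (the default); otherwise its
#' genotype is left missing and [filter_parent_snps()] will skip it.
#'
#' @param mother,father Tibbles as returned by [read_vcf()].
#' @param missing_as_homref Treat absent records as homozygous reference.
#' @return Tibble with one row per site: contig, pos, ref, alt, qual, depth,
#'   gt_mother, gt_father. `qual`/`depth` are the minima of the per-parent
#'   values where both parents carry a record.
#' @export
merge_parent_calls <- function(mother, father, missing_as_homref = TRUE) {
  key <- c("contig", "pos", "ref", "alt")
  m <- mother |> dplyr::select(dplyr::all_of(key), qual_m = "qual",
                               depth_m = "depth", gt_mother = "gt")
  f <- father |> dplyr::select(dplyr::all_of(key), qual_f = "qual",
                               depth_f = "depth", gt_father = "gt")
  merged <- dplyr::full_join(m, f, by = key)
  if (missing_as_homref) {
    merged <- merged |>
      dplyr::mutate(
        gt_mother = dplyr::coalesce(.data$gt_mother, "0/0"),
        gt_father = dplyr::coalesce(.data$gt_father, "0")
      )
  }
  merged |>
    dplyr::mutate(
      qual = pmin(.data$qual_m, .data$qual_f, na.rm = TRUE),
      depth = pmin(.data$depth_m, .data$depth_f, na.rm = TRUE)
    ) |>
    dplyr::select(dplyr::all_of(key), "qual", "depth", "gt_mother",
                  "gt_father") |>
    dplyr::arrange(.data$contig, .data$pos)
}

gt_class <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(is.na(a)) || any(a == ".")) return("missing")
    if (all(a == "1")) return("hom_alt")
    if (all(a == "0")) return("hom_ref")
    "het"
  }, character(1))
}

#' Filter parental SNPs to the informative, mask-safe set
#'
#' Applies, in order: biallelic SNVs only; QUAL >= `min_qual`; mean depth >=
#' `min_depth`; genotype pattern homozygous-alternative in exactly one parent
#' with the other parent homozygous reference (a haploid `1` counts as
#' homozygous-alternative); removal of C<->T SNPs, which are
#' indistinguishable from bisulfite-converted bases in WGBS reads. Records
#' with a missing genotype in either parent are skipped, not errored.
#'
#' @param variants Tibble from [merge_parent_calls()] (columns contig, pos,
#'   ref, alt, qual, depth, gt_mother, gt_father).
#' @param min_qual,min_depth Quality and mean-depth thresholds (20 and 10).
#' @return Tibble of retained records with a `parent` column
#'   ("mother"/"father"); the counts removed by each filter are attached as
#'   the `"log"` attribute.
#' @export
filter_parent_snps <- function(variants, min_qual = 20, min_depth = 10) {
  assert_cols(variants, c("contig", "pos", "ref", "alt", "qual", "depth",
                          "gt_mother", "gt_father"))
  v <- variants
  log <- c()
  drop_step <- function(v, keep, name) {
    log[[name]] <<- sum(!keep)
    v[keep, , drop = FALSE]
  }
  bases <- c("A", "C", "G", "T")
  v <- drop_step(v, v$ref %in% bases & v$alt %in% bases, "not_biallelic_snv")
  v <- drop_step(v, !is.na(v$qual) & v$qual >= min_qual, "low_qual")
  v <- drop_step(v, !is.na(v$depth) & v$depth >= min_depth, "low_depth")

  cm <- gt_class(v$gt_mother)
  cf <- gt_class(v$gt_father)
  missing <- cm == "missing" | cf == "missing"
  log[["missing_genotype"]] <- sum(missing)
  informative <- (cm == "hom_alt" & cf == "hom_ref") |
    (cf == "hom_alt" & cm == "hom_ref")
  keep <- !missing & informative
  log[["not_unique_hom_alt"]] <- sum(!informative & !missing)
  parent <- ifelse(cm == "hom_alt", "mother", "father")[keep]
  v <- v[keep, , drop = FALSE]

  ct <- (v$ref == "C" & v$alt == "T") | (v$ref == "T" & v$alt == "C")
  log[["c_t_snp"]] <- sum(ct)
  v <- v[!ct, , drop = FALSE]
  parent <- parent[!ct]

  out <- v |> dplyr::mutate(parent = parent)
  attr(out, "log") <- unlist(log)
  out
}

check_snp_bounds <- function(genome, snps) {
  widths <- setNames(Biostrings::width(genome), names(genome))
  bad_contig <- !snps$contig %in% names(widths)
  if (any(bad_contig)) {
    abort(sprintf("SNP contig '%s' not found in genome",
                  snps$contig[bad_contig][1]))
  }
  oob <- snps$pos < 1 | snps$pos > widths[snps$contig]
  if (any(oob)) {
    i <- which(oob)[1]
    abort(sprintf("SNP position out of bounds: %s:%d (contig length %d)",
                  snps$contig[i], snps$pos[i], widths[[snps$contig[i]]]))
  }
  invisible(TRUE)
}

#' N-mask a genome at SNP positions
#'
#' Replaces every SNP position with `N`, leaving the rest of the sequence
#' and all contig lengths untouched, so bisulfite alignment is not biased
#' toward the reference allele at sites where the parents differ.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param snps Tibble with contig and pos columns (e.g. from
#'   [filter_parent_snps()]).
#' @return The masked [Biostrings::DNAStringSet].
#' @export
mask_genome <- function(genome, snps) {
  if (nrow(snps) == 0) return(genome)
  check_snp_bounds(genome, snps)
  out <- genome
  for (ct in unique(snps$contig)) {
    at <- snps$pos[snps$contig == ct]
    out[[ct]] <- Biostrings::replaceLetterAt(
      out[[ct]], as.integer(at), strrep("N", length(at))
    )
  }
  out
}

#' Build an individualised (alternate) reference
#'
#' Substitutes an individual's homozygous-alternative alleles into the
#' reference. The record's REF allele must match the genome at every
#' position; a mismatch signals a coordinate or genome-version inconsistency
#' and is an error.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param snps Tibble with contig, pos, ref, alt restricted to one
#'   individual's homozygous-alternative calls.
#' @return The substituted [Biostrings::DNAStringSet] (lengths preserved).
#' @export
build_alternate_reference <- function(genome, snps) {
  if (nrow(snps) == 0) return(genome)
  check_snp_bounds(genome, snps)
  out <- genome
  for (ct in unique(snps$contig)) {
    rows <- snps[snps$contig == ct, , drop = FALSE]
    have <- as.character(Biostrings::extractAt(
      out[[ct]], IRanges::IRanges(rows$pos, rows$pos)
    ))
    # a base already equal to alt means the substitution was applied before;
    # re-applying is a no-op (idempotence), anything else is a mismatch
    bad <- have != rows$ref & have != rows$alt
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "reference mismatch at %s:%d: genome has %s, record claims %s",
        ct, rows$pos[i], have[i], rows$ref[i]
      ))
    }
    out[[ct]] <- Biostrings::replaceLetterAt(
      out[[ct]], as.integer(rows$pos), paste(rows$alt, collapse = "")
    )
  }
  out
}
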