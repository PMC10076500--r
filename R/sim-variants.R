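# Synthetic parental genotypes per colony, including decoy classes the SNP
# filter must remove.

#' Simulate parental variant calls per colony
#'
#' Emits, for every colony, the mother's (diploid) and father's (haploid)
#' variant records together with a per-SNP truth table. Besides the
#' informative class the downstream filter keeps (homozygous-alternative in
#' exactly one parent, non-C/T), each colony carries decoys that must be
#' removed: heterozygous calls, SNPs shared by both parents, C<->T SNPs
#' (indistinguishable from bisulfite conversion) and low-quality records.
#' When `snp_rate > 0` every class is represented at least once per colony.
#'
#' @param config A [sim_config()].
#' @param sim_genome Output of [simulate_genome()].
#' @return A list with `calls` (tibble: colony, parent, contig, pos, ref,
#'   alt, qual, depth, gt) holding the records as they appear in the
#'   per-parent VCFs, and `truth` (tibble adding `class` and `keep`).
#' @export
simulate_parent_variants <- function(config, sim_genome) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "variants"))
  genome_chr <- as.character(sim_genome$genome)
  bases <- c("A", "C", "G", "T")
  classes <- c("info_mother", "info_father", "het_decoy", "shared_decoy",
               "ct_decoy", "lowqual_decoy")
  class_w <- c(0.33, 0.33, 0.12, 0.1, 0.07, 0.05)

  out <- vector("list", config$n_colonies)
  for (col in seq_len(config$n_colonies)) {
    sites <- dplyr::bind_rows(lapply(names(genome_chr), function(ct) {
      len <- nchar(genome_chr[[ct]])
      n <- stats::rbinom(1L, len, config$snp_rate)
      if (n == 0L) return(NULL)
      pos <- sort(sample.int(len, n))
      tibble(contig = ct, pos = pos,
             ref = stringr::str_sub(genome_chr[[ct]], pos, pos))
    }))
    if (is.null(sites) || nrow(sites) == 0L) next

    cls <- sample(classes, nrow(sites), replace = TRUE, prob = class_w)
    # ct_decoy rows must sit on a C/T reference base; reassign the rest.
    ct_ok <- which(sites$ref %in% c("C", "T"))
    bad_ct <- cls == "ct_decoy" & !sites$ref %in% c("C", "T")
    cls[bad_ct] <- "info_mother"
    # Guarantee representation of each class when there is room.
    if (nrow(sites) >= length(classes)) {
      forced <- integer(0)
      for (cl in classes) {
        if (!cl %in% cls) {
          cand <- setdiff(if (cl == "ct_decoy") ct_ok else seq_len(nrow(sites)),
                          forced)
          if (length(cand) > 0L) {
            cls[cand[1L]] <- cl
            forced <- c(forced, cand[1L])
          }
        }
      }
    }

    alt <- vapply(seq_len(nrow(sites)), function(i) {
      r <- sites$ref[i]
      if (cls[i] == "ct_decoy") {
        if (r == "C") "T" else "C"
      } else {
        # Informative classes avoid C<->T so they survive that filter.
        pool <- setdiff(bases, r)
        if (cls[i] %in% c("info_mother", "info_father", "lowqual_decoy")) {
          if (r == "C") pool <- setdiff(pool, "T")
          if (r == "T") pool <- setdiff(pool, "C")
        }
        sample(pool, 1L)
      }
    }, character(1))

    qual <- round(stats::runif(nrow(sites), 30, 60), 1)
    qual[cls == "lowqual_decoy"] <- round(stats::runif(sum(cls == "lowqual_decoy"), 2, 19), 1)
    depth <- stats::rpois(nrow(sites), 20) + 10L

    truth <- sites |>
      dplyr::mutate(
        colony = col, class = cls, alt = alt, qual = qual, depth = depth,
        parent = dplyr::case_when(
          cls == "info_father" ~ "father",
          cls %in% c("info_mother", "het_decoy", "ct_decoy",
                     "lowqual_decoy") ~ "mother",
          TRUE ~ NA_character_
        ),
        keep = cls %in% c("info_mother", "info_father")
      )

    mother <- truth |>
      dplyr::filter(.data$class != "info_father") |>
      dplyr::mutate(
        parent = "mother",
        gt = dplyr::if_else(.data$class == "het_decoy", "0/1", "1/1")
      )
    father <- truth |>
      dplyr::filter(.data$class %in% c("info_father", "shared_decoy")) |>
      dplyr::mutate(parent = "father", gt = "1")
    out[[col]] <- list(
      calls = dplyr::bind_rows(mother, father) |>
        dplyr::select("colony", "parent", "contig", "pos", "ref", "alt",
                      "qual", "depth", "gt"),
      truth = truth |>
        dplyr::select("colony", "contig", "pos", "ref", "alt", "class",
                      "parent", "qual", "depth", "keep")
    )
  }
  list(
    calls = dplyr::bind_rows(lapply(out, `[[`, "calls")),
    truth = dplyr::bind_rows(lapply(out, `[[`, "truth"))
  )
}
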