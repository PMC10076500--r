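# Internal helpers shared across modules.

# Overlap-join a positional table onto an interval table. `x` needs columns
# contig and `x_start` (and optionally `x_end`); `features` needs contig,
# start, end plus any annotation columns to carry over. Returns one row per
# (x row, overlapping feature) pair.
overlap_join <- function(x, features, x_start = "pos", x_end = x_start) {
  if (nrow(x) == 0L || nrow(features) == 0L) {
    out <- x[0, , drop = FALSE]
    extra <- setdiff(names(features), c("contig", "start", "end", names(x)))
    for (nm in extra) out[[nm]] <- features[[nm]][0]
    return(as_tibble(out))
  }
  xr <- GenomicRanges::GRanges(
    x$contig, IRanges::IRanges(x[[x_start]], x[[x_end]])
  )
  fr <- GenomicRanges::GRanges(
    features$contig, IRanges::IRanges(features$start, features$end)
  )
  h <- GenomicRanges::findOverlaps(xr, fr, ignore.strand = TRUE)
  extra <- setdiff(names(features), c("contig", "start", "end", names(x)))
  dplyr::bind_cols(
    x[S4Vectors::queryHits(h), , drop = FALSE],
    features[S4Vectors::subjectHits(h), extra, drop = FALSE]
  )
}

# IRanges for one contig's rows of an interval tibble.
iranges_of <- function(tbl) {
  IRanges::IRanges(start = tbl$start, end = tbl$end)
}

# Tibble from a (possibly reduced) IRanges.
tbl_of_iranges <- function(ir, contig, feature) {
  tibble(
    contig = contig,
    start = IRanges::start(ir),
    end = IRanges::end(ir),
    feature = feature
  )
}

assert_cols <- function(x, cols, what = deparse(substitute(x))) {
  miss <- setdiff(cols, names(x))
  if (length(miss) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s", what, paste(miss, collapse = ", ")
    ))
  }
  invisible(x)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

# Split a CDS string into codons.
codons_of <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    abort(sprintf("CDS length %d is not a multiple of 3", n))
  }
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

`%just%` <- function(x, cols) x[, intersect(cols, names(x)), drop = FALSE]
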