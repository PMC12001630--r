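# Intragenic classification, strand-aware 5'->3' relative positions,
# and known-site overlap.

genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    gene_id = genes$gene_id
  )
}

#' Classify variants as intragenic or intergenic
#'
#' A variant is intragenic iff its position falls within the 1-based
#' inclusive `[start, end]` interval of at least one gene on the same
#' chromosome (strand is ignored for overlap). All overlapping gene IDs
#' are reported, so nested/overlapping genes each claim the variant.
#'
#' @param variants Variant tibble.
#' @param genes Gene-model tibble.
#' @return `variants` with logical `intragenic` and list-column
#'   `gene_ids` added.
#' @export
classify_intragenic <- function(variants, genes) {
  vr <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1)
  )
  hits <- GenomicRanges::findOverlaps(vr, genes_to_granges(genes), ignore.strand = TRUE)
  ids <- split(
    genes$gene_id[S4Vectors::subjectHits(hits)],
    factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(variants)))
  )
  variants$gene_ids <- unname(lapply(ids, as.character))
  variants$intragenic <- lengths(variants$gene_ids) > 0
  variants
}

#' Strand-aware relative position within a gene (5' -> 3')
#'
#' `r = 0` at the 5' end and `r = 1` at the 3' end:
#' `(pos - start) / (end - start)` on the + strand and
#' `(end - pos) / (end - start)` on the - strand. Single-base genes
#' return 0 by convention. Vectorized; positions outside the gene are
#' an error.
#'
#' @param pos Variant positions (1-based).
#' @param start,end Gene interval (1-based inclusive).
#' @param strand `"+"` or `"-"` per gene.
#' @return Numeric vector in `[0, 1]`.
#' @export
relative_position <- function(pos, start, end, strand) {
  if (any(pos < start | pos > end)) {
    abort("Variant position outside the gene interval.", class = "satseq_contract_error")
  }
  len <- end - start
  ifelse(len == 0, 0,
    ifelse(strand == "+", (pos - start) / len, (end - pos) / len)
  )
}

#' Relative positions of intragenic variants across all genes
#'
#' Expands each variant over every gene it overlaps and computes the
#' strand-aware 5'->3' relative position — the per-SNP values behind a
#' gene-body position histogram.
#'
#' @param variants Variant tibble.
#' @param genes Gene-model tibble.
#' @return Tibble with `chrom`, `pos`, `gene_id`, `rel_pos`.
#' @export
relative_positions <- function(variants, genes) {
  cls <- classify_intragenic(variants, genes)
  hit <- which(cls$intragenic)
  if (!length(hit)) {
    return(tibble(chrom = character(), pos = integer(), gene_id = character(), rel_pos = numeric()))
  }
  pairs <- tidyr::unnest(
    tibble(chrom = cls$chrom[hit], pos = cls$pos[hit], gene_id = cls$gene_ids[hit]),
    "gene_id"
  )
  g <- genes[match(pairs$gene_id, genes$gene_id), ]
  pairs$rel_pos <- relative_position(pairs$pos, g$start, g$end, g$strand)
  pairs
}

#' Histogram of 5'->3' relative positions
#'
#' Equal-width bins over `[0, 1]`; every bin is left-closed and the
#' last bin is closed on both sides, so counts always sum to the input
#' size. Out-of-range values are an error.
#'
#' @param rel_pos Numeric vector in `[0, 1]`.
#' @param n_bins Number of bins.
#' @return Tibble with `bin`, `lower`, `upper`, `count`.
#' @export
position_histogram <- function(rel_pos, n_bins = 20) {
  stopifnot(n_bins >= 1)
  if (length(rel_pos) && (any(rel_pos < 0) || any(rel_pos > 1))) {
    abort("Relative positions must lie in [0, 1].", class = "satseq_contract_error")
  }
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(findInterval(rel_pos, breaks, rightmost.closed = TRUE), n_bins)
  tibble(
    bin = seq_len(n_bins),
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    count = as.integer(tabulate(idx, nbins = n_bins))
  )
}

#' Gene-body position histogram plot
#'
#' @param rel_pos Numeric vector in `[0, 1]`.
#' @param n_bins Number of bins.
#' @return A ggplot.
#' @export
plot_position_histogram <- function(rel_pos, n_bins = 20) {
  h <- position_histogram(rel_pos, n_bins)
  ggplot2::ggplot(h, ggplot2::aes((.data$lower + .data$upper) / 2, .data$count)) +
    ggplot2::geom_col(width = 1 / n_bins, fill = "#6A3D9A") +
    ggplot2::labs(x = "Relative position along gene body (5' → 3')", y = "SNP count")
}

variant_keys <- function(x, match = c("allele", "position")) {
  match <- match.arg(match)
  if (is.list(x$alt)) {
    x <- tidyr::unnest(tibble(chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt), "alt")
  }
  if (match == "allele") {
    paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
  } else {
    paste(x$chrom, x$pos, sep = ":")
  }
}

#' Overlap of called variants with a known-site catalogue
#'
#' A called variant is known iff it matches a catalogue entry exactly
#' on (chrom, pos, ref, alt) — or on (chrom, pos) with
#' `match = "position"`. Counts satisfy
#' `n_known + n_novel = n_called` always.
#'
#' @param called Variant tibble (list-column `alt` allowed; a record is
#'   known if any of its alternate alleles matches).
#' @param known Known-site tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param match `"allele"` (default) or `"position"`.
#' @return List with `summary` (one-row tibble: `n_called`, `n_known`,
#'   `n_novel`, `fraction_known`) and `is_known` (logical per called
#'   record).
#' @export
known_site_overlap <- function(called, known, match = c("allele", "position")) {
  match <- match.arg(match)
  known_keys <- unique(variant_keys(known, match))
  is_known <- vapply(seq_len(nrow(called)), function(i) {
    keys <- variant_keys(called[i, ], match)
    any(keys %in% known_keys)
  }, logical(1))
  n_called <- nrow(called)
  list(
    summary = tibble(
      n_called = n_called,
      n_known = sum(is_known),
      n_novel = n_called - sum(is_known),
      fraction_known = if (n_called > 0) sum(is_known) / n_called else NA_real_
    ),
    is_known = is_known
  )
}
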