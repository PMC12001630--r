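# VCF / gene-model / known-site readers.

#' Read a VCF into the variant tibble used by the filters
#'
#' Requires per-sample `AD` and `DP` FORMAT fields; the site INFO keys
#' `QD`, `FS`, `MQRankSum`, `ReadPosRankSum`, `SOR` are optional (`NA`
#' when absent). Multiallelic records are kept as single rows (the
#' stringent filter is per-allele).
#'
#' @param path VCF file (plain text or bgzipped).
#' @return Variant tibble: `chrom`, `pos`, `ref`, `alt` (list of
#'   character), the five annotation columns, `ad` (list of samples x
#'   alleles integer matrices, reference allele first), `dp` (list of
#'   integer vectors), and `sample_ids` as an attribute.
#' @export
read_vcf <- function(path) {
  stopifnot(file.exists(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  info_num <- function(key) {
    out <- suppressWarnings(vcfR::extract.info(v, element = key, as.numeric = TRUE))
    if (is.null(out)) rep(NA_real_, n) else as.numeric(out)
  }
  ad_raw <- vcfR::extract.gt(v, element = "AD")
  dp_raw <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)

  ad <- lapply(seq_len(n), function(i) {
    n_alleles <- 1 + length(alts[[i]])
    row <- ad_raw[i, ]
    m <- t(vapply(row, function(cell) {
      if (is.na(cell) || cell == ".") {
        rep(NA_integer_, n_alleles)
      } else {
        vals <- suppressWarnings(as.integer(strsplit(cell, ",", fixed = TRUE)[[1]]))
        length(vals) <- n_alleles
        vals
      }
    }, integer(n_alleles)))
    rownames(m) <- colnames(ad_raw)
    m
  })
  dp <- lapply(seq_len(n), function(i) as.integer(dp_raw[i, ]))

  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = alts,
    qd = info_num("QD"),
    fs = info_num("FS"),
    mq_rank_sum = info_num("MQRankSum"),
    read_pos_rank_sum = info_num("ReadPosRankSum"),
    sor = info_num("SOR"),
    ad = ad,
    dp = dp
  )
  attr(out, "sample_ids") <- colnames(ad_raw)
  out
}

#' Classify records as SNP or INDEL
#'
#' A record is a SNP iff the reference and every alternate allele have
#' length 1; otherwise it is an INDEL (SelectVariants semantics).
#'
#' @param variants Variant tibble.
#' @return `variants` with a `type` column (`"SNP"` / `"INDEL"`).
#' @export
variant_type <- function(variants) {
  variants$type <- ifelse(
    nchar(variants$ref) == 1 &
      vapply(variants$alt, function(a) all(nchar(a) == 1), logical(1)),
    "SNP", "INDEL"
  )
  variants
}

#' Read gene models from GFF3/GTF or TSV
#'
#' GFF3/GTF files are parsed with rtracklayer and subset to
#' `type == "gene"` features; a plain TSV with columns `gene_id`,
#' `chrom`, `start`, `end`, `strand` is also accepted. Coordinates are
#' 1-based inclusive throughout.
#'
#' @param path Annotation file.
#' @param feature_type Feature type to keep from GFF/GTF (default
#'   `"gene"`).
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_models <- function(path, feature_type = "gene") {
  stopifnot(file.exists(path))
  if (grepl("\\.(gff3?|gtf)(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("rtracklayer is required to read GFF/GTF files.")
    }
    gr <- rtracklayer::import(path)
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == feature_type]
    ids <- gr$gene_id %||% gr$ID %||% sprintf("gene%05d", seq_along(gr))
    tibble(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr))
    )
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(df)))
    as_tibble(df[, c("gene_id", "chrom", "start", "end", "strand")])
  }
}

#' Read a known-variant site list
#'
#' Accepts a VCF (read with [read_vcf()]) or a TSV with columns
#' `chrom`, `pos`, `ref`, `alt`. Malformed rows (missing fields) are
#' skipped with a message.
#'
#' @param path File path.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt` (one row per
#'   alternate allele).
#' @export
read_known_sites <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- read_vcf(path)
    return(tidyr::unnest(
      tibble(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt),
      "alt"
    ))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(df)))
  bad <- !complete.cases(df[, c("chrom", "pos", "ref", "alt")])
  if (any(bad)) {
    message(sprintf("Skipping %d malformed known-site entries.", sum(bad)))
    df <- df[!bad, ]
  }
  tibble(
    chrom = as.character(df$chrom), pos = as.integer(df$pos),
    ref = as.character(df$ref), alt = as.character(df$alt)
  )
}
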