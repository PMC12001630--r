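# Synthetic gene models and variant records for exercising the
# variant-filtering and 3'-bias stages.

#' Simulate stranded gene models
#'
#' Random gene intervals on one or more chromosomes with random strand,
#' 1-based inclusive coordinates (GFF convention).
#'
#' @param n_genes Number of genes.
#' @param chroms Chromosome names.
#' @param chrom_length Length of each chromosome.
#' @param length_range Gene length range (bp).
#' @param seed Integer seed.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
simulate_gene_models <- function(n_genes = 150,
                                 chroms = c("1", "2"),
                                 chrom_length = 2e6,
                                 length_range = c(1000, 20000),
                                 seed = 1L) {
  stopifnot(n_genes >= 1, chrom_length > max(length_range))
  withr::with_seed(seed, {
    chrom <- sample(chroms, n_genes, replace = TRUE)
    len <- round(runif(n_genes, length_range[1], length_range[2]))
    start <- sapply(len, function(l) sample.int(chrom_length - l, 1))
    tibble(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      chrom = chrom,
      start = as.integer(start),
      end = as.integer(start + len - 1),
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
  })
}

#' Simulate called variant records with AD/DP and 3'-biased positions
#'
#' Generates a tibble of variant records mimicking a jointly-called,
#' annotated VCF: per-site quality annotations (QD, FS, MQRankSum,
#' ReadPosRankSum, SOR), per-sample allele depths (AD, reference
#' first) and total depths (DP). Intragenic positions are drawn with
#' density proportional to `r^three_prime_bias`, where `r` is the
#' strand-aware relative position toward the 3' end — emulating the 3'
#' coverage bias of poly-A-anchored libraries (`bias = 0` is uniform
#' along the gene body).
#'
#' A configurable fraction of sites is built to fail each filter tier:
#' `p_fail_site` sites get one hard-filter annotation past its
#' threshold, and `p_zero_alt` sites get zero alternate-allele support
#' in every sample (so they fail the lenient criterion by
#' construction).
#'
#' @param n_variants Number of records.
#' @param n_samples Number of samples.
#' @param genes Gene models (tibble as from [simulate_gene_models()]);
#'   required when `intragenic_fraction > 0`.
#' @param intragenic_fraction Fraction of variants placed inside genes.
#' @param three_prime_bias Non-negative exponent of the intragenic
#'   position density toward the 3' end.
#' @param depth_mean Mean per-sample depth (Poisson).
#' @param alt_fraction_shape Beta shape parameters of the per-site
#'   alternate-allele fraction.
#' @param indel_fraction Fraction of records that are INDELs.
#' @param p_fail_site Fraction of sites violating one hard-filter
#'   threshold.
#' @param p_zero_alt Fraction of sites with no alternate support.
#' @param seed Integer seed.
#' @return Variant tibble: `chrom`, `pos`, `ref`, `alt` (list of
#'   character), `qd`, `fs`, `mq_rank_sum`, `read_pos_rank_sum`, `sor`,
#'   `ad` (list of samples x alleles integer matrices), `dp` (list of
#'   integer vectors), plus the simulation-truth columns `sim_gene_id`
#'   and `sim_rel_pos` (`NA` for intergenic records).
#' @export
simulate_variant_records <- function(n_variants = 500,
                                     n_samples = 8,
                                     genes = NULL,
                                     intragenic_fraction = 0.8,
                                     three_prime_bias = 2,
                                     depth_mean = 20,
                                     alt_fraction_shape = c(2, 2),
                                     indel_fraction = 0.1,
                                     p_fail_site = 0.1,
                                     p_zero_alt = 0.1,
                                     seed = 1L) {
  stopifnot(n_variants >= 1, n_samples >= 1, three_prime_bias >= 0, depth_mean > 0)
  if (intragenic_fraction > 0 && (is.null(genes) || nrow(genes) == 0)) {
    abort("Gene models are required when `intragenic_fraction` > 0.")
  }
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    intragenic <- runif(n_variants) < intragenic_fraction
    chrom <- character(n_variants)
    pos <- integer(n_variants)
    sim_gene <- rep(NA_character_, n_variants)
    sim_r <- rep(NA_real_, n_variants)

    if (any(intragenic)) {
      idx <- sample.int(nrow(genes), sum(intragenic), replace = TRUE)
      g <- genes[idx, ]
      # inverse-CDF draw from density (b+1) r^b on [0, 1]
      r <- runif(sum(intragenic))^(1 / (three_prime_bias + 1))
      len <- g$end - g$start
      off <- round(r * len)
      p <- ifelse(g$strand == "+", g$start + off, g$end - off)
      chrom[intragenic] <- g$chrom
      pos[intragenic] <- as.integer(p)
      sim_gene[intragenic] <- g$gene_id
      sim_r[intragenic] <- ifelse(len >= 1,
        ifelse(g$strand == "+", (p - g$start) / len, (g$end - p) / len), 0
      )
    }
    if (any(!intragenic)) {
      n_out <- sum(!intragenic)
      ch <- sample(unique(genes$chrom %||% "1"), n_out, replace = TRUE)
      mx <- max(genes$end %||% 1e6)
      p <- integer(n_out)
      for (i in seq_len(n_out)) {
        for (try in 1:200) {
          cand <- sample.int(mx + 1e5, 1)
          hit <- !is.null(genes) &&
            any(genes$chrom == ch[i] & genes$start <= cand & genes$end >= cand)
          if (!hit) break
        }
        p[i] <- cand
      }
      chrom[!intragenic] <- ch
      pos[!intragenic] <- p
    }

    is_indel <- runif(n_variants) < indel_fraction
    ref <- sample(bases, n_variants, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    ref[is_indel] <- paste0(ref[is_indel], "A")
    # half the INDELs are insertions instead of deletions
    ins <- is_indel & runif(n_variants) < 0.5
    alt[ins] <- paste0(alt[ins], "TT")
    ref[ins] <- substr(ref[ins], 1, 1)

    # site annotations: passing baseline with jitter, a fraction pushed
    # past one randomly chosen hard-filter threshold
    qd <- pmax(rnorm(n_variants, 28, 3), 20.5)
    fs <- pmin(abs(rnorm(n_variants, 4, 3)), 19.5)
    mqrs <- rnorm(n_variants, 0, 2)
    rprs <- rnorm(n_variants, 0, 2)
    sor <- pmin(abs(rnorm(n_variants, 1.5, 0.8)), 4.5)
    fail_site <- runif(n_variants) < p_fail_site
    which_fail <- sample(5, n_variants, replace = TRUE)
    qd[fail_site & which_fail == 1] <- runif(sum(fail_site & which_fail == 1), 2, 19.9)
    fs[fail_site & which_fail == 2] <- runif(sum(fail_site & which_fail == 2), 20.1, 60)
    mqrs[fail_site & which_fail == 3] <- runif(sum(fail_site & which_fail == 3), -20, -12.6)
    rprs[fail_site & which_fail == 4] <- runif(sum(fail_site & which_fail == 4), -15, -8.1)
    sor[fail_site & which_fail == 5] <- runif(sum(fail_site & which_fail == 5), 5.1, 9)

    zero_alt <- runif(n_variants) < p_zero_alt
    f_alt <- rbeta(n_variants, alt_fraction_shape[1], alt_fraction_shape[2])
    ad <- vector("list", n_variants)
    dp <- vector("list", n_variants)
    for (i in seq_len(n_variants)) {
      d <- rpois(n_samples, depth_mean)
      a <- if (zero_alt[i]) rep(0L, n_samples) else rbinom(n_samples, d, f_alt[i])
      ad[[i]] <- cbind(ref = as.integer(d - a), alt = as.integer(a))
      dp[[i]] <- as.integer(d)
    }

    out <- tibble(
      chrom = chrom, pos = pos, ref = ref,
      alt = as.list(alt),
      qd = qd, fs = fs, mq_rank_sum = mqrs, read_pos_rank_sum = rprs, sor = sor,
      ad = ad, dp = dp,
      sim_gene_id = sim_gene, sim_rel_pos = sim_r
    )
    dplyr::arrange(out, .data$chrom, .data$pos)
  })
}

#' @importFrom stats rbeta
NULL

#' Write variant records as a minimal VCF
#'
#' VCFv4.2 text with the site annotations in INFO and per-sample
#' `GT:AD:DP` fields; round-trips through [read_vcf()].
#'
#' @param variants Variant tibble (see [simulate_variant_records()]).
#' @param path Output path.
#' @param sample_ids Sample names (defaults to `s1..sn`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_ids = NULL) {
  n_samples <- nrow(variants$ad[[1]])
  sample_ids <- sample_ids %||% sprintf("s%d", seq_len(n_samples))
  stopifnot(length(sample_ids) == n_samples)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Symmetric odds ratio\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", sample_ids),
      collapse = "\t"
    )
  )
  fmt_info <- function(i) {
    kv <- c(
      QD = variants$qd[i], FS = variants$fs[i], MQRankSum = variants$mq_rank_sum[i],
      ReadPosRankSum = variants$read_pos_rank_sum[i], SOR = variants$sor[i]
    )
    kv <- kv[!is.na(kv)]
    if (!length(kv)) return(".")
    paste(sprintf("%s=%.4g", names(kv), kv), collapse = ";")
  }
  rows <- vapply(seq_len(nrow(variants)), function(i) {
    ad <- variants$ad[[i]]
    dp <- variants$dp[[i]]
    gt <- vapply(seq_len(nrow(ad)), function(j) {
      sprintf("./.:%s:%d", paste(ad[j, ], collapse = ","), dp[j])
    }, character(1))
    paste(c(
      variants$chrom[i], variants$pos[i], ".", variants$ref[i],
      paste(variants$alt[[i]], collapse = ","), ".", ".", fmt_info(i), "GT:AD:DP", gt
    ), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model tibble (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  rows <- sprintf(
    "%s\tsatseq\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s",
    genes$chrom, genes$start, genes$end, genes$strand, genes$gene_id, genes$gene_id
  )
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}
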