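# Shared fixture builders (everything is generated in code).

# Tiny count matrix with explicit values.
toy_counts <- function(m, genes = NULL, samples = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  m <- matrix(as.integer(m), nrow = length(genes), dimnames = list(genes, samples))
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Hand-built variant record as a one-row variant tibble. `ad` is a
# samples x alleles matrix (ref first); `dp` defaults to row sums.
make_variant <- function(chrom = "1", pos = 100L, ref = "A", alt = "T",
                         qd = NA, fs = NA, mqrs = NA, rprs = NA, sor = NA,
                         ad, dp = NULL) {
  if (is.vector(ad)) ad <- matrix(as.integer(ad), nrow = 1)
  storage.mode(ad) <- "integer"
  dp <- dp %||% as.integer(rowSums(ad))
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = list(alt),
    qd = as.numeric(qd), fs = as.numeric(fs), mq_rank_sum = as.numeric(mqrs),
    read_pos_rank_sum = as.numeric(rprs), sor = as.numeric(sor),
    ad = list(ad), dp = list(as.integer(dp))
  )
}

# Random identifier set pair for confusion-metric property tests.
random_set_pair <- function(universe = 50) {
  ids <- sprintf("id%03d", seq_len(universe))
  list(
    a = sample(ids, sample(0:universe, 1)),
    t = sample(ids, sample(0:universe, 1))
  )
}
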