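# Internal helpers shared across modules.

# Deterministic substream seed from a tuple of integers/strings.
# Mixes parts into [0, 2^31 - 2] so the result is always a valid
# set.seed() argument regardless of iteration order at the call site.
derive_seed <- function(...) {
  parts <- list(...)
  m <- 2147483647 # 2^31 - 1, prime
  x <- 104729
  for (p in parts) {
    if (is.character(p)) {
      p <- sum(utf8ToInt(paste(p, collapse = "|")) * 131^(seq_along(utf8ToInt(paste(p, collapse = "|"))) %% 7))
    }
    p <- abs(as.numeric(p)) %% m
    x <- (x * 48271 + p + 1) %% m
  }
  as.integer(x)
}

# Validate a gene-by-sample count matrix; returns it invisibly.
validate_counts <- function(counts, call = rlang::caller_env()) {
  if (!is.matrix(counts)) {
    abort("`counts` must be a genes x samples matrix.", call = call)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must carry gene IDs as rownames and sample IDs as colnames.", call = call)
  }
  if (anyDuplicated(rownames(counts))) {
    abort("Duplicate gene IDs in count matrix.", call = call)
  }
  if (anyDuplicated(colnames(counts))) {
    abort("Duplicate sample IDs in count matrix.", call = call)
  }
  if (any(counts < 0)) {
    abort("Count matrix contains negative entries.", call = call)
  }
  if (any(counts != round(counts))) {
    abort("Count matrix contains non-integer entries.", call = call)
  }
  invisible(counts)
}

# Significance stars at the conventional thresholds used in the figures.
signif_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 5e-2 ~ "*",
    TRUE ~ "ns"
  )
}
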