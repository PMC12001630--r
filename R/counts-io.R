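#' Read a gene-by-sample count matrix
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`matrix_tsv`}{a single TSV with gene IDs in the first column
#'     and one column per sample (the format [write_counts()] emits).}
#'   \item{`star_genecounts`}{one four-column `ReadsPerGene.out.tab`
#'     style file per sample (gene, unstranded, forward-strand,
#'     reverse-strand counts). The leading `N_unmapped` /
#'     `N_multimapping` / `N_noFeature` / `N_ambiguous` summary rows are
#'     split off and returned in the `"summary"` attribute; the counted
#'     column is chosen by `strand_column`. Sample IDs come from
#'     `names(path)`, falling back to file basenames.}
#' }
#'
#' @param path File path (`matrix_tsv`) or character vector of per-sample
#'   file paths (`star_genecounts`).
#' @param dialect `"matrix_tsv"` or `"star_genecounts"`.
#' @param strand_column For `star_genecounts`: `"unstranded"`,
#'   `"forward"` or `"reverse"`.
#' @return Integer matrix (genes x samples) with dimnames; for the STAR
#'   dialect, a tibble of per-sample summary rows is attached as
#'   `attr(, "summary")`.
#' @export
read_counts <- function(path,
                        dialect = c("matrix_tsv", "star_genecounts"),
                        strand_column = c("unstranded", "forward", "reverse")) {
  dialect <- match.arg(dialect)
  strand_column <- match.arg(strand_column)
  if (dialect == "matrix_tsv") {
    stopifnot(length(path) == 1, file.exists(path))
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    gene_ids <- as.character(df[[1]])
    if (anyDuplicated(gene_ids)) abort("Duplicate gene IDs in count file.", class = "satseq_format_error")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
      abort("Counts must be non-negative integers.", class = "satseq_format_error")
    }
    storage.mode(m) <- "integer"
    rownames(m) <- gene_ids
    validate_counts(m)
    m
  } else {
    stopifnot(length(path) >= 1, all(file.exists(path)))
    ids <- names(path) %||% sub("\\.[^.]*$", "", basename(path))
    if (is.null(names(path))) names(path) <- ids
    col <- c(unstranded = 2L, forward = 3L, reverse = 4L)[[strand_column]]
    per <- purrr::imap(path, function(p, id) {
      df <- readr::read_tsv(p,
        col_names = c("gene_id", "unstranded", "forward", "reverse"),
        show_col_types = FALSE, progress = FALSE
      )
      is_summary <- startsWith(df$gene_id, "N_")
      list(
        summary = tibble(
          sample_id = id,
          category = df$gene_id[is_summary],
          count = as.integer(df[[col]][is_summary])
        ),
        counts = setNames(as.integer(df[[col]][!is_summary]), df$gene_id[!is_summary])
      )
    })
    gene_ids <- names(per[[1]]$counts)
    if (anyDuplicated(gene_ids)) abort("Duplicate gene IDs in GeneCounts file.", class = "satseq_format_error")
    m <- vapply(per, function(x) {
      if (!identical(names(x$counts), gene_ids)) {
        abort("GeneCounts files disagree on gene rows.", class = "satseq_format_error")
      }
      x$counts
    }, integer(length(gene_ids)))
    m <- matrix(m, nrow = length(gene_ids), dimnames = list(gene_ids, ids))
    if (any(m < 0)) abort("Counts must be non-negative integers.", class = "satseq_format_error")
    validate_counts(m)
    attr(m, "summary") <- dplyr::bind_rows(purrr::map(per, "summary"))
    m
  }
}

#' Write a count matrix as TSV
#'
#' Genes as rows (first column `gene_id`), one column per sample;
#' round-trips through [read_counts()].
#'
#' @param counts Integer matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- dplyr::bind_cols(
    tibble(gene_id = rownames(counts)),
    as_tibble(counts)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a sample sheet (sample IDs and condition labels) as TSV
#'
#' @param sample_ids Character vector.
#' @param condition Character vector, same length.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sample_ids, condition, path) {
  stopifnot(length(sample_ids) == length(condition))
  readr::write_tsv(tibble(sample_id = sample_ids, condition = condition), path, progress = FALSE)
  invisible(path)
}
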