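# Readers/writers for the package's plain-text exchange formats.

#' Read a summary-statistics table
#'
#' Tab-separated with header columns CHR, POS, A1 (effect allele), A2 and
#' either Z or BETA/SE (converted to Z = BETA/SE), plus N. Extra columns
#' are kept.
#'
#' @param path file path.
#' @return data frame with at least CHR, POS, A1, A2, Z, N.
#' @export
read_sumstats <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("CHR", "POS", "A1", "A2")
  if (!all(need %in% names(x)))
    stop("summary statistics need columns ", paste(need, collapse = ", "))
  if (!"Z" %in% names(x)) {
    if (!all(c("BETA", "SE") %in% names(x)))
      stop("need either Z or BETA and SE columns")
    x$Z <- x$BETA / x$SE
  }
  if (!"N" %in% names(x)) stop("summary statistics need an N column")
  x
}

#' Write a summary-statistics table
#' @param x data frame.
#' @param path file path.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT pathway file
#'
#' One pathway per line: name, description, then tab-separated gene ids.
#' Immune flags and signed subsets are not part of GMT; see
#' [read_immune_labels()] and the paired `.pos.gmt`/`.neg.gmt` convention.
#'
#' @param path file path.
#' @return `gene_set_collection` (immune flags all `FALSE`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  paths <- lapply(lines[nzchar(lines)], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    list(id = f[1L], genes = f[-(1:2)], immune = FALSE)
  })
  structure(paths, class = "gene_set_collection")
}

#' Write a collection (or its signed subsets) as GMT
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @param subset one of "all" (the member lists), "pos" or "neg" (the
#'   signed regulator subsets of signed pathways only).
#' @export
write_gmt <- function(collection, path, subset = c("all", "pos", "neg")) {
  subset <- match.arg(subset)
  lines <- character(0)
  for (p in collection) {
    genes <- switch(subset, all = p$genes, pos = p$pos, neg = p$neg)
    if (is.null(genes) || !length(genes)) next
    lines <- c(lines, paste(c(p$id, "na", genes), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read immune labels (two-column TSV: pathway id, 0/1 flag)
#' @param path file path.
#' @return named logical vector.
#' @export
read_immune_labels <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(as.logical(as.integer(x[[2L]])), x[[1L]])
}

#' Read a BED gene map
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention.
#'
#' @param path file path (3+ columns: chrom, start, end, optional name).
#' @return data frame gene_id, chrom, start, end.
#' @export
read_gene_bed <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(
    gene_id = if (ncol(x) >= 4L) x[[4L]] else sprintf("GENE%03d", seq_len(nrow(x))),
    chrom = x[[1L]],
    start = x[[2L]] + 1L,
    end = x[[3L]]
  )
}
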