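#' Generate a pathway collection with immune labels and signed regulators
#'
#' Samples pathways of random size from a gene universe; a fraction carry
#' an immune label, and a fraction are "signed": their members are
#' partitioned into disjoint positive- and negative-regulator subsets (the
#' structure needed by the signed activity statistic).
#'
#' @param genes character vector of gene ids, or a gene map with a
#'   `gene_id` column; at least 2 genes.
#' @param n_pathways number of pathways.
#' @param immune_fraction probability a pathway is flagged immune.
#' @param signed_fraction probability a pathway carries regulator signs.
#' @param size_range inclusive range of pathway sizes.
#' @param seed integer seed.
#' @return object of class `gene_set_collection`: a list of pathways, each
#'   a list with `id`, `genes`, `immune`, and (if signed) disjoint `pos`
#'   and `neg` regulator subsets.
#' @export
make_pathways <- function(genes, n_pathways, immune_fraction = 0.3,
                          signed_fraction = 0.5, size_range = c(5L, 30L),
                          seed = 1L) {
  if (is.data.frame(genes)) genes <- genes$gene_id
  if (length(genes) < 2L) stop("need at least 2 genes")
  if (max(size_range) > length(genes))
    stop("pathway size exceeds the gene universe")
  assert_prob(immune_fraction, "immune_fraction")
  assert_prob(signed_fraction, "signed_fraction")
  set.seed(seed)
  paths <- lapply(seq_len(n_pathways), function(i) {
    size <- sample(seq(min(size_range), max(size_range)), 1L)
    members <- sample(genes, size)
    p <- list(id = sprintf("PATHWAY%03d", i), genes = sort(members),
              immune = stats::runif(1) < immune_fraction)
    if (stats::runif(1) < signed_fraction) {
      pos_n <- sample(seq_len(size - 1L), 1L)
      pos <- sort(sample(members, pos_n))
      p$pos <- pos
      p$neg <- sort(setdiff(members, pos))
    }
    p
  })
  structure(paths, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d pathways (%d immune, %d signed)\n",
              length(x), sum(vapply(x, `[[`, TRUE, "immune")),
              sum(vapply(x, function(p) !is.null(p$pos), TRUE))))
  invisible(x)
}

#' Signed pathway definitions for activity inference
#'
#' Extracts, from a collection, one signed gene set per signed pathway:
#' regulator genes carry +1 (positive regulator) or -1 (negative
#' regulator).
#'
#' @param collection a [make_pathways()] collection.
#' @return list of signed pathways: `id`, named `signs` vector (+1/-1 per
#'   gene), `immune` flag.
#' @export
signed_pathways <- function(collection) {
  out <- list()
  for (p in collection) {
    if (is.null(p$pos)) next
    signs <- c(stats::setNames(rep(1, length(p$pos)), p$pos),
               stats::setNames(rep(-1, length(p$neg)), p$neg))
    out[[p$id]] <- list(id = p$id, signs = signs, immune = p$immune)
  }
  out
}
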