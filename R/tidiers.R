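#' @importFrom generics tidy glance
NULL

#' Tidy a species-tree search result
#'
#' One row per non-trivial bipartition of the estimated species tree.
#'
#' @param x An `stree_search` object.
#' @param ... Unused.
#' @return Tibble with columns `bipartition` (canonical split key) and
#'   `side_size`.
#' @export
tidy.stree_search <- function(x, ...) {
  keys <- bipartitions(x$tree)
  tibble::tibble(
    bipartition = as.character(keys),
    side_size = lengths(lapply(keys, split_side))
  )
}

#' One-row summary of a species-tree search
#'
#' @param x An `stree_search` object.
#' @param ... Unused.
#' @return Tibble with `criterion`, `score`, `n_genes`, `n_taxa`.
#' @export
glance.stree_search <- function(x, ...) {
  tibble::tibble(
    criterion = x$criterion,
    score = x$score,
    n_genes = x$n_genes,
    n_taxa = ape::Ntip(x$tree)
  )
}

#' @export
generics::tidy

#' @export
generics::glance
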