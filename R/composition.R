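#' Jaccard compositional dissimilarity between two webs
#'
#' Presence/absence dissimilarity of the taxon sets, `(a + b) / (a + b + c)`,
#' where `a` and `b` count taxa unique to each web and `c` the shared taxa.
#' Two empty webs are identical by convention (dissimilarity 0).
#'
#' @param w1,w2 [foodweb] objects.
#' @return dissimilarity in `[0, 1]`; 0 iff the taxon sets are equal, 1 iff
#'   they are disjoint and at least one is non-empty.
#' @seealso [jaccard_similarity()] for the `1 - Jaccard` transform used when
#'   comparing against interaction similarity.
#' @export
jaccard_dissimilarity <- function(w1, w2) {
  k <- composition_counts(w1, w2)
  tot <- sum(k)
  if (tot == 0) return(0)
  (k[["a"]] + k[["b"]]) / tot
}

#' Jaccard compositional similarity
#'
#' @inheritParams jaccard_dissimilarity
#' @return `1 - jaccard_dissimilarity(w1, w2)`.
#' @export
jaccard_similarity <- function(w1, w2) 1 - jaccard_dissimilarity(w1, w2)
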