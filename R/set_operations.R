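#' Venn regions of a collection of gene lists
#'
#' Computes, for every non-empty membership signature over the named lists,
#' the exact set of genes carrying that signature. Signatures partition the
#' union of the lists. Signatures are serialized as `"&"`-joined sorted
#' list names.
#'
#' @param collection Named list of gene-id vectors (2-4 lists for a
#'   drawable diagram; more are accepted, regions are still computed).
#' @return Named list of sorted gene-id vectors, one per non-empty
#'   signature.
#' @export
venn_regions <- function(collection) {
  if (is.null(names(collection)) || any(!nzchar(names(collection))))
    stop_fex("every list must be named")
  if (anyDuplicated(names(collection)))
    stop_fex("duplicate list name '%s'",
             names(collection)[duplicated(names(collection))][1L])
  if (length(collection) < 2L) stop_fex("need >= 2 lists")
  collection <- lapply(collection, function(x) unique(as.character(x)))
  universe <- sort(unique(unlist(collection)))
  member <- vapply(collection, function(l) universe %in% l,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, names(collection)))
  sig <- apply(member, 1L, function(row)
    paste(sort(names(collection)[row]), collapse = "&"))
  split(universe, sig)
}

#' Union or intersection of gene lists
#'
#' @param collection Named list of gene-id vectors (>= 1).
#' @param mode `"union"` or `"intersection"`.
#' @return Sorted character vector of gene ids.
#' @export
combine_lists <- function(collection, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (!length(collection)) stop_fex("need >= 1 list")
  collection <- lapply(collection, as.character)
  out <- if (mode == "union") Reduce(union, collection)
         else Reduce(intersect, collection)
  if (!length(out) && mode == "intersection")
    warning("intersection of the lists is empty")
  sort(unique(out))
}
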