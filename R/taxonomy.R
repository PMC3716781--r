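#' Construct a taxonomy fragment
#'
#' A small rooted fragment of an organismal taxonomy: a set of nodes with
#' labels and a child-to-parent map.  The parent map must be acyclic with
#' exactly one root.  Used to generalize over the organisms a model applies
#' to (e.g. lifting two species to their lowest common ancestor).
#'
#' @param nodes data frame with columns \code{id} and \code{label}.
#' @param parent named character vector mapping child id to parent id.
#' @return An object of class \code{"sf_taxonomy"}.
#' @export
taxonomy_fragment_new <- function(nodes, parent) {
  stopifnot(is.data.frame(nodes), all(c("id", "label") %in% names(nodes)))
  ids <- as.character(nodes$id)
  if (anyDuplicated(ids)) stop("duplicate node ids", call. = FALSE)
  if (!all(names(parent) %in% ids) || !all(parent %in% ids))
    stop("parent map refers to unknown node ids", call. = FALSE)
  roots <- setdiff(ids, names(parent))
  if (length(roots) != 1L)
    stop("taxonomy fragment must have exactly one root, found ",
         length(roots), call. = FALSE)
  # acyclicity: walking up from any node must terminate at the root
  for (id in ids) {
    seen <- character()
    cur <- id
    while (cur %in% names(parent)) {
      if (cur %in% seen) stop("parent map contains a cycle at ", cur, call. = FALSE)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  structure(list(nodes = nodes, parent = parent, root = roots),
            class = "sf_taxonomy")
}

#' @export
print.sf_taxonomy <- function(x, ...) {
  cat("<taxonomy fragment>", nrow(x$nodes), "nodes, root:", x$root, "\n")
  invisible(x)
}

taxonomy_lineage <- function(frag, id) {
  if (!id %in% frag$nodes$id)
    stop("unknown taxonomy node id ", sQuote(id), call. = FALSE)
  path <- id
  cur <- id
  while (cur %in% names(frag$parent)) {
    cur <- frag$parent[[cur]]
    path <- c(path, cur)
  }
  path
}

#' Generalize two organisms to their lowest common ancestor
#'
#' Returns the most specific taxonomy node that is an ancestor (or self) of
#' both arguments under the fragment's parent map.
#'
#' @param frag a taxonomy fragment (\code{\link{taxonomy_fragment_new}}).
#' @param a,b node ids present in the fragment.
#' @return The node id of the lowest common ancestor.
#' @examples
#' frag <- taxonomy_fragment()
#' generalize_organisms(frag, "7625", "frog")  # "33511" (Deuterostomia)
#' @export
generalize_organisms <- function(frag, a, b) {
  stopifnot(inherits(frag, "sf_taxonomy"))
  la <- taxonomy_lineage(frag, as.character(a))
  lb <- taxonomy_lineage(frag, as.character(b))
  common <- la[la %in% lb]
  if (length(common) == 0L)
    stop("nodes ", a, " and ", b, " share no ancestor", call. = FALSE)
  common[[1L]]
}
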