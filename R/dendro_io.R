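# Dendrogram serialization: newick (with internal node labels preserving
# merge order) and a JSON merge list.

#' Export a dendrogram as text
#'
#' `"newick"` writes an ultrametric newick string whose branch lengths
#' are differences of merge heights; each internal node is labelled
#' `m<merge index>` so that a re-import restores the exact merge order
#' (newick alone does not order tied heights). `"merge_json"` writes the
#' merge list verbatim as JSON.
#'
#' @param dendrogram A `trait_dendrogram`.
#' @param format `"newick"` or `"merge_json"`.
#' @return A single character string.
#' @export
export_dendrogram <- function(dendrogram, format = c("newick", "merge_json")) {
  stopifnot(inherits(dendrogram, "trait_dendrogram"))
  format <- match.arg(format)
  if (format == "merge_json") {
    return(jsonlite::toJSON(list(
      labels = dendrogram$labels,
      variant = dendrogram$variant,
      merges = data.frame(left = dendrogram$merge[, 1],
                          right = dendrogram$merge[, 2],
                          height = dendrogram$height,
                          size = dendrogram$size)),
      auto_unbox = TRUE, digits = NA))
  }
  h <- dendrogram$height
  node_text <- function(node, parent_h) {
    if (node < 0) {
      sprintf("%s:%.10g", dendrogram$labels[-node], parent_h)
    } else {
      sprintf("(%s,%s)m%d:%.10g",
              node_text(dendrogram$merge[node, 1], h[node]),
              node_text(dendrogram$merge[node, 2], h[node]),
              node, parent_h - h[node])
    }
  }
  root <- nrow(dendrogram$merge)
  inner <- sprintf("(%s,%s)m%d;",
                   node_text(dendrogram$merge[root, 1], h[root]),
                   node_text(dendrogram$merge[root, 2], h[root]),
                   root)
  inner
}

#' Import a dendrogram from text
#'
#' Inverse of [export_dendrogram()]. Newick input is parsed with
#' \pkg{ape}; internal `m<k>` node labels, when present, restore the
#' original merge order, otherwise merges are ordered by height.
#'
#' @param text Character string produced by [export_dendrogram()] (or any
#'   binary ultrametric newick tree).
#' @param format `"newick"` or `"merge_json"`.
#' @param labels Optional character vector fixing the leaf order of the
#'   result (newick files do not record it); defaults to tip order.
#' @return A `trait_dendrogram`.
#' @export
import_dendrogram <- function(text, format = c("newick", "merge_json"),
                              labels = NULL) {
  format <- match.arg(format)
  if (format == "merge_json") {
    obj <- jsonlite::fromJSON(text)
    merge <- as.matrix(obj$merges[, c("left", "right")])
    dimnames(merge) <- NULL
    return(structure(list(merge = merge, height = as.numeric(obj$merges$height),
                          size = as.integer(obj$merges$size),
                          labels = as.character(obj$labels),
                          variant = obj$variant),
                     class = "trait_dendrogram"))
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse newick text")
  if (!ape::is.binary(tr)) stop("dendrogram import requires a binary tree")
  n <- length(tr$tip.label)
  if (is.null(labels)) labels <- tr$tip.label
  if (!setequal(labels, tr$tip.label) || length(labels) != n) {
    stop("labels must be a permutation of the tree's tip labels")
  }
  leaf_id <- match(tr$tip.label, labels)  # ape tip -> output leaf index
  depth <- ape::node.depth.edgelength(tr)      # root-to-node distance
  node_h <- max(depth[seq_len(n)]) - depth      # ultrametric height
  internal <- (n + 1):(n + tr$Nnode)
  if (!is.null(tr$node.label) && all(grepl("^m[0-9]+$", tr$node.label))) {
    ord <- order(as.integer(sub("^m", "", tr$node.label)))
  } else {
    ord <- order(node_h[internal], internal)
  }
  internal <- internal[ord]
  merge_row <- integer(n + tr$Nnode)            # ape node -> merge index
  merge_row[internal] <- seq_along(internal)
  merge <- matrix(0L, tr$Nnode, 2L)
  size <- integer(tr$Nnode)
  leaf_count <- c(rep(1L, n), integer(tr$Nnode))
  code <- function(node) if (node <= n) -leaf_id[node] else merge_row[node]
  creation <- function(node) if (node <= n) leaf_id[node] else n + merge_row[node]
  for (m in seq_along(internal)) {
    kids <- tr$edge[tr$edge[, 1] == internal[m], 2]
    kids <- kids[order(vapply(kids, creation, integer(1)))]
    merge[m, ] <- vapply(kids, code, integer(1))
    leaf_count[internal[m]] <- sum(leaf_count[kids])
    size[m] <- leaf_count[internal[m]]
  }
  structure(list(merge = merge, height = as.numeric(node_h[internal]),
                 size = size, labels = labels, variant = "imported"),
            class = "trait_dendrogram")
}
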