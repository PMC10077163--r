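# Ward agglomerative clustering via the Lance-Williams recurrence,
# deterministic tie-breaking, tree cutting, and elbow selection of k.

#' Ward agglomerative hierarchical clustering
#'
#' Clusters species by trait dissimilarity with Ward's minimum-variance
#' criterion. The default variant (`"ward.D2"`) runs the Lance-Williams
#' recurrence on squared dissimilarities and reports merge heights on the
#' original scale (square root of the criterion), matching the common
#' default of hierarchical-clustering workflows on Gower matrices; the
#' classic unsquared variant (`"ward.D"`) is available behind the flag.
#' When two candidate merges have exactly equal cost, the pair whose
#' clusters were created earliest (smallest creation indices, row before
#' column) is merged, making the merge sequence fully deterministic.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`) with zero diagonal.
#' @param variant `"ward.D2"` (default) or `"ward.D"`.
#' @return Object of class `trait_dendrogram`: a list with `merge`
#'   (hclust-style (n-1) x 2 matrix; negative entries are leaves),
#'   `height`, `size` (members per merge), `labels`, and `variant`.
#' @export
#' @examples
#' tm <- table3_fixture(coverage = "modal")$trait_matrix
#' dend <- ward_cluster(gower_dissimilarity(tm))
#' tail(dend$height, 3)
ward_cluster <- function(d, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  d <- .validate_dissimilarity(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 items to cluster")
  labels <- rownames(d)

  D <- if (variant == "ward.D2") d^2 else d
  ids <- seq_len(n)            # creation index of each active cluster
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)
  active <- rep(TRUE, n)       # positions in D currently in use
  pos_id <- seq_len(n)         # creation id held at each position

  # positions stay in creation order because merged clusters reuse the
  # lower position; ties are resolved by scanning the upper triangle in
  # row-major order over positions sorted by creation id
  for (m in seq_len(n - 1L)) {
    act <- which(active)
    ord <- act[order(pos_id[act])]
    best <- Inf; bi <- 0L; bj <- 0L
    for (a in seq_len(length(ord) - 1L)) {
      i <- ord[a]
      row <- D[i, ord[(a + 1L):length(ord)]]
      k <- which.min(row)
      if (row[k] < best) { best <- row[k]; bi <- i; bj <- ord[a + k] }
    }
    crit <- best
    height[m] <- if (variant == "ward.D2") sqrt(max(crit, 0)) else crit
    msize[m] <- sizes[bi] + sizes[bj]
    code <- function(pos) {
      id <- pos_id[pos]
      if (id <= n) -id else id - n
    }
    merge[m, ] <- c(code(bi), code(bj))

    si <- sizes[bi]; sj <- sizes[bj]
    others <- ord[ord != bi & ord != bj]
    if (length(others)) {
      sk <- sizes[others]
      D[bi, others] <- D[others, bi] <-
        ((si + sk) * D[bi, others] + (sj + sk) * D[bj, others] - sk * crit) /
        (si + sj + sk)
    }
    sizes[bi] <- si + sj
    active[bj] <- FALSE
    pos_id[bi] <- n + m
  }

  structure(list(merge = merge, height = height, size = msize,
                 labels = labels, variant = variant),
            class = "trait_dendrogram")
}

#' @export
print.trait_dendrogram <- function(x, ...) {
  cat(sprintf("trait_dendrogram: %d leaves, %s linkage, top height %.4g\n",
              length(x$labels), x$variant, max(x$height)))
  invisible(x)
}

#' Convert a trait dendrogram to an hclust object
#'
#' @param x A `trait_dendrogram`.
#' @param ... Ignored.
#' @return A `stats::hclust` object (usable with [stats::cutree()],
#'   `plot()`, etc.).
#' @export
as.hclust.trait_dendrogram <- function(x, ...) {
  leaf_order <- function(node) {
    if (node < 0) return(-node)
    c(leaf_order(x$merge[node, 1]), leaf_order(x$merge[node, 2]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = leaf_order(nrow(x$merge)),
                 labels = x$labels, method = x$variant,
                 call = match.call(), dist.method = "gower"),
            class = "hclust")
}

#' Cut a dendrogram into k functional groups
#'
#' Undoes the last `k - 1` merges and numbers the resulting groups by
#' decreasing size, ties broken by order of first species appearance.
#'
#' @param dendrogram A `trait_dendrogram`.
#' @param k Number of groups, `1 <= k <= n`.
#' @return Data frame with columns `species`, `group` (integer 1..k), and
#'   attribute `k`.
#' @export
cut_tree <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "trait_dendrogram"))
  n <- length(dendrogram$labels)
  if (length(k) != 1 || k < 1 || k > n || k != round(k)) {
    stop("k must be an integer in 1..", n)
  }
  membership <- -seq_len(n)   # cluster id per leaf: start as own leaf
  if (n - k >= 1) {
    for (m in seq_len(n - k)) {
      pair <- dendrogram$merge[m, ]
      membership[membership %in% pair] <- m
    }
  }
  raw <- match(membership, unique(membership))
  sizes <- tabulate(raw)
  first <- match(seq_along(sizes), raw)
  relabel <- order(-sizes, first)
  group <- match(raw, relabel)
  out <- data.frame(species = dendrogram$labels, group = group,
                    stringsAsFactors = FALSE)
  attr(out, "k") <- as.integer(k)
  out
}

#' Elbow selection of the number of functional groups
#'
#' Computes the total within-cluster dispersion
#' `wss(k) = sum_clusters (1 / (2 size)) sum_{i,j in cluster} d_ij^2`
#' along the dendrogram's nested partitions for `k = 2..k_max`, and picks
#' the elbow. If some `k` already attains (numerically) zero dispersion,
#' the smallest such `k` is selected: the curve has hit its floor and the
#' bend is exactly there. Otherwise the `k` maximizing the discrete
#' curvature (second difference) `wss(k-1) - 2 wss(k) + wss(k+1)` over
#' `k = 3..k_max-1` is selected. The full curve is returned so the choice
#' can be overridden by inspection.
#'
#' @param d Dissimilarity matrix used to build the dendrogram.
#' @param dendrogram A `trait_dendrogram` on the same items.
#' @param k_max Largest k scanned; default `min(n - 1, 15)`.
#' @return List of class `elbow_curve`: `k_values`, `wss`, `selected_k`,
#'   `rule` (`"zero_floor"` or `"max_curvature"`).
#' @export
elbow_select <- function(d, dendrogram, k_max = NULL) {
  d <- .validate_dissimilarity(d)
  stopifnot(inherits(dendrogram, "trait_dendrogram"))
  n <- nrow(d)
  if (n != length(dendrogram$labels)) stop("d and dendrogram sizes differ")
  if (is.null(k_max)) k_max <- min(n - 1L, 15L)
  if (k_max < 2 || k_max > n - 1) stop("k_max must be in 2..n-1")

  d2 <- d^2
  ks <- 2:k_max
  wss <- vapply(ks, function(k) {
    cl <- cut_tree(dendrogram, k)$group
    s <- 0
    for (g in unique(cl)) {
      idx <- which(cl == g)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }, numeric(1))

  tol <- 1e-10 * max(wss[1], 1)
  if (any(wss <= tol)) {
    selected <- ks[which(wss <= tol)[1]]
    rule <- "zero_floor"
  } else if (k_max >= 4) {
    inner <- 3:(k_max - 1)
    curv <- wss[match(inner - 1, ks)] - 2 * wss[match(inner, ks)] +
      wss[match(inner + 1, ks)]
    selected <- inner[which.max(curv)]
    rule <- "max_curvature"
  } else {
    selected <- ks[1]
    rule <- "max_curvature"
  }
  structure(list(k_values = ks, wss = wss, selected_k = as.integer(selected),
                 rule = rule),
            class = "elbow_curve")
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat(sprintf("elbow_curve: k in %d..%d, selected k = %d (%s)\n",
              min(x$k_values), max(x$k_values), x$selected_k, x$rule))
  invisible(x)
}
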