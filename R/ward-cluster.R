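#' Ward.D2 hierarchical clustering
#'
#' Agglomerative clustering on Euclidean distances under the Ward.D2
#' criterion: the Lance-Williams update is applied to squared
#' dissimilarities and merge heights are reported on the distance scale.
#' Deterministic given input order: when several pairs attain the minimal
#' distance, the pair with the lowest (row, column) index merges first.
#'
#' @param x A trait matrix tibble from [assemble_trait_matrix()] (an
#'   `individual_id` column plus numeric traits), or a plain numeric matrix.
#' @return A `ward_clustering`: `merge` (hclust-style, negative entries are
#'   singletons), `height` (non-decreasing), `order`, `labels`,
#'   `linkage = "ward.D2"`, `distance = "euclidean"`. Convert with
#'   [as.hclust()].
#' @export
ward_cluster <- function(x) {
  if (is.data.frame(x)) x <- .trait_values(x)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) abort("clustering needs at least 2 rows")
  labels <- rownames(x) %||% as.character(seq_len(n))
  d2 <- as.matrix(stats::dist(x))^2
  diag(d2) <- Inf
  size <- rep(1, n)
  id <- -seq_len(n)              # hclust convention: negative = singleton
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best_d <- min(d2)
    cand <- which(d2 == best_d, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]   # ties: lowest (row, column) pair
    merge[step, ] <- .order_merge_pair(id[i], id[j])
    height[step] <- sqrt(max(best_d, 0))
    ni <- size[i]; nj <- size[j]
    others <- which(active & seq_len(n) != i & seq_len(n) != j)
    if (length(others) > 0) {
      nk <- size[others]
      upd <- ((ni + nk) * d2[i, others] + (nj + nk) * d2[j, others] -
                nk * best_d) / (ni + nj + nk)
      d2[i, others] <- d2[others, i] <- upd
    }
    size[i] <- ni + nj
    id[i] <- step
    active[j] <- FALSE
    d2[j, ] <- Inf
    d2[, j] <- Inf
  }
  structure(
    list(merge = merge, height = height,
         order = .leaf_order(merge, n), labels = labels,
         linkage = "ward.D2", distance = "euclidean"),
    class = "ward_clustering"
  )
}

# hclust merge-row convention: singletons (negative) before clusters, each
# sub-list ascending by absolute value
.order_merge_pair <- function(a, b) {
  v <- c(a, b)
  c(sort(v[v < 0], decreasing = TRUE), sort(v[v > 0]))
}

.leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(n - 1L)
}

#' @export
as.hclust.ward_clustering <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = "ward.D2", dist.method = x$distance,
         call = match.call()),
    class = "hclust"
  )
}

#' @export
print.ward_clustering <- function(x, ...) {
  cat(sprintf("<ward_clustering> %d leaves, %s linkage on %s distance\n",
              length(x$labels), x$linkage, x$distance))
  invisible(x)
}

#' Cut a clustering into k groups
#'
#' @param clustering A `ward_clustering`.
#' @param k Number of groups.
#' @return Integer cluster labels named by leaf label.
#' @export
cut_clusters <- function(clustering, k) {
  cutree(as.hclust(clustering), k = k)
}

#' Export a dendrogram as Newick
#'
#' Writes the merge tree with branch lengths derived from merge heights
#' (leaf = individual id). Requires the `ape` package.
#'
#' @param clustering A `ward_clustering`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the ape package is required to write Newick trees")
  }
  phy <- ape::as.phylo(as.hclust(clustering))
  ape::write.tree(phy, file = path)
  invisible(path)
}
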