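#' Cosine distance matrix between fingerprint vectors
#'
#' `d(x, y) = 1 - cos(x, y)`; distances lie in `[0, 2]` and are invariant
#' to positive rescaling of the vectors.
#'
#' @param vectors Named list of equal-length numeric vectors, or a matrix
#'   with samples in rows.
#' @return A symmetric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
cosine_distance_matrix <- function(vectors) {
  m <- if (is.matrix(vectors)) vectors else
    do.call(rbind, lapply(vectors, as.numeric))
  if (is.null(rownames(m)))
    rownames(m) <- if (!is.matrix(vectors) && !is.null(names(vectors)))
      names(vectors) else sprintf("sample_%d", seq_len(nrow(m)))
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0))
    stop("zero-norm fingerprint for: ",
         paste(rownames(m)[norms == 0], collapse = ", "))
  cosine <- (m %*% t(m)) / (norms %o% norms)
  d <- 1 - cosine
  d[d < 0] <- 0          # clip tiny negative round-off
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Agglomerative clustering with between-groups (average) linkage
#'
#' Unweighted average linkage (UPGMA): at each step the pair of clusters
#' with the smallest average cross-pair distance is merged; ties break
#' lexicographically on (smaller cluster id, larger cluster id) so the
#' merge sequence is reproducible. Height inversions, possible for average
#' linkage on non-ultrametric input, are recorded in the `inversions`
#' attribute rather than hidden.
#'
#' @param d Symmetric distance matrix with zero diagonal (e.g. from
#'   [cosine_distance_matrix()]).
#' @return An object of class `hclust` (merge, height, order, labels,
#'   method = "average") built by the package's own agglomeration, usable
#'   with [stats::cutree()], plotting and Newick export.
#' @export
hca_between_groups <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two samples")
  if (any(abs(d - t(d)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) labels <- sprintf("sample_%d", seq_len(n))

  # active cluster bookkeeping: id < 0 -> leaf -id; id > 0 -> merge row
  active_ids <- -seq_len(n)      # hclust convention
  members <- as.list(seq_len(n)) # leaf indices per active cluster
  cur <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active_ids)
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        dij <- cur[i, j]
        if (dij < best_d - 1e-12) {
          best <- c(i, j); best_d <- dij
        } else if (abs(dij - best_d) <= 1e-12) {
          # lexicographic tie-break on (smaller id, larger id)
          cand <- sort(c(active_ids[i], active_ids[j]))
          inc <- sort(c(active_ids[best[1]], active_ids[best[2]]))
          if (cand[1] < inc[1] || (cand[1] == inc[1] && cand[2] < inc[2])) {
            best <- c(i, j); best_d <- dij
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(active_ids[i], active_ids[j]))
    height[step] <- best_d
    mi <- members[[i]]; mj <- members[[j]]
    # unweighted average linkage update against every other cluster
    keep <- setdiff(seq_len(k), c(i, j))
    newrow <- vapply(keep, function(q)
      (length(mi) * cur[i, q] + length(mj) * cur[j, q]) /
        (length(mi) + length(mj)), numeric(1))
    cur <- cur[keep, keep, drop = FALSE]
    cur <- rbind(cbind(cur, newrow), c(newrow, 0))
    members <- c(members[keep], list(c(mi, mj)))
    active_ids <- c(active_ids[keep], step)
  }
  inversions <- which(diff(height) < -1e-12)
  tree <- structure(
    list(merge = merge, height = height, order = tree_order(merge, n),
         labels = labels, method = "average",
         call = match.call(), dist.method = "cosine"),
    class = "hclust")
  attr(tree, "inversions") <- inversions
  tree
}

# leaf order for plotting: left-to-right traversal of the merge tree
tree_order <- function(merge, n) {
  expand <- function(id) {
    if (id < 0) return(-id)
    c(expand(merge[id, 1]), expand(merge[id, 2]))
  }
  expand_row <- expand(nrow(merge))
  stopifnot(length(expand_row) == n)
  expand_row
}

#' Cut a linkage tree into k groups
#'
#' Undoes the last `k - 1` merges; each remaining subtree is one group.
#' Unlike a height-based cut this is well defined even when average
#' linkage produces height inversions.
#'
#' @param tree An `hclust`-style tree from [hca_between_groups()].
#' @param k Number of groups, `1 <= k <= n`.
#' @return Named integer vector: group label (1..k) per sample, groups
#'   numbered by first appearance in leaf order.
#' @export
cut_groups <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must lie in [1, n]")
  groups <- integer(n)
  if (k == 1L) {
    roots <- n - 1L
  } else {
    # undo the last k-1 merges; the roots are their children that are not
    # themselves undone
    undone <- seq(n - 1L, by = -1L, length.out = k - 1L)
    cand <- as.vector(tree$merge[undone, , drop = FALSE])
    roots <- cand[!(cand %in% undone)]
  }
  leaf_sets <- lapply(roots, function(id)
    if (id < 0) -id else collect_leaves(tree$merge, id))
  # order groups by first leaf appearance in the plotting order
  first_pos <- vapply(leaf_sets, function(s)
    min(match(s, tree$order)), numeric(1))
  leaf_sets <- leaf_sets[order(first_pos)]
  for (g in seq_along(leaf_sets)) groups[leaf_sets[[g]]] <- g
  stats::setNames(groups, tree$labels)
}

collect_leaves <- function(merge, id) {
  if (id < 0) return(-id)
  c(collect_leaves(merge, merge[id, 1]), collect_leaves(merge, merge[id, 2]))
}

#' Export a linkage tree as a Newick string
#'
#' @param tree An `hclust` tree (e.g. from [hca_between_groups()]).
#' @param path Optional file to write; with `NULL` the string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
tree_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Indented text rendering of a linkage tree
#'
#' @param tree An `hclust` tree.
#' @return A character vector, one line per node, suitable for
#'   `writeLines()`.
#' @export
tree_text <- function(tree) {
  render <- function(id, depth) {
    pad <- strrep("  ", depth)
    if (id < 0) return(paste0(pad, tree$labels[-id]))
    c(sprintf("%s+ h=%.6g", pad, tree$height[id]),
      render(tree$merge[id, 1], depth + 1L),
      render(tree$merge[id, 2], depth + 1L))
  }
  render(length(tree$height), 0L)
}
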