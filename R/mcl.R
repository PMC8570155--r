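#' Markov Clustering (MCL) of a weighted network
#'
#' From-scratch implementation of the Markov Cluster algorithm of van Dongen:
#' a random walk on the network is alternately *expanded* (matrix power,
#' simulating longer walks) and *inflated* (entrywise power followed by
#' column normalization, strengthening strong currents and demoting weak
#' ones) until the flow matrix reaches its doubly idempotent limit. The
#' inflation exponent is the granularity knob: larger values give finer
#' clusters. Entries below `prune_threshold` are set to zero after each
#' inflation (then columns are renormalized), keeping the limit sparse.
#'
#' Clusters are read off the limit matrix as connected components of its
#' nonzero structure; within each cluster the attractors (nodes retaining
#' positive flow on the diagonal) are reported. Cluster labels are small
#' integers, numbered by each cluster's lexicographically smallest member so
#' the output is invariant to node input order.
#'
#' @param network A `gene_sharing_network`, or a symmetric nonnegative
#'   weighted adjacency matrix with dimnames.
#' @param inflation Inflation exponent, must exceed 1. Default 1.5.
#' @param expansion Expansion power (integer >= 2). Default 2.
#' @param prune_threshold Entries below this are pruned each iteration.
#' @param max_iter Iteration cap; hitting it sets `converged = FALSE` and
#'   raises a warning rather than an error.
#' @param tol Convergence tolerance on the max entrywise change between
#'   successive flow matrices.
#' @param self_loops Loop policy applied before normalization: `"max"` adds
#'   to each node a loop weighted at its maximum incident edge weight (1 for
#'   isolated nodes), `"one"` adds unit loops, `"none"` adds loops only to
#'   isolated nodes (a walk must have somewhere to go).
#' @return An `mcl_clustering`: list with `membership` (named integer
#'   vector), `n_clusters`, `clusters` (list of member ids), `attractors`
#'   (list per cluster), `converged`, `iterations`, `colsum_dev` (worst
#'   deviation of any column sum from 1 across all iterations), the limit
#'   matrix, and the call parameters.
#' @export
#' @examples
#' A <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
#' A[cbind(c(1, 2, 1, 4, 5, 4), c(2, 3, 3, 5, 6, 6))] <- 1
#' A <- A + t(A)
#' mcl_cluster(A)$n_clusters  # two triangles -> 2
mcl_cluster <- function(network, inflation = 1.5, expansion = 2,
                        prune_threshold = 1e-5, max_iter = 200, tol = 1e-6,
                        self_loops = c("max", "one", "none")) {
  self_loops <- match.arg(self_loops)
  if (inflation <= 1) stop("inflation must be > 1")
  if (expansion < 2) stop("expansion must be >= 2")
  A <- if (inherits(network, "gene_sharing_network"))
    as_adjacency(network) else as.matrix(network)
  if (nrow(A) == 0) stop("empty network")
  if (is.null(rownames(A)))
    dimnames(A) <- list(seq_len(nrow(A)), seq_len(nrow(A)))
  if (any(A < 0)) stop("negative edge weights")
  if (max(abs(A - t(A))) > 1e-12) stop("adjacency must be symmetric")

  maxinc <- apply(A, 2, max)
  diag(A) <- switch(self_loops,
                    max = pmax(maxinc, ifelse(maxinc == 0, 1, 0)),
                    one = 1,
                    none = ifelse(maxinc == 0, 1, 0))

  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(A)
  converged <- FALSE
  iter <- 0
  colsum_dev <- max(abs(colSums(M) - 1))  # worst deviation ever seen
  while (iter < max_iter) {
    iter <- iter + 1
    Mnew <- M
    for (k in seq_len(expansion - 1)) Mnew <- Mnew %*% M
    Mnew <- normalize(Mnew ^ inflation)
    colsum_dev <- max(colsum_dev, abs(colSums(Mnew) - 1))
    Mnew[Mnew < prune_threshold] <- 0
    Mnew <- normalize(Mnew)
    colsum_dev <- max(colsum_dev, abs(colSums(Mnew) - 1))
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter, " iterations")

  # clusters: connected components of the symmetrized nonzero structure
  structure_graph <- igraph::graph_from_adjacency_matrix(
    1 * ((M > 0) | (t(M) > 0)), mode = "undirected", diag = FALSE)
  comp <- igraph::components(structure_graph)$membership
  ids <- rownames(A)
  cluster_sets <- split(ids, comp)
  # deterministic numbering by smallest member id
  ord <- order(vapply(cluster_sets, function(s) min(s), character(1)))
  cluster_sets <- lapply(cluster_sets[ord], sort)
  membership <- stats::setNames(rep(seq_along(cluster_sets),
                                    lengths(cluster_sets)),
                                unlist(cluster_sets))
  membership <- membership[ids]
  attractors <- lapply(cluster_sets, function(s)
    s[diag(M)[match(s, ids)] > 0])

  structure(list(membership = membership,
                 n_clusters = length(cluster_sets),
                 clusters = cluster_sets,
                 attractors = attractors,
                 converged = converged, iterations = iter,
                 colsum_dev = colsum_dev,
                 inflation = inflation, expansion = expansion,
                 prune_threshold = prune_threshold, self_loops = self_loops,
                 limit = M),
            class = "mcl_clustering")
}

#' @export
print.mcl_clustering <- function(x, ...) {
  cat("MCL clustering (inflation ", x$inflation, "): ",
      x$n_clusters, " cluster(s), ",
      length(x$membership), " node(s), ",
      if (x$converged) paste0("converged in ", x$iterations, " iterations")
      else paste0("NOT converged after ", x$iterations, " iterations"),
      "\n", sep = "")
  sizes <- lengths(x$clusters)
  cat("  cluster sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.mcl_clustering <- function(object, ...) {
  data.frame(cluster = seq_along(object$clusters),
             size = lengths(object$clusters),
             attractors = vapply(object$attractors, paste,
                                 character(1), collapse = ","),
             members = vapply(object$clusters, paste,
                              character(1), collapse = ","))
}
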