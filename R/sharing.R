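#' Build a genome-level copy-count matrix from an orthogroup catalog
#'
#' Counts, for every genome in the metadata table and every orthogroup in the
#' catalog, how many member proteins of that orthogroup the genome encodes.
#' Presence/absence (count > 0) is what the sharing statistic uses; the raw
#' copy numbers feed the host-shared orthogroup screen.
#'
#' Genomes present in the metadata but absent from the catalog get all-zero
#' rows (sequenced, sharing nothing). Genomes in the catalog but not in the
#' metadata are an error: the metadata is the taxon registry.
#'
#' @param catalog An `orthogroup_catalog`.
#' @param meta Validated genome metadata table.
#' @return A `count_matrix`: integer matrix (taxa x orthogroups) with
#'   attribute `level = "genome"`.
#' @export
build_count_matrix <- function(catalog, meta) {
  taxa <- meta$virus_id
  stray <- setdiff(unique(catalog$members$virus_id), taxa)
  if (length(stray))
    stop("catalog genome(s) missing from metadata: ",
         paste(stray, collapse = ", "))
  groups <- unique(catalog$members$group_id)
  counts <- matrix(0L, nrow = length(taxa), ncol = length(groups),
                   dimnames = list(taxa, groups))
  if (nrow(catalog$members)) {
    tab <- table(factor(catalog$members$virus_id, levels = taxa),
                 factor(catalog$members$group_id, levels = groups))
    counts[] <- as.integer(tab)
  }
  structure(counts, level = "genome", class = c("count_matrix", "matrix"))
}

#' Collapse a genome-level count matrix to family pangenomes
#'
#' All genes encoded by viruses of the same family are pooled into one
#' pangenome taxon; counts add, presence is the union of member presences.
#'
#' @param counts A genome-level `count_matrix`.
#' @param grouping Named vector mapping every taxon of `counts` to its family
#'   (or any other pooling label).
#' @return A `count_matrix` with `level = "pangenome"`, rows ordered by first
#'   appearance of each family in `counts`.
#' @export
collapse_to_pangenomes <- function(counts, grouping) {
  taxa <- rownames(counts)
  unmapped <- setdiff(taxa, names(grouping))
  if (length(unmapped))
    stop("taxa without a family mapping: ", paste(unmapped, collapse = ", "))
  fam <- as.character(grouping[taxa])
  out <- rowsum(unclass(counts), group = fam, reorder = FALSE)
  storage.mode(out) <- "integer"
  structure(out, level = "pangenome", class = c("count_matrix", "matrix"))
}

#' Compute the normalized gene-sharing statistic
#'
#' For every taxon pair (i, j) of a count matrix, the shared-orthogroup count
#' \eqn{U_{ij}} is the number of orthogroups present (count > 0) in both.
#' \eqn{T_i} is the number of orthogroups of taxon i present in at least one
#' *other* taxon of this matrix — i.e. its orthogroups shared with any taxon.
#' The sharing level is
#' \deqn{S_{ij} = U_{ij} / \sqrt{T_i T_j},}
#' the geometric-mean normalization guarding against one repertoire dwarfing
#' the other. Taxa with \eqn{T = 0} (isolates sharing nothing) get
#' \eqn{S = 0}, never `NaN`. T is always computed over the taxon set of the
#' matrix at hand, so genome-level and pangenome-level S values are
#' deliberately context-dependent.
#'
#' @param counts A `count_matrix` with at least two taxa.
#' @return A `sharing_matrix`: list with `taxa`, integer matrix `U`, integer
#'   vector `T`, numeric matrix `S` in \[0, 1\] (diagonal `NA`), and `level`.
#' @export
compute_sharing <- function(counts) {
  if (nrow(counts) < 2)
    stop("sharing needs at least two taxa")
  P <- matrix(as.numeric(counts > 0), nrow = nrow(counts),
              dimnames = dimnames(counts))
  colpres <- colSums(P)
  U <- tcrossprod(P)
  Tv <- as.vector(P %*% (colpres >= 2))
  denom <- sqrt(outer(Tv, Tv))
  S <- ifelse(denom > 0, U / denom, 0)
  diag(S) <- NA_real_
  storage.mode(U) <- "integer"
  dimnames(S) <- dimnames(U)
  structure(list(taxa = rownames(counts), U = U,
                 T = stats::setNames(as.integer(Tv), rownames(counts)),
                 S = S, level = attr(counts, "level")),
            class = "sharing_matrix")
}

#' @export
print.sharing_matrix <- function(x, ...) {
  cat("Gene-sharing matrix (", x$level, " level)\n", sep = "")
  cat("  taxa:", length(x$taxa), "\n")
  off <- x$S[upper.tri(x$S)]
  if (length(off))
    cat(sprintf("  S range: %.4f - %.4f (mean %.4f)\n",
                min(off), max(off), mean(off)))
  invisible(x)
}

#' @export
summary.sharing_matrix <- function(object, ...) {
  off <- object$S[upper.tri(object$S)]
  out <- list(level = object$level, n_taxa = length(object$taxa),
              n_edges = sum(object$U[upper.tri(object$U)] >= 1),
              S_summary = summary(off), T = object$T)
  class(out) <- "summary.sharing_matrix"
  out
}

#' @export
print.summary.sharing_matrix <- function(x, ...) {
  cat("Gene-sharing matrix (", x$level, " level): ", x$n_taxa, " taxa, ",
      x$n_edges, " sharing pairs\n", sep = "")
  print(x$S_summary)
  invisible(x)
}

#' Build a gene-sharing network from a sharing matrix
#'
#' Nodes are all taxa of the sharing matrix, including isolates; an undirected
#' edge connects every pair sharing at least one orthogroup
#' (\eqn{U_{ij} \ge 1}), weighted by \eqn{S_{ij}}. No weight threshold is
#' applied by default; `min_weight` exists for sensitivity analyses only.
#'
#' @param sharing A `sharing_matrix`.
#' @param meta Optional metadata table (genome level) used to attach a
#'   `family` attribute to nodes.
#' @param min_weight Drop edges with \eqn{S < } `min_weight` (default 0:
#'   keep everything).
#' @return A `gene_sharing_network`: list with `nodes` (data frame `id`,
#'   optional `family`) and `edges` (data frame `source`, `target`,
#'   `weight`).
#' @export
build_network <- function(sharing, meta = NULL, min_weight = 0) {
  taxa <- sharing$taxa
  idx <- which(upper.tri(sharing$U) & sharing$U >= 1, arr.ind = TRUE)
  edges <- data.frame(source = taxa[idx[, 1]], target = taxa[idx[, 2]],
                      weight = sharing$S[idx], stringsAsFactors = FALSE)
  edges <- edges[edges$weight >= min_weight, , drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(id = taxa, stringsAsFactors = FALSE)
  if (!is.null(meta) && all(taxa %in% meta$virus_id))
    nodes$family <- meta$family[match(taxa, meta$virus_id)]
  structure(list(nodes = nodes, edges = edges, level = sharing$level),
            class = "gene_sharing_network")
}

#' @export
print.gene_sharing_network <- function(x, ...) {
  cat("Gene-sharing network (", x$level, " level): ",
      nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Adjacency matrix of a gene-sharing network
#'
#' @param network A `gene_sharing_network`.
#' @return Symmetric numeric matrix of edge weights, zero diagonal.
#' @export
as_adjacency <- function(network) {
  ids <- network$nodes$id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(network$edges)) {
    i <- match(network$edges$source, ids)
    j <- match(network$edges$target, ids)
    A[cbind(i, j)] <- network$edges$weight
    A[cbind(j, i)] <- network$edges$weight
  }
  A
}

#' Plot a gene-sharing network
#'
#' Force-directed layout via igraph; edge width proportional to the sharing
#' level, node color by family (or cluster) when available.
#'
#' @param x A `gene_sharing_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @return The igraph object, invisibly.
#' @export
plot.gene_sharing_network <- function(x, ...) {
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                     vertices = x$nodes)
  col <- NULL
  if (!is.null(x$nodes$family)) {
    fam <- factor(x$nodes$family)
    col <- grDevices::rainbow(nlevels(fam))[as.integer(fam)]
  }
  igraph::plot.igraph(g, edge.width = 1 + 4 * igraph::E(g)$weight,
                      vertex.color = col, ...)
  invisible(g)
}
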