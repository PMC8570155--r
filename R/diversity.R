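#' Average per-genome values within intrafamilial lineages
#'
#' Oversampling of closely related strains would otherwise dominate
#' intrafamilial variation, so every per-genome quantity is first averaged
#' across the genomes of its lineage; between-lineage statistics are then
#' computed on these lineage means.
#'
#' @param values Named numeric vector, genome -> value.
#' @param lineage_map Named character vector, genome -> lineage; every genome
#'   in `values` must be mapped.
#' @return Named numeric vector, lineage -> mean value. Single-genome
#'   lineages pass through unchanged.
#' @export
lineage_means <- function(values, lineage_map) {
  unmapped <- setdiff(names(values), names(lineage_map))
  if (length(unmapped))
    stop("genome(s) without a lineage: ", paste(unmapped, collapse = ", "))
  lin <- lineage_map[names(values)]
  keep <- !is.na(values)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " genome value(s) that are NA")
    values <- values[keep]; lin <- lin[keep]
  }
  tapply(values, lin, mean)[unique(lin)]
}

#' Between-lineage standard deviation per family
#'
#' Sample standard deviation (n - 1 denominator) of lineage-level values
#' within each family; families with fewer than two lineages get `NA` (the
#' spread is undefined, not zero).
#'
#' @param lineage_values Named numeric vector, lineage -> value.
#' @param family_map Named character vector, lineage -> family.
#' @return Named numeric vector, family -> SD.
#' @export
family_sd <- function(lineage_values, family_map) {
  unmapped <- setdiff(names(lineage_values), names(family_map))
  if (length(unmapped))
    stop("lineage(s) without a family: ", paste(unmapped, collapse = ", "))
  fam <- family_map[names(lineage_values)]
  out <- tapply(lineage_values, fam, function(v)
    if (length(v) < 2) NA_real_ else stats::sd(v))
  out[unique(fam)]
}

#' Mean between-lineage patristic distance per family
#'
#' The distance between two lineages is the mean patristic distance (sum of
#' branch lengths, substitutions per site) over all cross-lineage tip pairs;
#' a family's value is the mean over all unordered lineage pairs within it.
#' Families with a single lineage get `NA`. With `representative = TRUE`,
#' each lineage is instead represented by its first tip (a sensitivity mode).
#'
#' @param tree A `phylo` tree whose tips are virus ids.
#' @param lineage_map Named character vector, genome -> lineage. Every mapped
#'   genome must be a tip.
#' @param family_map Named character vector, lineage -> family.
#' @param representative Use one tip per lineage instead of all pairs.
#' @return Named numeric vector, family -> mean distance.
#' @export
mean_interlineage_patristic <- function(tree, lineage_map, family_map,
                                        representative = FALSE) {
  genomes <- names(lineage_map)
  missing <- setdiff(genomes, tree$tip.label)
  if (length(missing))
    stop("genome(s) missing from tree: ", paste(missing, collapse = ", "))
  D <- ape::cophenetic.phylo(tree)

  lineages <- unique(lineage_map)
  fam <- family_map[lineages]
  unmapped <- lineages[is.na(fam)]
  if (length(unmapped))
    stop("lineage(s) without a family: ", paste(unmapped, collapse = ", "))

  lineage_tips <- split(genomes, lineage_map[genomes])
  if (representative)
    lineage_tips <- lapply(lineage_tips, function(t) sort(t)[1])

  pair_dist <- function(l1, l2) {
    mean(D[lineage_tips[[l1]], lineage_tips[[l2]], drop = FALSE])
  }
  out <- vapply(unique(unname(fam)), function(f) {
    ls <- lineages[fam == f]
    if (length(ls) < 2) return(NA_real_)
    pairs <- utils::combn(ls, 2)
    mean(apply(pairs, 2, function(p) pair_dist(p[1], p[2])))
  }, numeric(1))
  out
}

#' Shannon host-supergroup diversity of a family
#'
#' For each family, the proportions \eqn{p_j} of its lineages whose hosts
#' fall in eukaryotic supergroup j (Amoebozoa, Archaeplastida, Discoba,
#' Haptista, Opisthokonta, SAR) give the Shannon index
#' \deqn{D = -\sum_j p_j \ln p_j,}
#' in nats: 0 when all lineages infect one supergroup, \eqn{\ln 6} at a
#' six-way uniform split. Lineages with unknown supergroup are excluded with
#' a warning; a family with no assigned lineage gets `NA`.
#'
#' @param lineage_supergroup Named character vector, lineage -> supergroup.
#' @param family_map Named character vector, lineage -> family.
#' @return Named numeric vector, family -> D (nats).
#' @export
shannon_host_diversity <- function(lineage_supergroup, family_map) {
  unmapped <- setdiff(names(lineage_supergroup), names(family_map))
  if (length(unmapped))
    stop("lineage(s) without a family: ", paste(unmapped, collapse = ", "))
  fam_all <- family_map[names(lineage_supergroup)]
  known <- !is.na(lineage_supergroup) & lineage_supergroup != "unknown"
  if (!all(known))
    warning("excluding ", sum(!known),
            " lineage(s) with unknown host supergroup")
  sg <- lineage_supergroup[known]
  fam <- fam_all[known]
  out <- stats::setNames(rep(NA_real_, length(unique(fam_all))),
                         unique(fam_all))
  for (f in unique(fam)) {
    p <- table(sg[fam == f])
    p <- p[p > 0] / sum(p)
    out[f] <- -sum(p * log(p))
  }
  out
}

#' Supergroup assignment of lineages by majority over their genomes
#'
#' A lineage's host supergroup is the majority supergroup among its genomes;
#' an exact tie is a validation error forcing the user to decide, since a
#' lineage is expected to have one supergroup of hosts.
#'
#' @param meta Validated genome metadata table.
#' @return Named character vector, lineage -> supergroup.
#' @export
lineage_supergroups <- function(meta) {
  vapply(split(meta$host_supergroup, meta$lineage), function(sg) {
    known <- sg[sg != "unknown"]
    if (!length(known)) return("unknown")
    tab <- sort(table(known), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2])
      stop("lineage with tied host supergroups; assign one explicitly")
    names(tab)[1]
  }, character(1))
}

#' Intrafamilial genomic variation vs. host diversity report
#'
#' For every family: the between-lineage sample SD of protein-coding gene
#' counts, the between-lineage SD of unclustered singleton counts (only when
#' the catalog carries a protein index — absence of the index is reported as
#' missing, never zero), the mean between-lineage patristic distance on the
#' core-gene tree, the Shannon host-supergroup diversity D, and the lineage
#' count. Per-genome quantities are lineage-averaged first via
#' [lineage_means()].
#'
#' @param meta Validated genome metadata (must carry `protein_count`).
#' @param catalog Optional `orthogroup_catalog` with singleton information.
#' @param tree Optional core-gene `phylo` tree.
#' @return A `family_variation_report` data frame: `family`,
#'   `lineage_count`, `sd_protein_counts`, `sd_singleton_counts`,
#'   `mean_patristic`, `host_diversity_D`.
#' @export
family_variation_report <- function(meta, catalog = NULL, tree = NULL) {
  lineage_map <- stats::setNames(meta$lineage, meta$virus_id)
  family_map <- stats::setNames(meta$family, meta$lineage)[!duplicated(meta$lineage)]
  families <- unique(meta$family)

  lin_count <- tapply(meta$lineage, meta$family,
                      function(l) length(unique(l)))[families]

  sd_prot <- rep(NA_real_, length(families))
  if ("protein_count" %in% names(meta)) {
    pc <- stats::setNames(as.numeric(meta$protein_count), meta$virus_id)
    sd_prot <- family_sd(lineage_means(pc, lineage_map), family_map)[families]
  }

  sd_single <- rep(NA_real_, length(families))
  if (!is.null(catalog) && isTRUE(catalog$has_singletons)) {
    sc <- table(factor(catalog$singletons$virus_id, levels = meta$virus_id))
    sc <- stats::setNames(as.numeric(sc), meta$virus_id)
    sd_single <- family_sd(lineage_means(sc, lineage_map),
                           family_map)[families]
  }

  mean_pat <- rep(NA_real_, length(families))
  if (!is.null(tree)) {
    present <- meta$virus_id %in% tree$tip.label
    lm_tree <- lineage_map[meta$virus_id[present]]
    mean_pat <- mean_interlineage_patristic(tree, lm_tree,
                                            family_map)[families]
  }

  D <- shannon_host_diversity(lineage_supergroups(meta),
                              family_map)[families]

  out <- data.frame(family = families,
                    lineage_count = as.integer(lin_count),
                    sd_protein_counts = as.numeric(sd_prot),
                    sd_singleton_counts = as.numeric(sd_single),
                    mean_patristic = as.numeric(mean_pat),
                    host_diversity_D = as.numeric(D),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("family_variation_report", "data.frame")
  out
}

#' Plot genomic variation against host diversity
#'
#' One panel per variation measure, each family a labeled point against its
#' Shannon host diversity D.
#'
#' @param x A `family_variation_report`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.family_variation_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panels <- c(sd_protein_counts = "SD protein counts",
              sd_singleton_counts = "SD singleton counts",
              mean_patristic = "Mean patristic distance")
  for (col in names(panels)) {
    graphics::plot(x$host_diversity_D, x[[col]],
                   xlab = "Host diversity D (nats)", ylab = panels[[col]],
                   pch = 19)
    graphics::text(x$host_diversity_D, x[[col]], x$family,
                   pos = 3, cex = 0.7)
  }
  invisible(x)
}
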