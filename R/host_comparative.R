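#' Cross-family virus pairs split by host-type similarity
#'
#' Enumerates every pair (a, b) with a in `famA` and b in `famB` — viruses at
#' roughly the same phylogenetic distance, which disentangles host effects
#' from relatedness — and routes the pair's gene-sharing level S to the
#' *similar* list when both infect `host_type`, to the *dissimilar* list when
#' exactly one does. Pairs where neither virus infects `host_type` are
#' excluded.
#'
#' @param sharing A genome-level `sharing_matrix`.
#' @param meta Validated genome metadata.
#' @param famA,famB The two family labels; each must have at least one virus.
#' @param host_type One of the canonical host types (see
#'   [host_type_aliases()]).
#' @return List with `family_pair`, `host_type`, data frames `similar` and
#'   `dissimilar` (columns `a`, `b`, `S`), counts `n_similar`,
#'   `n_dissimilar`, and `untestable` (no similar or no dissimilar pairs).
#' @export
cross_family_pair_sharing <- function(sharing, meta, famA, famB, host_type) {
  va <- meta$virus_id[meta$family == famA]
  vb <- meta$virus_id[meta$family == famB]
  if (!length(va)) stop("family has no viruses: ", famA)
  if (!length(vb)) stop("family has no viruses: ", famB)
  missing <- setdiff(c(va, vb), sharing$taxa)
  if (length(missing))
    stop("virus(es) absent from sharing matrix: ",
         paste(missing, collapse = ", "))
  host <- stats::setNames(meta$host_type, meta$virus_id)

  pairs <- expand.grid(a = va, b = vb, stringsAsFactors = FALSE)
  pairs$S <- sharing$S[cbind(match(pairs$a, sharing$taxa),
                             match(pairs$b, sharing$taxa))]
  n_match <- (host[pairs$a] == host_type) + (host[pairs$b] == host_type)
  similar <- pairs[n_match == 2, , drop = FALSE]
  dissimilar <- pairs[n_match == 1, , drop = FALSE]
  rownames(similar) <- rownames(dissimilar) <- NULL
  list(family_pair = c(famA, famB), host_type = host_type,
       similar = similar, dissimilar = dissimilar,
       n_similar = nrow(similar), n_dissimilar = nrow(dissimilar),
       untestable = nrow(similar) == 0 || nrow(dissimilar) == 0)
}

#' One-sided Mann-Whitney-Wilcoxon test (similar greater)
#'
#' Tests whether the `similar` sample is stochastically greater than the
#' `dissimilar` sample. Ties are handled by midranks. When
#' `n1 * n2 <= exact_limit` the p value is the exact conditional permutation
#' tail probability, computed by a counting dynamic program over the tie
#' structure of the pooled midranks (all \eqn{\binom{n_1+n_2}{n_1}} group
#' assignments equally likely); otherwise the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction is used.
#'
#' @param similar,dissimilar Nonempty numeric vectors.
#' @param exact_limit Use the exact distribution when
#'   `length(similar) * length(dissimilar)` is at most this. Default 400.
#' @return List with `U` (Mann-Whitney statistic of the similar sample),
#'   `p_value`, `method` (`"exact"` or `"normal"`), `n_similar`,
#'   `n_dissimilar`.
#' @export
#' @examples
#' mww_one_sided(c(3, 4), c(1, 2))$p_value  # 1/6
mww_one_sided <- function(similar, dissimilar, exact_limit = 400) {
  x <- as.numeric(similar); y <- as.numeric(dissimilar)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (anyNA(c(x, y))) stop("NA values in input")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))                      # midranks
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2

  if (n1 * n2 <= exact_limit) {
    # Exact tail P(W_perm >= W) over all C(N, n1) assignments; DP over the
    # doubled midranks (integers), grouped by ties, on the smaller sample.
    flip <- n1 > n2
    m <- if (flip) n2 else n1
    target <- if (flip) sum(r[n1 + seq_len(n2)]) else W
    r2 <- as.integer(round(2 * r))
    groups <- table(r2)
    vals <- as.integer(names(groups))
    mult <- as.integer(groups)
    maxS <- sum(sort(r2, decreasing = TRUE)[seq_len(m)])
    # ways[k+1, s+1] = number of m-subsets of size k with doubled-rank sum s
    ways <- matrix(0, nrow = m + 1, ncol = maxS + 1)
    ways[1, 1] <- 1
    for (g in seq_along(vals)) {
      v <- vals[g]
      take_max <- min(mult[g], m)
      ch <- choose(mult[g], 0:take_max)
      new <- matrix(0, nrow = m + 1, ncol = maxS + 1)
      for (t in 0:take_max) {
        add <- t * v
        kk <- seq_len(m + 1 - t)
        ss <- seq_len(maxS + 1 - add)
        new[kk + t, ss + add] <- new[kk + t, ss + add] +
          ch[t + 1] * ways[kk, ss]
      }
      ways <- new
    }
    counts <- ways[m + 1, ]
    sums <- (seq_len(maxS + 1) - 1) / 2   # back to midrank scale
    total <- choose(N, m)
    if (flip) {
      # small sample is the dissimilar one: similar large <=> dissimilar small
      p <- sum(counts[sums <= target + 1e-9]) / total
    } else {
      p <- sum(counts[sums >= target - 1e-9]) / total
    }
    list(U = U, p_value = min(1, p), method = "exact",
         n_similar = n1, n_dissimilar = n2)
  } else {
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - 0.5) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    list(U = U, p_value = p, method = "normal",
         n_similar = n1, n_dissimilar = n2)
  }
}

#' Compare gene sharing between similar- and dissimilar-host virus pairs
#'
#' Convenience wrapper: [cross_family_pair_sharing()] followed by
#' [mww_one_sided()] on the two value lists (similar stochastically
#' greater).
#'
#' @inheritParams cross_family_pair_sharing
#' @param exact_limit Passed to [mww_one_sided()].
#' @return A `host_pair_comparison`: the pair-sharing list plus
#'   `U_statistic`, `p_value`, `method` (`NA` when untestable).
#' @export
host_compare <- function(sharing, meta, famA, famB, host_type,
                         exact_limit = 400) {
  cmp <- cross_family_pair_sharing(sharing, meta, famA, famB, host_type)
  if (cmp$untestable) {
    cmp$U_statistic <- NA_real_
    cmp$p_value <- NA_real_
    cmp$method <- NA_character_
  } else {
    tst <- mww_one_sided(cmp$similar$S, cmp$dissimilar$S,
                         exact_limit = exact_limit)
    cmp$U_statistic <- tst$U
    cmp$p_value <- tst$p_value
    cmp$method <- tst$method
  }
  class(cmp) <- "host_pair_comparison"
  cmp
}

#' @export
print.host_pair_comparison <- function(x, ...) {
  cat("Gene sharing, ", x$family_pair[1], " vs ", x$family_pair[2],
      ", host type: ", x$host_type, "\n", sep = "")
  cat("  similar-host pairs:  n = ", x$n_similar, "\n", sep = "")
  cat("  dissimilar-host pairs: n = ", x$n_dissimilar, "\n", sep = "")
  if (x$untestable) {
    cat("  untestable (an arm is empty)\n")
  } else {
    cat(sprintf("  one-sided MWW (%s): U = %g, p = %.4g\n",
                x$method, x$U_statistic, x$p_value))
  }
  invisible(x)
}

#' Screen for orthogroups shared by viruses of a target host type
#'
#' An orthogroup is *shared by the target host type* when it is present in at
#' least one target-host virus of each of the two families; *shared by the
#' reference host type* analogously. The report lists orthogroups shared by
#' target but not by reference, with:
#' \describe{
#'   \item{freq_target}{carrier proportion among target-host viruses,
#'     averaged across the two families}
#'   \item{freq_reference}{same among reference-host viruses}
#'   \item{freq_diff}{`freq_target - freq_reference`}
#'   \item{mean_copy_number}{mean gene copy number among target-host carrier
#'     viruses, averaged across the families that have at least one carrier}
#' }
#' Rows are sorted by `freq_diff` descending, ties by orthogroup id. Rows
#' with non-positive `freq_diff` are retained; filter downstream if desired.
#'
#' @param counts Genome-level `count_matrix`.
#' @param meta Validated genome metadata.
#' @param famA,famB Family labels; each needs at least one target-host and
#'   one reference-host virus.
#' @param target,reference Host types being contrasted.
#' @param annotations Optional annotation data frame (`orthogroup_id`,
#'   `annotation`).
#' @return A `host_shared_report` data frame: `orthogroup_id`,
#'   `freq_target`, `freq_reference`, `freq_diff`, `mean_copy_number`,
#'   `annotation`.
#' @export
host_shared_orthogroups <- function(counts, meta, famA, famB,
                                    target, reference, annotations = NULL) {
  host <- stats::setNames(meta$host_type, meta$virus_id)
  fam <- stats::setNames(meta$family, meta$virus_id)
  taxa <- rownames(counts)
  strata <- list()
  for (f in c(famA, famB)) for (h in c(target, reference)) {
    v <- taxa[fam[taxa] == f & host[taxa] == h & !is.na(fam[taxa])]
    if (!length(v))
      stop("no ", h, "-host virus in family ", f)
    strata[[paste(f, h, sep = "|")]] <- v
  }
  P <- unclass(counts) > 0
  pres_any <- function(v) colSums(P[v, , drop = FALSE]) > 0
  tA <- strata[[paste(famA, target, sep = "|")]]
  tB <- strata[[paste(famB, target, sep = "|")]]
  rA <- strata[[paste(famA, reference, sep = "|")]]
  rB <- strata[[paste(famB, reference, sep = "|")]]

  shared_target <- pres_any(tA) & pres_any(tB)
  shared_ref <- pres_any(rA) & pres_any(rB)
  keep <- which(shared_target & !shared_ref)

  freq_in <- function(v, g) mean(P[v, g])
  rows <- lapply(colnames(counts)[keep], function(g) {
    ft <- mean(c(freq_in(tA, g), freq_in(tB, g)))
    fr <- mean(c(freq_in(rA, g), freq_in(rB, g)))
    copy_fam <- function(v) {
      carriers <- v[P[v, g]]
      if (!length(carriers)) return(NA_real_)
      mean(unclass(counts)[carriers, g])
    }
    cn <- c(copy_fam(tA), copy_fam(tB))
    data.frame(orthogroup_id = g, freq_target = ft, freq_reference = fr,
               freq_diff = ft - fr,
               mean_copy_number = mean(cn, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(orthogroup_id = character(), freq_target = numeric(),
               freq_reference = numeric(), freq_diff = numeric(),
               mean_copy_number = numeric(), stringsAsFactors = FALSE)
  ann_vals <- rep(NA_character_, nrow(out))
  if (!is.null(annotations))
    ann_vals <- annotations$annotation[match(out$orthogroup_id,
                                             annotations$orthogroup_id)]
  ann_vals[is.na(ann_vals)] <- ""
  out$annotation <- ann_vals
  out <- out[order(-out$freq_diff, out$orthogroup_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "family_pair") <- c(famA, famB)
  attr(out, "target") <- target
  attr(out, "reference") <- reference
  class(out) <- c("host_shared_report", "data.frame")
  out
}

#' Presence/absence matrix of report orthogroups across all genomes
#'
#' Exports the presence/absence block behind a host-shared report
#' (orthogroups x genomes), with genomes ordered along the core-gene tree
#' when one is supplied — ready for external heat-map plotting.
#'
#' @param report A `host_shared_report`.
#' @param counts The genome-level `count_matrix` the report came from.
#' @param tree Optional `phylo`; genomes are ordered by its tip order.
#' @return Integer 0/1 matrix, rows = report orthogroups, columns = genomes.
#' @export
report_presence_matrix <- function(report, counts, tree = NULL) {
  genomes <- rownames(counts)
  if (!is.null(tree))
    genomes <- c(intersect(tree$tip.label, genomes),
                 setdiff(genomes, tree$tip.label))
  m <- t(unclass(counts)[genomes, report$orthogroup_id, drop = FALSE] > 0)
  storage.mode(m) <- "integer"
  m
}
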