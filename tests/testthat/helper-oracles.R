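# Independent oracles and fixture builders shared across tests.
# Everything here works from first principles (set enumeration, double
# loops) and never calls the code paths it checks.

# Brute-force sharing statistic from per-taxon orthogroup sets:
# U by direct intersection, T_i as the size of the union of i's pairwise
# intersections with every other taxon, S = U / sqrt(T_i T_j) (0 if a T
# is 0).
oracle_sharing <- function(sets) {
  taxa <- names(sets)
  n <- length(sets)
  U <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n))
    for (j in seq_len(n))
      U[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  Tv <- vapply(seq_len(n), function(i) {
    shared <- character()
    for (j in seq_len(n)[-i])
      shared <- union(shared, intersect(sets[[i]], sets[[j]]))
    length(shared)
  }, integer(1))
  S <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n))
    for (j in seq_len(n))
      S[i, j] <- if (Tv[i] > 0 && Tv[j] > 0)
        U[i, j] / sqrt(Tv[i] * Tv[j]) else 0
  diag(S) <- NA_real_
  list(U = U, T = stats::setNames(Tv, taxa), S = S)
}

# Random per-taxon orthogroup sets over a small shared pool.
random_sets <- function(n_taxa = 5, pool = 12, p = 0.4) {
  pool_ids <- sprintf("og%02d", seq_len(pool))
  sets <- lapply(seq_len(n_taxa), function(i)
    pool_ids[stats::runif(pool) < p])
  names(sets) <- sprintf("tax%02d", seq_len(n_taxa))
  sets
}

# Turn per-taxon sets into a count_matrix-compatible 0/1 matrix.
sets_to_counts <- function(sets) {
  pool <- sort(unique(unlist(sets)))
  m <- matrix(0L, length(sets), length(pool),
              dimnames = list(names(sets), pool))
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1L
  structure(m, level = "genome", class = c("count_matrix", "matrix"))
}

# Minimal metadata table for hand-built fixtures.
make_meta <- function(virus_id, family, host_type = "other/unknown",
                      lineage = virus_id, host_supergroup = "unknown",
                      protein_count = NA_integer_) {
  validate_genome_metadata(data.frame(
    virus_id = virus_id, family = family, lineage = lineage,
    host_type = host_type, host_supergroup = host_supergroup,
    protein_count = protein_count, stringsAsFactors = FALSE))
}

# Double-loop oracle for the host-shared orthogroup screen: iterates over
# orthogroups and genomes directly on a counts matrix.
oracle_host_screen <- function(counts, meta, famA, famB, target, reference) {
  host <- stats::setNames(meta$host_type, meta$virus_id)
  fam <- stats::setNames(meta$family, meta$virus_id)
  stratum <- function(f, h)
    rownames(counts)[fam[rownames(counts)] == f & host[rownames(counts)] == h]
  tA <- stratum(famA, target); tB <- stratum(famB, target)
  rA <- stratum(famA, reference); rB <- stratum(famB, reference)
  rows <- list()
  for (g in colnames(counts)) {
    in_tA <- sum(counts[tA, g] > 0); in_tB <- sum(counts[tB, g] > 0)
    in_rA <- sum(counts[rA, g] > 0); in_rB <- sum(counts[rB, g] > 0)
    if (in_tA >= 1 && in_tB >= 1 && !(in_rA >= 1 && in_rB >= 1)) {
      ft <- mean(c(in_tA / length(tA), in_tB / length(tB)))
      fr <- mean(c(in_rA / length(rA), in_rB / length(rB)))
      cns <- c()
      for (v in list(tA, tB)) {
        carriers <- v[counts[v, g] > 0]
        if (length(carriers))
          cns <- c(cns, mean(counts[carriers, g]))
      }
      rows[[g]] <- data.frame(orthogroup_id = g, freq_target = ft,
                              freq_reference = fr, freq_diff = ft - fr,
                              mean_copy_number = mean(cns),
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(orthogroup_id = character(), freq_target = numeric(),
               freq_reference = numeric(), freq_diff = numeric(),
               mean_copy_number = numeric())
  out <- out[order(-out$freq_diff, out$orthogroup_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random genome-level counts with family/host labels, for screen oracles.
random_host_fixture <- function(n_per_stratum = 2, pool = 15,
                                copy_max = 3) {
  strata <- expand.grid(family = c("FA", "FB"),
                        host = c("vertebrate", "insect"),
                        stringsAsFactors = FALSE)
  ids <- character(); fams <- character(); hosts <- character()
  for (k in seq_len(nrow(strata))) {
    ids <- c(ids, sprintf("%s_%s_%d", strata$family[k],
                          substr(strata$host[k], 1, 3),
                          seq_len(n_per_stratum)))
    fams <- c(fams, rep(strata$family[k], n_per_stratum))
    hosts <- c(hosts, rep(strata$host[k], n_per_stratum))
  }
  counts <- matrix(stats::rpois(length(ids) * pool, 0.6) *
                     (stats::runif(length(ids) * pool) < 0.5),
                   nrow = length(ids),
                   dimnames = list(ids, sprintf("og%02d", seq_len(pool))))
  storage.mode(counts) <- "integer"
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  counts <- structure(counts, level = "genome",
                      class = c("count_matrix", "matrix"))
  meta <- make_meta(ids, fams, host_type = hosts)
  list(counts = counts, meta = meta)
}

# Catalog fixture written as a plain groups data frame.
make_catalog <- function(...) {
  members <- do.call(rbind, lapply(list(...), function(x)
    data.frame(group_id = x[1], virus_id = x[2], protein_id = x[3],
               stringsAsFactors = FALSE)))
  new_orthogroup_catalog(members)
}
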