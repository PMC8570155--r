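#' Parameters for the synthetic giant-virus gene-content generator
#'
#' The generator plants the gene-content structure the analyses are designed
#' to detect: a handful of universal core orthogroups (the analog of the few
#' widely distributed proteins used for core-gene phylogenies), family-core
#' pools retained stochastically by each member genome, lineage-private
#' repertoires, cross-family host-type gene pools (genes carried by every
#' virus of a host type regardless of family), genome-private singletons,
#' and per-gene copy numbers of 1 + Poisson(`copy_lambda`).
#'
#' Defaults describe the regime used throughout the package's own
#' validation: 4 families x 3 lineages x 4 genomes, family-core retention
#' 0.8, two host-type pools of 30 genes at retention 0.7 each spanning two
#' families. Pool sizes are anchored to realistic giant-virus scales: a few
#' hundred protein-coding genes per genome, of which the large majority are
#' family- or lineage-specific, a few dozen are host-type-associated, and
#' around seventy are unclustered singletons.
#'
#' @param n_families,lineages_per_family,genomes_per_lineage Shape of the
#'   planted taxonomy.
#' @param n_universal_core Orthogroups carried by every genome.
#' @param family_core_pool_size,retention_prob Size of each family's core
#'   pool and the per-genome, per-gene retention probability.
#' @param core_universe_factor Family core pools are sampled from a common
#'   gene universe of `core_universe_factor * family_core_pool_size`
#'   orthogroups, so two families' pools overlap by chance (about
#'   `1 / core_universe_factor` of each pool). This background homology is
#'   what gives real virus families their nonzero baseline sharing; a very
#'   large factor makes the pools effectively disjoint.
#' @param lineage_private_pool_size Orthogroups carried by every genome of a
#'   lineage and no one else.
#' @param host_gene_pool_size,host_retention_prob Size of each host type's
#'   cross-family pool and the per-genome retention probability. A size of 0
#'   (or retention 0) is the null: no planted host signal.
#' @param singletons_per_genome Poisson mean of per-genome singleton counts.
#' @param copy_lambda Poisson mean of *extra* copies per present gene; 0
#'   makes every count 0/1.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(n_families = 4, lineages_per_family = 3,
                              genomes_per_lineage = 4,
                              n_universal_core = 5,
                              family_core_pool_size = 250,
                              retention_prob = 0.8,
                              core_universe_factor = 40,
                              lineage_private_pool_size = 100,
                              host_gene_pool_size = 30,
                              host_retention_prob = 0.7,
                              singletons_per_genome = 70,
                              copy_lambda = 0.1,
                              seed = 1) {
  p <- list(n_families = n_families,
            lineages_per_family = lineages_per_family,
            genomes_per_lineage = genomes_per_lineage,
            n_universal_core = n_universal_core,
            family_core_pool_size = family_core_pool_size,
            retention_prob = retention_prob,
            core_universe_factor = core_universe_factor,
            lineage_private_pool_size = lineage_private_pool_size,
            host_gene_pool_size = host_gene_pool_size,
            host_retention_prob = host_retention_prob,
            singletons_per_genome = singletons_per_genome,
            copy_lambda = copy_lambda,
            seed = as.integer(seed))
  sizes <- c("n_families", "lineages_per_family", "genomes_per_lineage",
             "n_universal_core", "family_core_pool_size",
             "lineage_private_pool_size", "host_gene_pool_size",
             "singletons_per_genome")
  for (s in sizes)
    if (p[[s]] < 0) stop(s, " must be >= 0")
  if (p$n_families < 1 || p$lineages_per_family < 1 ||
      p$genomes_per_lineage < 1)
    stop("taxonomy dimensions must be >= 1")
  for (s in c("retention_prob", "host_retention_prob"))
    if (p[[s]] < 0 || p[[s]] > 1) stop(s, " must be in [0, 1]")
  if (p$copy_lambda < 0) stop("copy_lambda must be >= 0")
  if (p$core_universe_factor < 1) stop("core_universe_factor must be >= 1")
  class(p) <- "simulation_params"
  p
}

# Host types are assigned at the lineage level: families are grouped in
# consecutive pairs, the first pair alternating vertebrate/insect lineages,
# the second alga/amoeba, then cycling. Each host type therefore spans (at
# least) two families, mirroring the family-pair comparisons.
.sim_host_scheme <- function(n_families, lineages_per_family) {
  pairs <- list(c("vertebrate", "insect"), c("alga", "amoeba"))
  host <- matrix("", n_families, lineages_per_family)
  for (f in seq_len(n_families)) {
    types <- pairs[[((f - 1) %/% 2) %% 2 + 1]]
    for (l in seq_len(lineages_per_family))
      host[f, l] <- types[(l - 1) %% 2 + 1]
  }
  host
}

.sim_supergroup <- function(host_type, lineage_index) {
  algal <- c("Archaeplastida", "Haptista", "SAR")
  switch(host_type,
         vertebrate = "Opisthokonta",
         insect = "Opisthokonta",
         amoeba = "Amoebozoa",
         alga = algal[(lineage_index - 1) %% 3 + 1],
         "unknown")
}

#' Simulate an orthogroup catalog with planted structure
#'
#' Generates a full synthetic dataset — orthogroup catalog (with protein
#' index and singletons), genome metadata, a core-gene tree consistent with
#' the family/lineage nesting, and the ground truth of what was planted —
#' so every pipeline stage can be exercised without any external data.
#'
#' Orthogroups that end up with fewer than two member proteins (possible for
#' sparsely retained pool genes) are demoted to singletons, matching the
#' upstream convention that a cluster has at least two sequences.
#'
#' @param params A [simulation_params()] object.
#' @return List with `catalog` (an `orthogroup_catalog`), `meta` (validated
#'   metadata), `tree` (`phylo`), `protein_index`, and `truth` (list:
#'   `family` genome -> family, `lineage`, `host_type`, `host_genes` named
#'   list host type -> planted orthogroup ids, `universal`, `family_core`,
#'   `lineage_private`).
#' @export
simulate_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  nf <- params$n_families; nl <- params$lineages_per_family
  ng <- params$genomes_per_lineage

  host_scheme <- .sim_host_scheme(nf, nl)
  og_counter <- 0L
  next_ogs <- function(k) {
    ids <- sprintf("OG%04d", og_counter + seq_len(k))
    og_counter <<- og_counter + as.integer(k)
    ids
  }
  universal <- next_ogs(params$n_universal_core)
  core_universe <- next_ogs(ceiling(params$core_universe_factor *
                                      params$family_core_pool_size))
  family_core <- lapply(seq_len(nf), function(f)
    sort(sample(core_universe, params$family_core_pool_size)))
  names(family_core) <- sprintf("Fam%d", seq_len(nf))
  lineage_private <- list()
  host_types_used <- unique(as.vector(host_scheme))
  host_pools <- lapply(host_types_used, function(h)
    next_ogs(params$host_gene_pool_size))
  names(host_pools) <- host_types_used

  meta_rows <- list()
  member_rows <- list()
  index_rows <- list()

  for (f in seq_len(nf)) {
    fam <- sprintf("Fam%d", f)
    for (l in seq_len(nl)) {
      lin <- sprintf("%s_L%d", fam, l)
      lineage_private[[lin]] <- next_ogs(params$lineage_private_pool_size)
      h <- host_scheme[f, l]
      sg <- .sim_supergroup(h, l)
      for (g in seq_len(ng)) {
        vid <- sprintf("F%02dL%02dG%02d", f, l, g)
        present <- c(
          universal,
          family_core[[fam]][stats::runif(params$family_core_pool_size) <
                               params$retention_prob],
          lineage_private[[lin]],
          host_pools[[h]][stats::runif(params$host_gene_pool_size) <
                            params$host_retention_prob])
        copies <- 1L + stats::rpois(length(present), params$copy_lambda)
        n_prot <- sum(copies)
        n_single <- stats::rpois(1, params$singletons_per_genome)
        prot_ids <- sprintf("P%05d", seq_len(n_prot + n_single))
        if (n_prot > 0)
          member_rows[[vid]] <- data.frame(
            group_id = rep(present, copies),
            virus_id = vid,
            protein_id = prot_ids[seq_len(n_prot)],
            stringsAsFactors = FALSE)
        index_rows[[vid]] <- data.frame(
          virus_id = vid, protein_id = prot_ids, stringsAsFactors = FALSE)
        meta_rows[[vid]] <- data.frame(
          virus_id = vid, family = fam, lineage = lin,
          host_type = h, host_supergroup = sg,
          genome_size = NA_integer_,
          protein_count = n_prot + n_single,
          stringsAsFactors = FALSE)
      }
    }
  }

  members <- do.call(rbind, member_rows)
  rownames(members) <- NULL
  # demote under-populated orthogroups (single member) to singletons
  size <- table(members$group_id)
  small <- names(size)[size < 2]
  if (length(small))
    members <- members[!(members$group_id %in% small), , drop = FALSE]
  meta <- do.call(rbind, meta_rows)
  rownames(meta) <- NULL
  # fabricated genome sizes: roughly 1 kb per protein plus noise
  meta$genome_size <- as.integer(round(
    meta$protein_count * 1000 * stats::runif(nrow(meta), 0.9, 1.1)))
  meta <- validate_genome_metadata(meta)
  protein_index <- do.call(rbind, index_rows)
  rownames(protein_index) <- NULL

  catalog <- new_orthogroup_catalog(members, protein_index)
  tree <- .sim_tree(meta)

  surviving <- unique(members$group_id)
  truth <- list(
    family = stats::setNames(meta$family, meta$virus_id),
    lineage = stats::setNames(meta$lineage, meta$virus_id),
    host_type = stats::setNames(meta$host_type, meta$virus_id),
    host_genes = lapply(host_pools, function(p) intersect(p, surviving)),
    universal = universal,
    family_core = family_core,
    lineage_private = lineage_private,
    seed = params$seed)

  list(catalog = catalog, meta = meta, tree = tree,
       protein_index = protein_index, truth = truth, params = params)
}

# Coalescent-flavoured tree honouring the family/lineage nesting: genomes
# fan out of their lineage node, lineages out of their family node, families
# out of the root, with exponential branch lengths whose means grow with
# depth (0.02 / 0.1 / 0.3 substitutions per site). Not calibrated to any
# real clock; it only has to give diversity metrics nontrivial structure.
.sim_tree <- function(meta) {
  # subtrees carried as (newick string without root branch, pending length);
  # single-child nodes collapse by adding their branch to the child's
  join <- function(children, own_len) {
    if (length(children) == 1) {
      ch <- children[[1]]
      return(list(str = ch$str, len = ch$len + own_len))
    }
    inner <- paste(vapply(children, function(ch)
      sprintf("%s:%.6f", ch$str, ch$len), character(1)), collapse = ",")
    list(str = paste0("(", inner, ")"), len = own_len)
  }
  fams <- lapply(unique(meta$family), function(f) {
    lins <- lapply(unique(meta$lineage[meta$family == f]), function(l) {
      tips <- meta$virus_id[meta$lineage == l]
      children <- lapply(tips, function(t)
        list(str = t, len = stats::rexp(1, rate = 1 / 0.02)))
      join(children, stats::rexp(1, rate = 1 / 0.1))
    })
    join(lins, stats::rexp(1, rate = 1 / 0.3))
  })
  root <- join(fams, 0)
  nwk <- if (length(fams) == 1)
    paste0("(", sprintf("%s:%.6f", fams[[1]]$str, fams[[1]]$len), ");") else
    paste0(root$str, ";")
  ape::read.tree(text = nwk)
}

#' Write a simulated dataset in the package's input formats
#'
#' Emits exactly the files [read_orthogroups()], [read_genome_metadata()],
#' [read_protein_index()] and [read_core_tree()] consume: `groups.txt`,
#' `metadata.tsv`, `protein_index.tsv`, `tree.nwk`. TSV and groups files
#' carry the generator seed in a `#` header comment.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed_line <- paste0("# seed: ", sim$truth$seed)
  paths <- c(groups = file.path(dir, "groups.txt"),
             metadata = file.path(dir, "metadata.tsv"),
             protein_index = file.path(dir, "protein_index.tsv"),
             tree = file.path(dir, "tree.nwk"))

  members <- sim$catalog$members
  lines <- vapply(split(members, members$group_id), function(df)
    paste0(df$group_id[1], ": ",
           paste(df$virus_id, df$protein_id, sep = "|", collapse = " ")),
    character(1))
  writeLines(c(seed_line, lines[order(names(lines))]), paths["groups"])

  con <- file(paths["metadata"], "w")
  writeLines(seed_line, con)
  utils::write.table(sim$meta, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  con <- file(paths["protein_index"], "w")
  writeLines(seed_line, con)
  utils::write.table(sim$protein_index, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  ape::write.tree(sim$tree, paths["tree"])
  invisible(paths)
}
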