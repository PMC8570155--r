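#' Assemble and validate a pipeline configuration
#'
#' @param groups Path to the orthogroup groups file.
#' @param metadata Path to the genome metadata TSV.
#' @param protein_index Optional path to the protein index TSV (enables
#'   singleton metrics).
#' @param tree Optional path to the core-gene newick tree.
#' @param annotations Optional path to the orthogroup annotation TSV.
#' @param out_dir Output directory; created if absent.
#' @param family_columns Metadata columns holding family labelings for the
#'   pangenome networks; alternative classifications (e.g. a nine-family
#'   system with nested families pulled out) are just alternate columns.
#' @param host_comparisons List of `list(families = c(A, B), host_type = h)`
#'   entries for similar/dissimilar host testing.
#' @param host_screens List of `list(families = c(A, B), target = t,
#'   reference = r)` entries for the host-shared orthogroup screen.
#' @param inflation,prune_threshold,max_iter MCL settings.
#' @param min_weight Edge-weight floor for network construction (default 0).
#' @param seed Seed recorded in the manifest and set before any stochastic
#'   step (the pipeline itself is deterministic given inputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(groups, metadata, protein_index = NULL,
                            tree = NULL, annotations = NULL,
                            out_dir = "ncldvnet_out",
                            family_columns = "family",
                            host_comparisons = list(),
                            host_screens = list(),
                            inflation = 1.5, prune_threshold = 1e-5,
                            max_iter = 200, min_weight = 0, seed = 1) {
  cfg <- list(groups = groups, metadata = metadata,
              protein_index = protein_index, tree = tree,
              annotations = annotations, out_dir = out_dir,
              family_columns = family_columns,
              host_comparisons = host_comparisons,
              host_screens = host_screens,
              inflation = inflation, prune_threshold = prune_threshold,
              max_iter = max_iter, min_weight = min_weight,
              seed = as.integer(seed))
  for (p in c("groups", "metadata"))
    if (!file.exists(cfg[[p]])) stop(p, " file not found: ", cfg[[p]])
  for (p in c("protein_index", "tree", "annotations"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop(p, " file not found: ", cfg[[p]])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full gene-content analysis pipeline
#'
#' Executes, in order: input reading and validation; genome-level count
#' matrix, sharing matrix and edge table; MCL clustering of the genome
#' network; family-pangenome edge tables for every configured family
#' labeling; the intrafamilial variation / host diversity report; the
#' configured similar-vs-dissimilar host comparisons; and the configured
#' host-shared orthogroup screens. Every output lands in `out_dir` and is
#' listed in `manifest.json` with its md5 checksum and the full parameter
#' set, so identical inputs and configuration reproduce identical manifests.
#' A failing stage aborts with the stage name; outputs already written are
#' retained next to a `FAILED` marker naming the stage.
#'
#' @param config A `pipeline_config`.
#' @return The manifest, invisibly (list with `outputs`, `parameters`,
#'   `checksums`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  outputs <- character()
  stage <- "setup"
  set.seed(config$seed)

  result <- tryCatch({
    stage <- "read inputs"
    meta <- read_genome_metadata(config$metadata)
    idx <- if (!is.null(config$protein_index))
      read_protein_index(config$protein_index) else NULL
    catalog <- read_orthogroups(config$groups, protein_index = idx)
    tree <- if (!is.null(config$tree))
      read_core_tree(config$tree, meta) else NULL
    ann <- if (!is.null(config$annotations))
      read_annotations(config$annotations) else NULL

    stage <- "genome sharing"
    counts <- build_count_matrix(catalog, meta)
    sharing <- compute_sharing(counts)
    net <- build_network(sharing, meta, min_weight = config$min_weight)
    outputs["genome_sharing"] <- write_sharing_matrix(
      sharing, out("genome_sharing.tsv"))
    outputs["genome_edges"] <- write_edge_table(net, out("genome_edges.tsv"))

    stage <- "MCL clustering"
    clustering <- mcl_cluster(net, inflation = config$inflation,
                              prune_threshold = config$prune_threshold,
                              max_iter = config$max_iter)
    outputs["mcl_clusters"] <- write_cluster_table(
      clustering, out("mcl_clusters.tsv"))

    stage <- "family networks"
    for (col in config$family_columns) {
      if (!col %in% names(meta)) {
        warning("family column absent from metadata, skipped: ", col)
        next
      }
      grouping <- stats::setNames(meta[[col]], meta$virus_id)
      pancounts <- collapse_to_pangenomes(counts, grouping)
      pansharing <- compute_sharing(pancounts)
      pannet <- build_network(pansharing, min_weight = config$min_weight)
      key <- paste0("family_edges_", col)
      outputs[key] <- write_edge_table(
        pannet, out(paste0("family_edges_", col, ".tsv")))
    }

    stage <- "variation report"
    report <- family_variation_report(meta, catalog = catalog, tree = tree)
    utils::write.table(report, out("variation_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs["variation_report"] <- out("variation_report.tsv")

    stage <- "host comparisons"
    for (hc in config$host_comparisons) {
      cmp <- host_compare(sharing, meta, hc$families[1], hc$families[2],
                          hc$host_type)
      key <- paste("host_compare", hc$families[1], hc$families[2],
                   hc$host_type, sep = "_")
      path <- out(paste0(key, ".tsv"))
      df <- rbind(cbind(cmp$similar, arm = "similar"),
                  cbind(cmp$dissimilar, arm = "dissimilar"))
      con <- file(path, "w")
      writeLines(sprintf(
        "# families: %s %s; host_type: %s; U = %s; p = %s; method = %s",
        hc$families[1], hc$families[2], hc$host_type,
        format(cmp$U_statistic), format(cmp$p_value), cmp$method), con)
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
      outputs[key] <- path
    }

    stage <- "host-shared orthogroup screens"
    for (hs in config$host_screens) {
      rep <- host_shared_orthogroups(counts, meta, hs$families[1],
                                     hs$families[2], hs$target,
                                     hs$reference, annotations = ann)
      key <- paste("host_genes", hs$target, "vs", hs$reference, sep = "_")
      path <- out(paste0(key, ".tsv"))
      utils::write.table(as.data.frame(rep), path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs[key] <- path
      pm <- report_presence_matrix(rep, counts, tree)
      pm_path <- out(paste0(key, "_presence.tsv"))
      utils::write.table(cbind(orthogroup_id = rownames(pm),
                               as.data.frame(pm)),
                         pm_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs[paste0(key, "_presence")] <- pm_path
    }
    TRUE
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               out("FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  parameters <- config[c("family_columns", "inflation", "prune_threshold",
                         "max_iter", "min_weight", "seed")]
  parameters$host_comparisons <- config$host_comparisons
  parameters$host_screens <- config$host_screens
  manifest <- list(
    outputs = as.list(stats::setNames(basename(outputs), names(outputs))),
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(outputs)), names(outputs))),
    parameters = parameters)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest$path <- out("manifest.json")
  invisible(manifest)
}
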