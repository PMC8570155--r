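#' Canonical host-type alias table
#'
#' Host labels in virus metadata are free text ("algae", "fish", ...). This
#' table maps common spellings onto the four comparative host types used
#' throughout the package (`vertebrate`, `insect`, `amoeba`, `alga`) plus the
#' catch-all `other/unknown`. Users with additional labels can extend the
#' returned vector and pass it to [read_genome_metadata()].
#'
#' @return Named character vector: names are lower-case input tokens, values
#'   the canonical host-type levels.
#' @export
#' @examples
#' host_type_aliases()[["algae"]]
host_type_aliases <- function() {
  c(vertebrate = "vertebrate", vertebrates = "vertebrate",
    fish = "vertebrate", mammal = "vertebrate", mammals = "vertebrate",
    amphibian = "vertebrate", reptile = "vertebrate", bird = "vertebrate",
    tetrapod = "vertebrate",
    insect = "insect", insects = "insect",
    amoeba = "amoeba", amoebae = "amoeba", amoebal = "amoeba",
    alga = "alga", algae = "alga", algal = "alga",
    other = "other/unknown", unknown = "other/unknown",
    "other/unknown" = "other/unknown", none = "other/unknown",
    na = "other/unknown")
}

.host_types <- c("vertebrate", "insect", "amoeba", "alga", "other/unknown")

.supergroups <- c("Amoebozoa", "Archaeplastida", "Discoba", "Haptista",
                  "Opisthokonta", "SAR", "unknown")

#' Read and validate a genome metadata table
#'
#' The metadata table is the taxon registry for every downstream analysis: one
#' row per viral genome with its family, intrafamilial lineage, host type and
#' host eukaryotic supergroup, and optionally genome size (bp) and
#' protein-coding gene count.
#'
#' @param path Path to a tab-separated file with a header. Required columns:
#'   `virus_id`, `family`, `lineage`, `host_type`, `host_supergroup`.
#'   Optional: `genome_size`, `protein_count`. Additional family-labeling
#'   columns (e.g. an alternative nine-family assignment) are carried through
#'   untouched. Lines starting with `#` are ignored.
#' @param aliases Host-type alias map, see [host_type_aliases()].
#' @return A `data.frame` with validated columns; `host_type` and
#'   `host_supergroup` are restricted to their canonical levels, unknown
#'   tokens are mapped to `other/unknown` / `unknown` with a warning.
#' @export
read_genome_metadata <- function(path, aliases = host_type_aliases()) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("virus_id", "family", "lineage", "host_type", "host_supergroup")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata missing required column(s): ", paste(missing, collapse = ", "))
  validate_genome_metadata(meta, aliases = aliases)
}

#' Validate an in-memory genome metadata table
#'
#' Applies the same checks and normalizations as [read_genome_metadata()] to a
#' data frame built in code (e.g. by [simulate_dataset()]).
#'
#' @param meta Data frame with the required metadata columns.
#' @param aliases Host-type alias map.
#' @return The validated, normalized data frame.
#' @export
validate_genome_metadata <- function(meta, aliases = host_type_aliases()) {
  dup <- meta$virus_id[duplicated(meta$virus_id)]
  if (length(dup))
    stop("duplicate virus_id in metadata: ", paste(unique(dup), collapse = ", "))

  tok <- tolower(trimws(meta$host_type))
  mapped <- unname(aliases[tok])
  unknown <- is.na(mapped)
  if (any(unknown)) {
    warning("unrecognized host_type token(s) mapped to other/unknown: ",
            paste(unique(meta$host_type[unknown]), collapse = ", "))
    mapped[unknown] <- "other/unknown"
  }
  meta$host_type <- mapped

  sg <- trimws(meta$host_supergroup)
  canon <- .supergroups[match(toupper(sg), toupper(.supergroups))]
  bad <- is.na(canon)
  if (any(bad)) {
    warning("unrecognized host_supergroup token(s) mapped to unknown: ",
            paste(unique(sg[bad]), collapse = ", "))
    canon[bad] <- "unknown"
  }
  meta$host_supergroup <- canon

  # each lineage must belong to exactly one family
  fam_per_lin <- tapply(meta$family, meta$lineage,
                        function(x) length(unique(x)))
  if (any(fam_per_lin > 1))
    stop("lineage(s) mapped to more than one family: ",
         paste(names(fam_per_lin)[fam_per_lin > 1], collapse = ", "))

  if ("protein_count" %in% names(meta) &&
      any(!is.na(meta$protein_count) & meta$protein_count < 0))
    stop("protein_count must be >= 0")
  if ("genome_size" %in% names(meta) &&
      any(!is.na(meta$genome_size) & meta$genome_size <= 0))
    stop("genome_size must be > 0 when present")
  rownames(meta) <- NULL
  meta
}

#' Read an orthogroup membership ("groups") file
#'
#' Parses the OrthoMCL groups dialect: one orthogroup per line, either
#' `GROUP_ID: Virus|prot Virus|prot ...` or
#' `GROUP_ID(N genes,M taxa): Virus|prot ...`. The parenthesized counts are
#' ignored, not trusted. Member tokens are split on the *first* `|` into
#' (virus id, protein accession); virus ids containing `|` are therefore not
#' supported.
#'
#' @param path Path to the groups file. Lines starting with `#` are ignored.
#' @param protein_index Optional data frame (`virus_id`, `protein_id`) listing
#'   every protein of every genome. When given, proteins absent from all
#'   groups become the catalog's singletons; when absent, singleton-dependent
#'   metrics are flagged unavailable rather than reported as zero.
#' @return An `orthogroup_catalog`: list with `members` (data frame
#'   `group_id`, `virus_id`, `protein_id`), `singletons` (same shape, or
#'   `NULL`), and `has_singletons`.
#' @export
read_orthogroups <- function(path, protein_index = NULL) {
  if (!file.exists(path)) stop("groups file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineno <- seq_along(keep)[keep]

  parse_line <- function(line, no) {
    colon <- regexpr(":", line, fixed = TRUE)
    if (colon < 0)
      stop("line ", no, ": missing ':' separator")
    id <- trimws(substr(line, 1L, colon - 1L))
    id <- sub("\\([^()]*\\)$", "", id)   # strip optional "(N genes,M taxa)"
    members <- strsplit(trimws(substr(line, colon + 1L, nchar(line))),
                        "\\s+")[[1]]
    bar <- regexpr("|", members, fixed = TRUE)
    if (any(bar < 0))
      stop("line ", no, ": member without '|' separator: ",
           members[bar < 0][1])
    data.frame(group_id = id,
               virus_id = substr(members, 1L, bar - 1L),
               protein_id = substr(members, bar + 1L, nchar(members)),
               stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, Map(parse_line, lines, lineno))
  if (is.null(members))
    members <- data.frame(group_id = character(), virus_id = character(),
                          protein_id = character(), stringsAsFactors = FALSE)
  rownames(members) <- NULL
  new_orthogroup_catalog(members, protein_index)
}

#' Construct an orthogroup catalog from a membership table
#'
#' @param members Data frame with columns `group_id`, `virus_id`,
#'   `protein_id`; one row per protein-in-group.
#' @param protein_index Optional full protein listing (`virus_id`,
#'   `protein_id`) used to derive singletons.
#' @return An `orthogroup_catalog` object.
#' @export
new_orthogroup_catalog <- function(members, protein_index = NULL) {
  key <- paste(members$virus_id, members$protein_id, sep = "|")
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("protein(s) assigned to more than one orthogroup: ",
         paste(utils::head(unique(dup), 5), collapse = ", "))
  size <- table(members$group_id)
  small <- names(size)[size < 2]
  if (length(small))
    stop("orthogroup(s) with fewer than 2 members: ",
         paste(small, collapse = ", "))

  singletons <- NULL
  if (!is.null(protein_index)) {
    stopifnot(all(c("virus_id", "protein_id") %in% names(protein_index)))
    ikey <- paste(protein_index$virus_id, protein_index$protein_id, sep = "|")
    singletons <- protein_index[!(ikey %in% key),
                                c("virus_id", "protein_id"), drop = FALSE]
    rownames(singletons) <- NULL
  }
  structure(list(members = members, singletons = singletons,
                 has_singletons = !is.null(protein_index)),
            class = "orthogroup_catalog")
}

#' @export
print.orthogroup_catalog <- function(x, ...) {
  cat("Orthogroup catalog\n")
  cat("  orthogroups:", length(unique(x$members$group_id)), "\n")
  cat("  clustered proteins:", nrow(x$members), "\n")
  cat("  genomes:", length(unique(x$members$virus_id)), "\n")
  if (x$has_singletons)
    cat("  singletons:", nrow(x$singletons), "\n")
  else
    cat("  singletons: unavailable (no protein index)\n")
  invisible(x)
}

#' Read a protein index table
#'
#' @param path TSV with columns `virus_id`, `protein_id`; `#` lines ignored.
#' @return Data frame.
#' @export
read_protein_index <- function(path) {
  idx <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("virus_id", "protein_id") %in% names(idx)))
  idx
}

#' Read an orthogroup annotation table
#'
#' @param path TSV with columns `orthogroup_id`, `annotation`.
#' @return Data frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("orthogroup_id", "annotation") %in% names(ann)))
  ann
}

#' Read a core-gene tree in newick format
#'
#' @param path Newick file; tips must be virus ids and branch lengths must be
#'   present and non-negative (substitutions per site).
#' @param meta Optional metadata table; tips absent from it are collected into
#'   a warning and attached as attribute `"unmatched"`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_core_tree <- function(path, meta = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("malformed newick file: ", path)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths: ", path)
  if (any(tree$edge.length < 0))
    stop("tree has negative branch length(s)")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree")
  if (!is.null(meta)) {
    unmatched <- setdiff(tree$tip.label, meta$virus_id)
    if (length(unmatched)) {
      warning("tree tip(s) absent from metadata: ",
              paste(unmatched, collapse = ", "))
      attr(tree, "unmatched") <- unmatched
    }
  }
  tree
}

#' Write a network as a Cytoscape-importable edge table
#'
#' Three tab-separated columns (`source`, `target`, `weight`), one row per
#' undirected edge with `source < target` lexicographically.
#'
#' @param network A `gene_sharing_network` (see [build_network()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_table <- function(network, path) {
  ed <- network$edges
  swap <- ed$source > ed$target
  tmp <- ed$source[swap]; ed$source[swap] <- ed$target[swap]; ed$target[swap] <- tmp
  ed <- ed[order(ed$source, ed$target), , drop = FALSE]
  ed$weight <- format(ed$weight, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.table(ed[, c("source", "target", "weight")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge table written by [write_edge_table()]
#'
#' @param path Edge-table TSV.
#' @return Data frame (`source`, `target`, `weight`).
#' @export
read_edge_table <- function(path) {
  ed <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  stopifnot(all(c("source", "target", "weight") %in% names(ed)))
  ed
}

#' Write a cluster assignment table
#'
#' @param clustering An `mcl_clustering` or a named vector taxon -> label.
#' @param path Output TSV path (`taxon`, `cluster`).
#' @return The path, invisibly.
#' @export
write_cluster_table <- function(clustering, path) {
  member <- if (inherits(clustering, "mcl_clustering"))
    clustering$membership else clustering
  df <- data.frame(taxon = names(member), cluster = unname(member),
                   stringsAsFactors = FALSE)
  df <- df[order(df$taxon), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cluster assignment table
#'
#' @param path TSV written by [write_cluster_table()].
#' @return Named integer vector taxon -> cluster.
#' @export
read_cluster_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$cluster), df$taxon)
}

#' Write a sharing matrix as a square TSV
#'
#' @param sharing A `sharing_matrix` from [compute_sharing()].
#' @param path Output path.
#' @param what Which matrix to dump: the normalized sharing `"S"` or the raw
#'   shared-orthogroup counts `"U"`.
#' @return The path, invisibly.
#' @export
write_sharing_matrix <- function(sharing, path, what = c("S", "U")) {
  what <- match.arg(what)
  m <- sharing[[what]]
  utils::write.table(cbind(taxon = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
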