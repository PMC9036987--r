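#' Construct and validate a taxonomy tree
#'
#' A rooted, rank-annotated tree in tabular form (an NCBI-style
#' nodes/names subset). The single root is its own parent; every node
#' must reach the root by parent traversal.
#'
#' @param nodes `data.frame` with columns `tax_id`, `parent_id`, `rank`
#'   and `name`. Ranks are drawn from root, superkingdom, phylum, class,
#'   order, family, genus, species.
#' @return A `taxonomy_tree` object.
#' @export
taxonomy_tree <- function(nodes) {
  req <- c("tax_id", "parent_id", "rank", "name")
  if (!all(req %in% names(nodes))) {
    stop("taxonomy table needs columns: ", paste(req, collapse = ", "))
  }
  ranks <- c("root", "superkingdom", "phylum", "class", "order",
             "family", "genus", "species")
  if (!all(nodes$rank %in% ranks)) {
    stop("unknown rank(s): ",
         paste(setdiff(unique(nodes$rank), ranks), collapse = ", "))
  }
  if (anyDuplicated(nodes$tax_id)) stop("duplicate tax_id values")
  root <- nodes$tax_id[nodes$tax_id == nodes$parent_id]
  if (length(root) != 1L) stop("tree must have exactly one root node")
  parent <- setNames(nodes$parent_id, as.character(nodes$tax_id))
  for (id in nodes$tax_id) {
    seen <- character(0)
    cur <- id
    repeat {
      key <- as.character(cur)
      if (!key %in% names(parent)) stop("parent of node ", cur,
                                        " not in tree")
      if (key %in% seen) stop("cycle detected at node ", cur)
      seen <- c(seen, key)
      if (cur == root) break
      cur <- parent[[key]]
    }
  }
  structure(list(nodes = nodes, root = root, parent = parent,
                 rank = setNames(nodes$rank, as.character(nodes$tax_id)),
                 name = setNames(nodes$name, as.character(nodes$tax_id))),
            class = "taxonomy_tree")
}

#' Read a taxonomy table from TSV
#'
#' @param path TSV with header columns `tax_id`, `parent_id`, `rank`,
#'   `name`. Lines starting with `#` are ignored.
#' @return A `taxonomy_tree`.
#' @export
read_taxonomy_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  taxonomy_tree(read.delim(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE))
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("Taxonomy tree:", nrow(x$nodes), "nodes,",
      sum(x$nodes$rank == "genus"), "genera\n")
  invisible(x)
}

# Root-to-node path of tax ids, root first.
.root_path <- function(id, tree) {
  path <- id
  cur <- id
  while (cur != tree$root) {
    cur <- tree$parent[[as.character(cur)]]
    path <- c(cur, path)
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is ancestral to (or equal to) every input node.
#'
#' @param taxa Non-empty vector of tax ids present in the tree.
#' @param tree A `taxonomy_tree`.
#' @return A single tax id.
#' @export
lca <- function(taxa, tree) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxa <- unique(taxa)
  if (length(taxa) == 0L) stop("need at least one taxon")
  unknown <- setdiff(as.character(taxa), names(tree$parent))
  if (length(unknown)) stop("unknown tax id(s): ",
                            paste(unknown, collapse = ", "))
  paths <- lapply(taxa, .root_path, tree = tree)
  shortest <- min(lengths(paths))
  anc <- tree$root
  for (d in seq_len(shortest)) {
    level <- vapply(paths, `[`, paths[[1]][1], d)
    if (length(unique(level)) == 1L) anc <- level[[1]] else break
  }
  anc
}

#' Provisional taxon for one read from its top alignment hits
#'
#' MEGAN-style placement: hits below the minimum bit score are dropped;
#' of the rest, only hits scoring within `top_percent` percent of the
#' best retained bit score are kept; surviving hits are mapped to the
#' genus of their reference (hits on references without a source genus
#' are dropped) and the read is placed on the lowest common ancestor of
#' those genera. With no surviving hit the read is UNCLASSIFIED.
#'
#' @param hits `data.frame` of one read's top hits (columns `ref_id`,
#'   `bit_score`), best first.
#' @param ref_genus_map Named vector: reference id -> genus tax id
#'   (`NA` for untagged references).
#' @param tree A `taxonomy_tree`.
#' @param min_score Minimum bit score (>=).
#' @param top_percent Retention band below the best score, in percent.
#' @return A tax id, or `NA` for UNCLASSIFIED.
#' @export
assign_read <- function(hits, ref_genus_map, tree, min_score = 50,
                        top_percent = 10.0) {
  hits <- hits[hits$bit_score >= min_score, , drop = FALSE]
  if (nrow(hits) == 0L) return(NA)
  best <- max(hits$bit_score)
  hits <- hits[hits$bit_score >= (1 - top_percent / 100) * best, ,
               drop = FALSE]
  genera <- ref_genus_map[hits$ref_id]
  genera <- genera[!is.na(genera)]
  if (length(genera) == 0L) return(NA)
  lca(unname(genera), tree)
}

#' Min-support filtering of provisional read placements
#'
#' The support of a node is the fraction of the sample's placed reads
#' resting at or below it. Reads on nodes whose support is strictly
#' below `min_support` are promoted, in a single leaf-to-root pass, to
#' the nearest ancestor whose support meets the threshold (the root is
#' the fallback). Reads that finish on a non-genus node are reported
#' UNCLASSIFIED at the genus rank.
#'
#' @param provisional `data.frame` with columns `read_id` and `taxon`
#'   (tax id or `NA`), one sample's annotated reads.
#' @param tree A `taxonomy_tree`.
#' @param min_support Support threshold as a fraction of the sample's
#'   placed reads (default 0.01); the boundary is strict (<).
#' @return `data.frame` with columns `read_id`, `taxon` (final node),
#'   `genus` (genus tax id or `NA`) and `rank_reported` (`"genus"` or
#'   `"UNCLASSIFIED"`).
#' @export
apply_min_support <- function(provisional, tree, min_support = 0.01) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  placed <- !is.na(provisional$taxon)
  n_placed <- sum(placed)
  taxon <- provisional$taxon
  if (n_placed > 0L) {
    # support of every node: placed reads at or below it
    support <- new.env()
    for (t in taxon[placed]) {
      for (a in .root_path(t, tree)) {
        key <- as.character(a)
        support[[key]] <- (if (is.null(support[[key]])) 0 else
          support[[key]]) + 1
      }
    }
    sup <- function(id) {
      v <- support[[as.character(id)]]
      if (is.null(v)) 0 else v / n_placed
    }
    promote <- function(t) {
      path <- rev(.root_path(t, tree))   # leaf to root
      for (node in path) if (sup(node) >= min_support) return(node)
      tree$root
    }
    taxon[placed] <- vapply(taxon[placed], promote, taxon[placed][1])
  }
  is_genus <- !is.na(taxon) &
    tree$rank[as.character(taxon)] == "genus"
  data.frame(read_id = provisional$read_id,
             taxon = taxon,
             genus = ifelse(is_genus, taxon, NA),
             rank_reported = ifelse(is_genus, "genus", "UNCLASSIFIED"),
             stringsAsFactors = FALSE)
}

#' Genus-level assignment of a sample's annotated reads
#'
#' Runs [assign_read()] on every annotated read's top hits and then
#' [apply_min_support()] over the sample.
#'
#' @param screen_result A `screen_result` from [screen_sample()].
#' @param db The `reference_db`; its `source_genus` labels are mapped to
#'   genus nodes of `tree` by name.
#' @param tree A `taxonomy_tree`.
#' @param min_score,top_percent,min_support LCA parameters.
#' @return The per-read assignment table of [apply_min_support()], plus
#'   a `sample_id` column.
#' @export
assign_sample <- function(screen_result, db, tree, min_score = 50,
                          top_percent = 10.0, min_support = 0.01) {
  stopifnot(inherits(screen_result, "screen_result"))
  map <- genus_map(db, tree)
  ann <- screen_result$annotated
  th <- screen_result$top_hits
  prov <- data.frame(read_id = ann$read_id,
                     taxon = rep(NA, nrow(ann)),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ann))) {
    h <- th[th$read_id == ann$read_id[i], , drop = FALSE]
    prov$taxon[i] <- assign_read(h, map, tree, min_score, top_percent)
  }
  out <- apply_min_support(prov, tree, min_support)
  out$sample_id <- screen_result$sample_id
  out
}

#' Map reference records to genus tax ids by source-genus name
#'
#' @param db A `reference_db`.
#' @param tree A `taxonomy_tree`.
#' @return Named vector reference id -> genus tax id (`NA` when the
#'   record is untagged or its genus is absent from the tree).
#' @export
genus_map <- function(db, tree) {
  genus_nodes <- tree$nodes[tree$nodes$rank == "genus", ]
  by_name <- setNames(genus_nodes$tax_id, genus_nodes$name)
  setNames(unname(by_name[db$records$source_genus]), db$records$id)
}

#' Signaled-community profile across samples
#'
#' Per sample: the relative abundance of each genus among the sample's
#' annotated (signaled) reads — with an explicit `unclassified` column
#' so rows sum to one — and the ratio of signaled reads to total clean
#' reads. Genera are flagged signaled-bacterial when their reads carry
#' IAA-synthetase subtypes and signaled-algal when they carry the algal
#' cyclin.
#'
#' @param assignments List (or rbind) of per-sample assignment tables
#'   from [assign_sample()].
#' @param results The matching list of `screen_result` objects
#'   (supplies read totals and the subtype of each read).
#' @param tree A `taxonomy_tree`.
#' @return List with `profile` (an `abundance_table`, unit RELATIVE,
#'   samples x genera + `unclassified`), `signaled_ratio` (named vector:
#'   annotated / total reads per sample) and `flags` (`data.frame`:
#'   `genus`, `signaled_bacterial`, `signaled_algal`).
#' @export
community_profile <- function(assignments, results, tree) {
  if (is.data.frame(assignments)) {
    assignments <- split(assignments, assignments$sample_id)
  }
  if (inherits(results, "screen_result")) results <- list(results)
  names(results) <- vapply(results, `[[`, character(1), "sample_id")
  samples <- vapply(assignments, function(a) a$sample_id[1], character(1))
  asg <- do.call(rbind, assignments)
  genera_ids <- unique(asg$genus[!is.na(asg$genus)])
  genera <- tree$name[as.character(genera_ids)]
  feats <- c(unname(genera), "unclassified")
  mat <- matrix(0, nrow = length(samples), ncol = length(feats),
                dimnames = list(samples, feats))
  ratio <- setNames(numeric(length(samples)), samples)
  subtype_by_read <- list()
  for (s in seq_along(assignments)) {
    a <- assignments[[s]]
    sid <- a$sample_id[1]
    res <- results[[sid]]
    if (is.null(res)) stop("no screening result for sample ", sid)
    n_ann <- nrow(a)
    ratio[sid] <- n_ann / res$summary$total_reads
    if (n_ann == 0L) next
    for (i in seq_len(n_ann)) {
      feat <- if (is.na(a$genus[i])) "unclassified" else
        tree$name[[as.character(a$genus[i])]]
      mat[sid, feat] <- mat[sid, feat] + 1 / n_ann
    }
    st <- setNames(res$annotated$subtype, res$annotated$read_id)
    g <- tree$name[as.character(a$genus)]
    subtype_by_read[[sid]] <- data.frame(
      genus = unname(g), subtype = unname(st[a$read_id]),
      stringsAsFactors = FALSE)
  }
  sb <- do.call(rbind, subtype_by_read)
  sb <- sb[!is.na(sb$genus), , drop = FALSE]
  flags <- data.frame(genus = unname(genera), stringsAsFactors = FALSE)
  flags$signaled_bacterial <- vapply(flags$genus, function(g) {
    any(sb$genus == g & sb$subtype %in% .BACTERIAL_SUBTYPES)
  }, logical(1))
  flags$signaled_algal <- vapply(flags$genus, function(g) {
    any(sb$genus == g & sb$subtype == "ALGAL_CYCLIN")
  }, logical(1))
  list(profile = abundance_table(mat, "RELATIVE"),
       signaled_ratio = ratio, flags = flags)
}

#' Write per-read assignments as TSV
#'
#' @param assignments Assignment table(s) from [assign_sample()].
#' @param path Output TSV path.
#' @param tree Optional `taxonomy_tree` used to add a genus-name column.
#' @param header_comment Optional `#`-prefixed first line.
#' @return `path`, invisibly.
#' @export
write_assignments_tsv <- function(assignments, path, tree = NULL,
                                  header_comment = NULL) {
  if (is.list(assignments) && !is.data.frame(assignments)) {
    assignments <- do.call(rbind, assignments)
  }
  if (!is.null(tree)) {
    assignments$genus_name <- ifelse(
      is.na(assignments$genus), "UNCLASSIFIED",
      tree$name[as.character(assignments$genus)])
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(assignments, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
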