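#' Pipeline configuration
#'
#' Collects all input paths and stage thresholds. Defaults are the
#' screening, LCA and network parameters of the study design:
#' E-value <= 1e-5, identity > 50%, alignment length > 25 aa,
#' clustering identity 0.97, LCA min score 50 / top percent 10 /
#' min support 0.01, and network |rho| > 0.6 with p < 0.01.
#'
#' @param reference_fastas Named character vector: subtype -> protein
#'   FASTA path (names from [iaa_subtypes()]).
#' @param read_files Named character vector: sample id -> FASTQ/FASTA
#'   path.
#' @param taxonomy_tsv Taxonomy table path (see [read_taxonomy_tsv()]).
#' @param abundance_tsv Optional genus-abundance-series TSV feeding the
#'   network stage (samples as rows, genera as columns).
#' @param genus_flags Optional `data.frame` (`genus`, `kingdom`,
#'   `signaled`) for the network stage.
#' @param output_dir Output directory.
#' @param dedupe_threshold,evalue_max,identity_min,alnlen_min
#'   Reference-clustering and screening thresholds.
#' @param min_score,top_percent,min_support LCA parameters.
#' @param rho_threshold,p_threshold Network thresholds.
#' @param seed Integer seed recorded in the run log.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(reference_fastas = character(0),
                            read_files = character(0),
                            taxonomy_tsv = NULL,
                            abundance_tsv = NULL,
                            genus_flags = NULL,
                            output_dir = tempfile("phycosignal_run"),
                            dedupe_threshold = 0.97,
                            evalue_max = 1e-5,
                            identity_min = 0.50,
                            alnlen_min = 25L,
                            min_score = 50,
                            top_percent = 10.0,
                            min_support = 0.01,
                            rho_threshold = 0.6,
                            p_threshold = 0.01,
                            seed = 1L) {
  if (!(dedupe_threshold > 0 && dedupe_threshold <= 1)) {
    stop("dedupe_threshold must be in (0, 1]")
  }
  if (!(identity_min >= 0 && identity_min <= 1)) {
    stop("identity_min must be in [0, 1]")
  }
  if (evalue_max <= 0) stop("evalue_max must be positive")
  if (alnlen_min < 0) stop("alnlen_min must be non-negative")
  if (min_score < 0) stop("min_score must be non-negative")
  if (!(top_percent >= 0 && top_percent <= 100)) {
    stop("top_percent must be in [0, 100]")
  }
  if (!(min_support >= 0 && min_support <= 1)) {
    stop("min_support must be in [0, 1]")
  }
  if (!(rho_threshold >= 0 && rho_threshold <= 1)) {
    stop("rho_threshold must be in [0, 1]")
  }
  if (!(p_threshold > 0 && p_threshold <= 1)) {
    stop("p_threshold must be in (0, 1]")
  }
  cfg <- list(reference_fastas = reference_fastas,
              read_files = read_files, taxonomy_tsv = taxonomy_tsv,
              abundance_tsv = abundance_tsv, genus_flags = genus_flags,
              output_dir = output_dir,
              dedupe_threshold = dedupe_threshold,
              evalue_max = evalue_max, identity_min = identity_min,
              alnlen_min = alnlen_min, min_score = min_score,
              top_percent = top_percent, min_support = min_support,
              rho_threshold = rho_threshold, p_threshold = p_threshold,
              seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Hash of a pipeline configuration
#'
#' An md5 digest of the serialised configuration (paths and
#' thresholds), recorded in the header comment of every output file so
#' that artefacts can be traced to the run that produced them.
#'
#' @param config A `pipeline_config` (the internal `hash` field is
#'   ignored).
#' @return Character md5 hash.
#' @export
config_hash <- function(config) {
  config$hash <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(config)), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

.STAGES <- c("refdb", "screen", "abundance", "taxonomy", "network")

#' Run one pipeline stage
#'
#' Stages must run in dependency order (refdb before screen, screen
#' before abundance and taxonomy, taxonomy and an abundance series
#' before network); a missing upstream product raises an error naming
#' the stage to run first. Outputs are written under
#' `config$output_dir`, each file carrying the configuration hash in a
#' header comment, and the running `state` list is returned enriched
#' with the stage's in-memory products.
#'
#' @param stage One of `"refdb"`, `"screen"`, `"abundance"`,
#'   `"taxonomy"`, `"network"`.
#' @param config A [pipeline_config()].
#' @param state State list from previous stages (empty for refdb).
#' @param quiet Suppress log messages.
#' @return The updated state list.
#' @export
run_stage <- function(stage, config, state = list(), quiet = FALSE) {
  stage <- match.arg(stage, .STAGES)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hc <- paste0("config_hash=", config$hash)
  log <- function(...) if (!quiet) message("[", stage, "] ", ...)
  need <- function(field, upstream) {
    if (is.null(state[[field]])) {
      stop("stage '", stage, "' requires output of stage '", upstream,
           "'; run it first")
    }
  }
  if (stage == "refdb") {
    if (length(config$reference_fastas) == 0L) {
      stop("no reference FASTA files configured")
    }
    recs <- do.call(rbind, lapply(names(config$reference_fastas),
                                  function(st) {
      read_protein_fasta(config$reference_fastas[[st]], st)
    }))
    state$db <- dedupe(recs, config$dedupe_threshold)
    write_reference_fasta(state$db,
                          file.path(config$output_dir, "refdb.faa"),
                          file.path(config$output_dir,
                                    "refdb_clusters.tsv"),
                          header_comment = hc)
    log(nrow(recs), " input records -> ", nrow(state$db$records),
        " representatives")
  } else if (stage == "screen") {
    need("db", "refdb")
    if (length(config$read_files) == 0L) stop("no read files configured")
    thr <- screen_thresholds(config$evalue_max, config$identity_min,
                             config$alnlen_min)
    state$screen <- lapply(names(config$read_files), function(sid) {
      reads <- read_reads(config$read_files[[sid]], sample_id = sid)
      res <- screen_sample(reads, state$db, thr, sample_id = sid)
      log("sample ", sid, ": ", res$summary$annotated_reads, "/",
          res$summary$total_reads, " reads annotated")
      res
    })
    names(state$screen) <- names(config$read_files)
    write_hits_tsv(state$screen,
                   file.path(config$output_dir, "hits.tsv"),
                   header_comment = hc)
  } else if (stage == "abundance") {
    need("screen", "screen")
    state$rpkm <- subtype_abundance(state$screen, state$db)
    write_abundance_tsv(state$rpkm,
                        file.path(config$output_dir,
                                  "subtype_rpkm.tsv"),
                        header_comment = hc)
    log("RPKM table: ", nrow(state$rpkm), " samples x ",
        ncol(state$rpkm), " subtypes")
  } else if (stage == "taxonomy") {
    need("screen", "screen")
    if (is.null(config$taxonomy_tsv)) stop("no taxonomy_tsv configured")
    state$tree <- read_taxonomy_tsv(config$taxonomy_tsv)
    state$assignments <- lapply(state$screen, assign_sample,
                                db = state$db, tree = state$tree,
                                min_score = config$min_score,
                                top_percent = config$top_percent,
                                min_support = config$min_support)
    state$profile <- community_profile(state$assignments,
                                       state$screen, state$tree)
    write_assignments_tsv(state$assignments,
                          file.path(config$output_dir,
                                    "assignments.tsv"),
                          tree = state$tree, header_comment = hc)
    write_abundance_tsv(state$profile$profile,
                        file.path(config$output_dir,
                                  "genus_profile.tsv"),
                        header_comment = hc)
    log(sum(!is.na(do.call(rbind, state$assignments)$genus)),
        " reads placed at genus level")
  } else if (stage == "network") {
    if (is.null(config$abundance_tsv)) {
      stop("no abundance_tsv configured for the network stage")
    }
    flags <- config$genus_flags
    if (is.null(flags)) {
      stop("genus_flags with kingdom annotations are required")
    }
    tab <- read.delim(config$abundance_tsv, sep = "\t",
                      comment.char = "#", check.names = FALSE)
    series <- as.matrix(tab[, -1, drop = FALSE])
    rownames(series) <- tab[[1]]
    state$network <- build_network(series, flags,
                                   config$rho_threshold,
                                   config$p_threshold)
    write_network(state$network, config$output_dir,
                  header_comment = hc)
    if (any(state$network$edges$sign == "POSITIVE")) {
      state$fraction <- signaled_positive_fraction(state$network)
      jsonlite::write_json(state$fraction,
                           file.path(config$output_dir,
                                     "signaled_fraction.json"),
                           auto_unbox = TRUE, digits = NA)
      log(sprintf("signaled positive-edge fraction %.2f%%",
                  state$fraction$fraction))
    }
  }
  state
}

#' Run the full pipeline
#'
#' Executes refdb, screen, abundance, taxonomy and network in order.
#' Stages whose inputs are not configured (e.g. no abundance series
#' for the network) can be skipped via `stages`.
#'
#' @param config A [pipeline_config()].
#' @param stages Stages to run, in pipeline order.
#' @param quiet Suppress log messages.
#' @return The final state list (db, screen, rpkm, tree, assignments,
#'   profile, network, fraction).
#' @export
run_pipeline <- function(config, stages = .STAGES, quiet = FALSE) {
  state <- list()
  for (s in .STAGES[.STAGES %in% stages]) {
    state <- run_stage(s, config, state, quiet = quiet)
  }
  state
}
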