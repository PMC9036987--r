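#' Read curated protein sequences for one gene subtype
#'
#' Parses a protein FASTA file into a record table for reference-database
#' construction. FASTA headers may carry a `genus=<name>` token which is
#' stored as the record's source genus and later used for taxonomic
#' binning of reads hitting that reference.
#'
#' Sequences are upper-cased and a single trailing stop symbol (`*`) is
#' stripped; internal stop symbols or gap characters are rejected because
#' reference entries must be complete, ungapped protein sequences.
#'
#' @param path Path to a protein FASTA file.
#' @param subtype One of [iaa_subtypes()].
#' @return A `data.frame` with columns `id`, `subtype`, `sequence`,
#'   `source_genus` (`NA` when untagged) and `length_aa`.
#' @export
read_protein_fasta <- function(path, subtype) {
  subtype <- match.arg(subtype, .SUBTYPES)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA (line ", nonblank[1],
         "): expected '>' header, got: ", lines[nonblank[1]])
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genus <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("genus=[^[:space:]]+", h))
    if (length(m)) sub("^genus=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  bad <- grepl("[*]", seqs) | grepl("[-.]", seqs)
  if (any(bad)) {
    stop("internal stop or gap symbol in record(s): ",
         paste(ids[bad], collapse = ", "))
  }
  if (any(!nzchar(seqs))) {
    stop("zero-length sequence in record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  protein_records(ids, subtype, seqs, genus)
}

#' Construct a protein record table
#'
#' @param id Character vector of unique record ids.
#' @param subtype Subtype label(s), recycled; see [iaa_subtypes()].
#' @param sequence Amino-acid sequences (20-letter alphabet plus `X`).
#' @param source_genus Optional genus of origin per record.
#' @return A `data.frame` of protein records.
#' @export
protein_records <- function(id, subtype, sequence,
                            source_genus = NA_character_) {
  stopifnot(all(subtype %in% .SUBTYPES))
  sequence <- toupper(sequence)
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", sequence)
  if (!all(ok)) {
    stop("invalid amino-acid alphabet in record(s): ",
         paste(id[!ok], collapse = ", "))
  }
  data.frame(id = as.character(id),
             subtype = rep_len(subtype, length(id)),
             sequence = sequence,
             source_genus = rep_len(as.character(source_genus), length(id)),
             length_aa = nchar(sequence),
             stringsAsFactors = FALSE)
}

#' Pairwise sequence identity (clustering convention)
#'
#' Identity between two protein sequences as used for non-redundancy
#' clustering: identical aligned positions on the optimal global-overlap
#' alignment (match 1, mismatch 0, free gaps), divided by the length of
#' the shorter sequence. This is the cd-hit-style identity used by
#' [dedupe()]; it differs from the alignment-column identity reported by
#' the screening stage.
#'
#' @param a,b Amino-acid sequences (character scalars) or single-row
#'   records as returned by [protein_records()].
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  a <- .as_sequence(a); b <- .as_sequence(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "overlap", substitutionMatrix = .identity_matrix(),
    gapOpening = 0, gapExtension = 0, scoreOnly = TRUE)
  aln / min(nchar(a), nchar(b))
}

.as_sequence <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x$sequence
  } else {
    toupper(as.character(x))
  }
}

.identity_matrix <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      letters <- c("A","C","D","E","F","G","H","I","K","L","M","N",
                   "P","Q","R","S","T","V","W","Y","X")
      m <- diag(1L, length(letters))
      dimnames(m) <- list(letters, letters)
      env$m <- m
    }
    env$m
  }
})

#' Greedy non-redundancy clustering of reference proteins
#'
#' Removes redundant reference sequences within each subtype by greedy
#' incremental clustering: records are sorted by length (descending, ties
#' broken lexicographically by id) and each record joins the first
#' existing cluster whose representative it matches at or above the
#' identity threshold (see [pairwise_identity()]), otherwise it founds a
#' new cluster. Only cluster representatives are retained. Subtypes are
#' never merged: a record can only be absorbed by a representative of its
#' own subtype.
#'
#' @param records Protein record table ([protein_records()]).
#' @param threshold Identity threshold in `(0, 1]`; default 0.97.
#' @return A `reference_db` object: list with elements `records`
#'   (representatives), `clusters` (`representative_id`, `member_id`) and
#'   `identity_threshold`.
#' @export
dedupe <- function(records, threshold = 0.97) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("no input records to cluster")
  }
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]")
  }
  if (anyDuplicated(records$id)) stop("record ids must be unique")
  keep <- integer(0)
  clusters <- list()
  for (st in unique(records$subtype)) {
    idx <- which(records$subtype == st)
    ord <- idx[order(-records$length_aa[idx], records$id[idx])]
    reps <- integer(0)
    for (i in ord) {
      placed <- FALSE
      for (r in reps) {
        if (pairwise_identity(records$sequence[i],
                              records$sequence[r]) >= threshold) {
          clusters[[length(clusters) + 1L]] <-
            c(records$id[r], records$id[i])
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        reps <- c(reps, i)
        clusters[[length(clusters) + 1L]] <-
          c(records$id[i], records$id[i])
      }
    }
    keep <- c(keep, reps)
  }
  keep <- sort(keep)
  cl <- do.call(rbind, clusters)
  structure(list(
    records = records[keep, , drop = FALSE],
    clusters = data.frame(representative_id = cl[, 1],
                          member_id = cl[, 2],
                          stringsAsFactors = FALSE),
    identity_threshold = threshold
  ), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("Reference database:", nrow(x$records), "representative sequences",
      sprintf("(identity threshold %.2f)\n", x$identity_threshold))
  tab <- table(x$records$subtype)
  for (st in names(tab)) cat("  ", st, ": ", tab[[st]], "\n", sep = "")
  invisible(x)
}

#' Total residue count of a reference database
#'
#' Used as the search-space size `n` in Karlin-Altschul E-values.
#'
#' @param db A `reference_db`.
#' @return Total number of amino-acid residues across representatives.
#' @export
db_residues <- function(db) {
  stopifnot(inherits(db, "reference_db"))
  sum(db$records$length_aa)
}

#' Write a reference database to FASTA and cluster-membership TSV
#'
#' @param db A `reference_db`.
#' @param fasta_path Output FASTA path; headers carry
#'   `subtype=<SUBTYPE>` and, when known, `genus=<name>` tokens.
#' @param clusters_path Optional output TSV path for cluster membership
#'   (`representative_id`, `member_id`).
#' @param header_comment Optional comment line written at the top of the
#'   clusters TSV (prefixed with `#`).
#' @return `fasta_path`, invisibly.
#' @export
write_reference_fasta <- function(db, fasta_path, clusters_path = NULL,
                                  header_comment = NULL) {
  stopifnot(inherits(db, "reference_db"))
  r <- db$records
  hdr <- paste0(r$id, " subtype=", r$subtype,
                ifelse(is.na(r$source_genus), "",
                       paste0(" genus=", r$source_genus)))
  aa <- Biostrings::AAStringSet(r$sequence)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, fasta_path)
  if (!is.null(clusters_path)) {
    con <- file(clusters_path, "w")
    on.exit(close(con))
    if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
    write.table(db$clusters, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(fasta_path)
}
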