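#' Six-frame translation of a nucleotide read
#'
#' Translates a read in all six frames with the standard genetic code,
#' splits each frame at stop codons and discards fragments shorter than
#' the minimum peptide length. Codons containing `N` translate to `X`.
#'
#' @param sequence Nucleotide sequence (ACGTN, case-insensitive).
#' @param min_fragment_aa Minimum retained fragment length (default 8).
#' @return A `data.frame` with columns `frame` (one of +1..+3, -1..-3)
#'   and `peptide`; zero rows when no fragment survives.
#' @export
six_frame_translate <- function(sequence, min_fragment_aa = 8L) {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGTN]+$", sequence)) {
    stop("read sequence must use the ACGTN alphabet")
  }
  fwd <- Biostrings::DNAString(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  out_frame <- integer(0)
  out_pep <- character(0)
  for (f in 1:3) {
    for (strand in c(1L, -1L)) {
      s <- if (strand == 1L) fwd else rev
      n <- length(s) - f + 1L
      n <- n - n %% 3L
      if (n < 3L) next
      pep <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::subseq(s, start = f, width = n),
        if.fuzzy.codon = "X")))
      frags <- strsplit(pep, "*", fixed = TRUE)[[1]]
      frags <- frags[nchar(frags) >= min_fragment_aa]
      if (length(frags)) {
        out_frame <- c(out_frame, rep(strand * f, length(frags)))
        out_pep <- c(out_pep, frags)
      }
    }
  }
  data.frame(frame = out_frame, peptide = out_pep,
             stringsAsFactors = FALSE)
}

#' Smith-Waterman local alignment of two peptides
#'
#' Optimal local alignment under BLOSUM62 with affine gap penalties
#' (open 11, extend 1; a gap of length k costs 11 + k). Identity is the
#' fraction of identical positions over all alignment columns, gap
#' columns included (the BLAST reporting convention, distinct from the
#' clustering identity of [pairwise_identity()]).
#'
#' @param query,target Peptide sequences (character scalars).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return A list with `raw_score`, `identity` and `alignment_length_aa`.
#' @export
smith_waterman <- function(query, target, gap_opening = 11,
                           gap_extension = 1) {
  query <- toupper(as.character(query))
  target <- toupper(as.character(target))
  if (!nzchar(query) || !nzchar(target)) {
    stop("peptides must be non-empty")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = .blosum62(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  s <- Biostrings::score(aln)
  if (s <= 0) {
    return(list(raw_score = 0, identity = 0, alignment_length_aa = 0L))
  }
  list(raw_score = s,
       identity = Biostrings::nmatch(aln) / nchar(aln),
       alignment_length_aa = nchar(aln))
}

#' Karlin-Altschul E-value and bit score
#'
#' `E = K * m * n * exp(-lambda * S)` for raw score `S`, query length `m`
#' and database length `n` (residues). The defaults are the standard
#' gapped BLOSUM62 (open 11 / extend 1) parameters. No effective
#' search-space correction is applied, so values may differ slightly
#' from BLASTX output.
#'
#' @param raw_score Raw alignment score `S`.
#' @param query_len_aa Query (translated fragment) length in residues.
#' @param db_len_aa Total database residues (see [db_residues()]).
#' @param K,lambda Karlin-Altschul parameters; must be positive.
#' @return The expected number of chance hits (E-value).
#' @export
evalue <- function(raw_score, query_len_aa, db_len_aa,
                   K = 0.041, lambda = 0.267) {
  if (any(K <= 0) || any(lambda <= 0)) {
    stop("K and lambda must be positive")
  }
  if (any(query_len_aa <= 0) || any(db_len_aa <= 0)) {
    stop("query and database lengths must be positive")
  }
  K * query_len_aa * db_len_aa * exp(-lambda * raw_score)
}

#' @rdname evalue
#' @export
bit_score <- function(raw_score, K = 0.041, lambda = 0.267) {
  if (any(K <= 0) || any(lambda <= 0)) {
    stop("K and lambda must be positive")
  }
  (lambda * raw_score - log(K)) / log(2)
}

#' Screening thresholds
#'
#' The annotation rule: a read is annotated with the subtype of its best
#' hit only when that hit has E-value at or below `evalue_max`, identity
#' strictly above `identity_min` and alignment length strictly above
#' `alnlen_min` amino acids.
#'
#' @param evalue_max Maximum E-value for a hit to be considered (<=).
#' @param identity_min Identity a best hit must exceed (strict >).
#' @param alnlen_min Alignment length (aa) a best hit must exceed
#'   (strict >).
#' @param K,lambda Karlin-Altschul parameters used for E-values.
#' @return A `screen_thresholds` list.
#' @export
screen_thresholds <- function(evalue_max = 1e-5, identity_min = 0.50,
                              alnlen_min = 25L, K = 0.041,
                              lambda = 0.267) {
  stopifnot(evalue_max > 0, identity_min >= 0, identity_min <= 1,
            alnlen_min >= 0, K > 0, lambda > 0)
  structure(list(evalue_max = evalue_max, identity_min = identity_min,
                 alnlen_min = alnlen_min, K = K, lambda = lambda),
            class = "screen_thresholds")
}

# Order hits best-first: bit score descending, then E-value ascending,
# then lexicographic reference id.
.order_hits <- function(hits) {
  order(-hits$bit_score, hits$evalue, hits$ref_id)
}

#' Apply the best-hit annotation rule to a table of alignment hits
#'
#' Given all E-value-passing hits of one read, picks the best hit
#' (maximum bit score; ties broken by lower E-value, then reference id)
#' and decides whether the read is annotated: the best hit must have
#' identity strictly greater than `identity_min` and alignment length
#' strictly greater than `alnlen_min`. Both are strict inequalities, so
#' a hit at exactly 50% identity or exactly 25 aligned residues is
#' rejected.
#'
#' @param hits `data.frame` of hits of a single read with columns
#'   `ref_id`, `subtype`, `bit_score`, `evalue`, `identity`,
#'   `alignment_length_aa` (additional columns pass through).
#' @param thresholds A [screen_thresholds()] object.
#' @return List with `annotated` (logical), `subtype` (or `NA`),
#'   `best_hit` (single-row data.frame or `NULL`) and `top_hits` (up to
#'   10 best passing hits, best first).
#' @export
annotate_hits <- function(hits, thresholds = screen_thresholds()) {
  hits <- hits[hits$evalue <= thresholds$evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(list(annotated = FALSE, subtype = NA_character_,
                best_hit = NULL, top_hits = hits))
  }
  hits <- hits[.order_hits(hits), , drop = FALSE]
  top <- hits[seq_len(min(10L, nrow(hits))), , drop = FALSE]
  best <- hits[1L, , drop = FALSE]
  ok <- best$identity > thresholds$identity_min &&
    best$alignment_length_aa > thresholds$alnlen_min
  list(annotated = ok,
       subtype = if (ok) best$subtype else NA_character_,
       best_hit = best, top_hits = top)
}

#' Screen one sample of metagenomic reads against the reference database
#'
#' Translates every read in six frames, aligns every retained peptide
#' fragment against every reference by Smith-Waterman, converts raw
#' scores to Karlin-Altschul E-values against the whole-database search
#' space, and applies the best-hit annotation rule ([annotate_hits()]).
#' A read carries at most one subtype: that of its best hit.
#'
#' @param reads `data.frame` with columns `id`, `sequence` and optional
#'   `sample_id` (a scalar `sample_id` argument overrides).
#' @param db A `reference_db` from [dedupe()].
#' @param thresholds A [screen_thresholds()] object.
#' @param sample_id Sample identifier recorded in the output.
#' @param min_fragment_aa Minimum translated fragment length.
#' @return A `screen_result` object: list with `annotated` (one row per
#'   annotated read: `read_id`, `sample_id`, `subtype`, `ref_id`,
#'   `frame`, `raw_score`, `bit_score`, `identity`,
#'   `alignment_length_aa`, `evalue`), `top_hits` (up to ten passing
#'   hits per annotated read, for taxonomic binning), `summary` (total
#'   reads, annotated reads, per-subtype counts) and `sample_id`.
#' @export
screen_sample <- function(reads, db, thresholds = screen_thresholds(),
                          sample_id = NULL, min_fragment_aa = 8L) {
  stopifnot(inherits(db, "reference_db"), nrow(db$records) > 0L)
  if (is.null(sample_id)) {
    sample_id <- if (!is.null(reads$sample_id)) reads$sample_id[1] else "S1"
  }
  n_total <- nrow(reads)
  frags <- .six_frame_batch(reads$sequence, reads$id, min_fragment_aa)
  hits <- .align_fragments(frags, db, thresholds)
  ann_rows <- list(); top_rows <- list()
  if (!is.null(hits) && nrow(hits)) {
    for (rid in unique(hits$read_id)) {
      h <- hits[hits$read_id == rid, , drop = FALSE]
      res <- annotate_hits(h, thresholds)
      if (res$annotated) {
        row <- res$best_hit
        row$sample_id <- sample_id
        ann_rows[[rid]] <- row
        th <- res$top_hits
        th$sample_id <- sample_id
        top_rows[[rid]] <- th
      }
    }
  }
  annotated <- .bind_or_empty(ann_rows, .hit_columns())
  top_hits <- .bind_or_empty(top_rows, .hit_columns())
  counts <- table(factor(annotated$subtype, levels = .SUBTYPES))
  structure(list(
    annotated = annotated,
    top_hits = top_hits,
    summary = list(sample_id = sample_id, total_reads = n_total,
                   annotated_reads = nrow(annotated),
                   subtype_counts = as.list(counts)),
    sample_id = sample_id
  ), class = "screen_result")
}

.hit_columns <- function() {
  data.frame(read_id = character(0), ref_id = character(0),
             subtype = character(0), frame = integer(0),
             raw_score = numeric(0), bit_score = numeric(0),
             identity = numeric(0), alignment_length_aa = integer(0),
             evalue = numeric(0), sample_id = character(0),
             stringsAsFactors = FALSE)
}

.bind_or_empty <- function(rows, template) {
  if (length(rows) == 0L) return(template)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, names(template), drop = FALSE]
}

# Vectorised six-frame translation of many reads at once; equivalent
# to rbind-ing six_frame_translate() over reads, but with whole-set
# Biostrings calls per frame instead of per read.
.six_frame_batch <- function(sequences, read_ids, min_fragment_aa = 8L) {
  dna <- Biostrings::DNAStringSet(toupper(sequences))
  sets <- list(`1` = dna, `-1` = Biostrings::reverseComplement(dna))
  out <- list()
  for (f in 1:3) {
    for (strand in c("1", "-1")) {
      s <- sets[[strand]]
      w <- Biostrings::width(s) - f + 1L
      w <- pmax(w - w %% 3L, 0L)
      keep <- which(w >= 3L)
      if (!length(keep)) next
      pep <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::subseq(s[keep], start = f, width = w[keep]),
        if.fuzzy.codon = "X")))
      pieces <- strsplit(pep, "*", fixed = TRUE)
      lens <- lengths(pieces)
      df <- data.frame(
        read_id = rep(read_ids[keep], lens),
        frame = as.integer(strand) * f,
        peptide = unlist(pieces, use.names = FALSE),
        stringsAsFactors = FALSE)
      df <- df[nchar(df$peptide) >= min_fragment_aa, , drop = FALSE]
      if (nrow(df)) out[[length(out) + 1L]] <- df
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# Batched fragment-vs-reference alignment: one pairwiseAlignment call
# per reference against the full fragment set, keeping only hits at or
# below the E-value cutoff.
.align_fragments <- function(frags, db, thresholds) {
  if (is.null(frags) || nrow(frags) == 0L) return(NULL)
  n_db <- db_residues(db)
  pat <- Biostrings::AAStringSet(frags$peptide)
  qlen <- nchar(frags$peptide)
  out <- list()
  for (j in seq_len(nrow(db$records))) {
    aln <- Biostrings::pairwiseAlignment(
      pat, Biostrings::AAString(db$records$sequence[j]),
      type = "local", substitutionMatrix = .blosum62(),
      gapOpening = 11, gapExtension = 1)
    s <- Biostrings::score(aln)
    e <- evalue(s, qlen, n_db, thresholds$K, thresholds$lambda)
    keep <- which(s > 0 & e <= thresholds$evalue_max)
    if (length(keep)) {
      a <- aln[keep]
      out[[length(out) + 1L]] <- data.frame(
        read_id = frags$read_id[keep],
        ref_id = db$records$id[j],
        subtype = db$records$subtype[j],
        frame = frags$frame[keep],
        raw_score = s[keep],
        bit_score = bit_score(s[keep], thresholds$K, thresholds$lambda),
        identity = Biostrings::nmatch(a) / Biostrings::nchar(a),
        alignment_length_aa = Biostrings::nchar(a),
        evalue = e[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Screen a single read
#'
#' Convenience wrapper around [screen_sample()] for one read.
#'
#' @param sequence Nucleotide sequence of the read.
#' @param db A `reference_db`.
#' @param thresholds A [screen_thresholds()] object.
#' @param read_id,sample_id Identifiers recorded in the output.
#' @return A single-row annotation `data.frame` (with the read's top
#'   hits as attribute `top_hits`), or `NULL` when the read is not
#'   annotated.
#' @export
screen_read <- function(sequence, db, thresholds = screen_thresholds(),
                        read_id = "read1", sample_id = "S1") {
  res <- screen_sample(
    data.frame(id = read_id, sequence = sequence,
               stringsAsFactors = FALSE),
    db, thresholds, sample_id = sample_id)
  if (nrow(res$annotated) == 0L) return(NULL)
  out <- res$annotated
  attr(out, "top_hits") <- res$top_hits
  out
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat("Screening of sample", s$sample_id, "\n")
  cat("  reads:", s$total_reads, " annotated:", s$annotated_reads, "\n")
  for (st in names(s$subtype_counts)) {
    cat("  ", st, ": ", s$subtype_counts[[st]], "\n", sep = "")
  }
  invisible(x)
}

#' Read nucleotide reads from FASTA or FASTQ
#'
#' Qualities in FASTQ input are ignored; only sequences are used.
#'
#' @param path Input file; format detected from the first character
#'   (`@` for FASTQ, `>` for FASTA).
#' @param sample_id Sample identifier attached to every read.
#' @return `data.frame` with columns `id`, `sequence`, `sample_id`.
#' @export
read_reads <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- substr(readLines(path, n = 1L), 1, 1)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  dna <- Biostrings::readDNAStringSet(path, format = fmt)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fastq|fq|fasta|fa)(\\.gz)?$", "",
                     basename(path))
  }
  data.frame(
    id = vapply(strsplit(names(dna), "\\s+"), `[`, character(1), 1L),
    sequence = as.character(dna),
    sample_id = sample_id,
    stringsAsFactors = FALSE)
}

#' Write screening hits in a blast-outfmt6-like TSV
#'
#' @param result A `screen_result` or a list of them.
#' @param path Output TSV path.
#' @param header_comment Optional `#`-prefixed first line.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(result, path, header_comment = NULL) {
  if (inherits(result, "screen_result")) result <- list(result)
  tab <- do.call(rbind, lapply(result, `[[`, "annotated"))
  out <- data.frame(qseqid = tab$read_id, sseqid = tab$ref_id,
                    pident = round(100 * tab$identity, 2),
                    length = tab$alignment_length_aa,
                    evalue = tab$evalue, bitscore = round(tab$bit_score, 2),
                    frame = tab$frame, subtype = tab$subtype,
                    sample = tab$sample_id, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
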