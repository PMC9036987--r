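#' Reads per kilobase per million mapped reads
#'
#' Length- and depth-normalised abundance of a reference gene:
#' `RPKM = count * 1e9 / (L_nt * total_reads)` where `L_nt` is the
#' coding-nucleotide length, i.e. three times the protein length, and
#' `total_reads` is the sample's total clean read count.
#'
#' @param count Number of reads assigned to the reference.
#' @param ref_length_aa Reference protein length in amino acids.
#' @param total_reads Total clean reads in the sample (>= 1).
#' @return RPKM value(s); vectorised over its arguments.
#' @export
rpkm <- function(count, ref_length_aa, total_reads) {
  if (any(total_reads < 1)) stop("total_reads must be >= 1")
  if (any(ref_length_aa < 1)) stop("ref_length_aa must be >= 1")
  if (any(count < 0)) stop("count must be non-negative")
  count * 1e9 / (3 * ref_length_aa * total_reads)
}

#' Construct an abundance table
#'
#' @param values Numeric matrix, samples as rows, features as columns.
#' @param unit `"RPKM"` or `"RELATIVE"`. Rows of a RELATIVE table must
#'   sum to 1 (tolerance 1e-9).
#' @return An `abundance_table` (a matrix with a `unit` attribute).
#' @export
abundance_table <- function(values, unit = c("RPKM", "RELATIVE")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (any(values < 0)) stop("abundance values must be non-negative")
  if (unit == "RELATIVE" && nrow(values) > 0) {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-9)) {
      stop("rows of a RELATIVE abundance table must sum to 1")
    }
  }
  structure(values, unit = unit, class = c("abundance_table", "matrix",
                                           "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table (", attr(x, "unit"), "): ",
      nrow(x), " samples x ", ncol(x), " features\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Subtype-level RPKM abundances from screening results
#'
#' For each sample and gene subtype, sums the per-reference RPKM of all
#' reads whose best hit fell on a reference of that subtype. References
#' without assigned reads contribute zero.
#'
#' @param results List of `screen_result` objects (one per sample), or a
#'   single `screen_result`.
#' @param db The `reference_db` screened against; supplies reference
#'   lengths.
#' @param totals Optional named vector of per-sample total clean reads;
#'   defaults to each result's screening summary total.
#' @return An `abundance_table` (unit RPKM), samples x subtypes.
#' @export
subtype_abundance <- function(results, db, totals = NULL) {
  stopifnot(inherits(db, "reference_db"))
  if (inherits(results, "screen_result")) results <- list(results)
  samples <- vapply(results, `[[`, character(1), "sample_id")
  if (anyDuplicated(samples)) stop("duplicate sample ids in results")
  reflen <- setNames(db$records$length_aa, db$records$id)
  mat <- matrix(0, nrow = length(samples), ncol = length(.SUBTYPES),
                dimnames = list(samples, .SUBTYPES))
  for (k in seq_along(results)) {
    res <- results[[k]]
    total <- if (!is.null(totals)) {
      if (is.na(totals[res$sample_id])) {
        stop("missing read total for sample ", res$sample_id)
      }
      totals[[res$sample_id]]
    } else {
      res$summary$total_reads
    }
    if (is.null(total) || total < 1) {
      stop("missing read total for sample ", res$sample_id)
    }
    ann <- res$annotated
    if (nrow(ann) == 0L) next
    unknown <- setdiff(ann$ref_id, names(reflen))
    if (length(unknown)) {
      stop("annotated reads reference unknown db entries: ",
           paste(unknown, collapse = ", "))
    }
    per_ref <- table(ann$ref_id, ann$subtype)
    for (rid in rownames(per_ref)) {
      for (st in colnames(per_ref)) {
        cnt <- per_ref[rid, st]
        if (cnt > 0) {
          mat[res$sample_id, st] <- mat[res$sample_id, st] +
            rpkm(cnt, reflen[[rid]], total)
        }
      }
    }
  }
  abundance_table(mat, "RPKM")
}

#' Write an abundance table as TSV
#'
#' Samples as rows, features as columns, both labelled.
#'
#' @param x An `abundance_table` or matrix.
#' @param path Output TSV path.
#' @param header_comment Optional `#`-prefixed first line.
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  out <- data.frame(sample = rownames(x), unclass(x),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
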