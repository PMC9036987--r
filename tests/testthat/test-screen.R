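test_that("six-frame translation covers codons, strands and stop splits", {
  fr <- six_frame_translate("ATGGCT", min_fragment_aa = 1)
  expect_equal(fr$peptide[fr$frame == 1], "MA")
  # reverse complement of ATGGCT is AGCCAT; its reverse frames
  # recover MA
  fr2 <- six_frame_translate("AGCCAT", min_fragment_aa = 1)
  expect_true("MA" %in% fr2$peptide[fr2$frame < 0])
  # stop-split: both 1-aa fragments fall below the length floor
  fr3 <- six_frame_translate("ATGTAAATG")
  expect_false(any(fr3$frame == 1))
  fr3b <- six_frame_translate("ATGTAAATG", min_fragment_aa = 1)
  expect_equal(fr3b$peptide[fr3b$frame == 1], c("M", "M"))
  # N-containing codons translate to X
  frN <- six_frame_translate("ATGNNT", min_fragment_aa = 1)
  expect_equal(frN$peptide[frN$frame == 1], "MX")
  expect_error(six_frame_translate("ATGU"), "ACGTN")
})

test_that("batched translation matches the per-read operation", {
  set.seed(5)
  seqs <- c(vapply(1:15, function(i) {
    paste(sample(c("A", "C", "G", "T", "N"), sample(30:90, 1),
                 replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
          collapse = "")
  }, character(1)))
  ids <- paste0("r", seq_along(seqs))
  batched <- phycosignal:::.six_frame_batch(seqs, ids)
  single <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    d <- six_frame_translate(seqs[i])
    if (nrow(d)) d$read_id <- ids[i]
    d
  }))
  expect_setequal(paste(batched$read_id, batched$frame, batched$peptide),
                  paste(single$read_id, single$frame, single$peptide))
})

test_that("local alignment scores match BLOSUM62 and the DP oracle", {
  self <- smith_waterman("MKVLA", "MKVLA")
  expect_equal(self$raw_score, 22)   # diagonal M5 K5 V4 L4 A4
  expect_equal(self$identity, 1.0)
  expect_equal(self$alignment_length_aa, 5L)
  set.seed(17)
  for (k in 1:25) {
    a <- random_peptide(20); b <- random_peptide(20)
    expect_equal(smith_waterman(a, b)$raw_score, sw_oracle(a, b))
    expect_equal(smith_waterman(a, a)$identity, 1.0)
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  expect_equal(evalue(0, 30, 1e5), 0.041 * 30 * 1e5)
  expect_equal(evalue(60, 30, 2e5), 2 * evalue(60, 30, 1e5))
  expect_equal(evalue(60, 30, 1e5, K = 0.041, lambda = 0.267),
               0.041 * 30 * 1e5 * exp(-0.267 * 60))
  # E strictly decreasing in the score / bit score
  s <- seq(10, 200, by = 10)
  expect_true(all(diff(evalue(s, 30, 1e5)) < 0))
  expect_true(all(diff(bit_score(s)) > 0))
  expect_equal(bit_score(60), (0.267 * 60 - log(0.041)) / log(2))
  expect_error(evalue(60, 30, 1e5, K = -1), "positive")
  expect_error(evalue(60, 30, 1e5, lambda = 0), "positive")
  expect_error(evalue(60, 0, 1e5), "positive")
})

.hit_row <- function(identity, alnlen, bit = 100, ev = 1e-10,
                     ref = "ref1", subtype = "IAM_HYDROLASE") {
  data.frame(read_id = "r1", ref_id = ref, subtype = subtype,
             frame = 1L, raw_score = 250, bit_score = bit,
             identity = identity, alignment_length_aa = alnlen,
             evalue = ev, stringsAsFactors = FALSE)
}

test_that("annotation thresholds are strict inequalities", {
  thr <- screen_thresholds()
  # boundary: exactly 50% identity is rejected
  expect_false(annotate_hits(.hit_row(0.50, 30), thr)$annotated)
  # boundary: exactly 25 aligned residues is rejected
  expect_false(annotate_hits(.hit_row(0.80, 25L), thr)$annotated)
  # just past both boundaries is accepted
  expect_true(annotate_hits(.hit_row(0.51, 26L), thr)$annotated)
  # sub-threshold identity below the boundary
  expect_false(annotate_hits(.hit_row(0.45, 30L), thr)$annotated)
  # E-value uses <=: a hit at exactly 1e-5 is retained
  expect_true(annotate_hits(.hit_row(0.80, 30L, ev = 1e-5),
                            thr)$annotated)
  expect_false(annotate_hits(.hit_row(0.80, 30L, ev = 1.01e-5),
                             thr)$annotated)
})

test_that("best-hit selection prefers bit score, then evalue, then id", {
  h <- rbind(.hit_row(0.9, 30, bit = 80, ref = "b"),
             .hit_row(0.9, 30, bit = 90, ref = "c",
                      subtype = "IAN_NITRILASE"),
             .hit_row(0.9, 30, bit = 90, ref = "a",
                      subtype = "IAN_NITRILASE"))
  res <- annotate_hits(h)
  expect_equal(res$best_hit$ref_id, "a")
  expect_equal(res$subtype, "IAN_NITRILASE")
  expect_equal(res$top_hits$ref_id[1], "a")
  expect_lte(nrow(res$top_hits), 10L)
})

test_that("a read with an exact reference segment is annotated with it", {
  fx <- small_fixture()
  db <- small_db()
  ref <- db$records[db$records$id == "IAM_Hydrogenophaga", ]
  gene <- fx$refs$genes[["IAM_Hydrogenophaga"]]
  read <- substr(gene, 91, 180)    # exact 90 nt = 30 aa segment
  out <- screen_read(read, db)
  expect_false(is.null(out))
  expect_equal(out$ref_id, "IAM_Hydrogenophaga")
  expect_equal(out$subtype, "IAM_HYDROLASE")
  expect_equal(out$identity, 1.0)
  # frame symmetry: the reverse-complemented read gives the same best
  # reference and raw score
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  out2 <- screen_read(rc, db)
  expect_equal(out2$ref_id, out$ref_id)
  expect_equal(out2$raw_score, out$raw_score)
  expect_equal(out2$frame, -out$frame)
})

test_that("screening a sample conserves totals and recovers planted reads", {
  fx <- small_fixture()
  res <- small_screen("S01")
  truth <- fx$reads$truth
  t1 <- truth[truth$sample_id == "S01", ]
  expect_equal(res$summary$total_reads, nrow(t1))
  planted <- t1[t1$subtype != "background", ]
  hit <- merge(res$annotated, planted, by = "read_id")
  # no background read annotated
  bg <- t1$read_id[t1$subtype == "background"]
  expect_length(intersect(res$annotated$read_id, bg), 0L)
  # recall and subtype accuracy on planted reads
  expect_gte(nrow(hit) / nrow(planted), 0.95)
  expect_gte(mean(hit$subtype.x == hit$subtype.y), 0.99)
  # every retained top hit satisfies the E-value cutoff
  expect_true(all(res$top_hits$evalue <= 1e-5))
})

test_that("a sample without gene reads yields no annotations", {
  set.seed(9)
  reads <- data.frame(
    id = paste0("bg", 1:30),
    sequence = vapply(1:30, function(i) {
      paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    }, character(1)),
    stringsAsFactors = FALSE)
  res <- screen_sample(reads, small_db(), sample_id = "bgonly")
  expect_equal(nrow(res$annotated), 0L)
  expect_equal(res$summary$total_reads, 30L)
  expect_equal(res$summary$annotated_reads, 0L)
})

test_that("lowering the identity threshold never loses annotations", {
  res_default <- small_screen("S02")
  fx <- small_fixture()
  reads <- fx$reads$reads[fx$reads$reads$sample_id == "S02", ]
  res_loose <- screen_sample(reads, small_db(),
                             screen_thresholds(identity_min = 0.30),
                             sample_id = "S02")
  expect_gte(nrow(res_loose$annotated), nrow(res_default$annotated))
  expect_true(all(res_default$annotated$read_id %in%
                    res_loose$annotated$read_id))
})

test_that("hits TSV export carries blast-like columns", {
  res <- small_screen("S01")
  path <- tempfile(fileext = ".tsv")
  write_hits_tsv(res, path, header_comment = "h")
  lines <- readLines(path)
  expect_equal(lines[1], "# h")
  tab <- read.delim(path, comment.char = "#")
  expect_true(all(c("qseqid", "sseqid", "pident", "length", "evalue",
                    "bitscore", "frame", "subtype") %in% names(tab)))
  expect_equal(nrow(tab), nrow(res$annotated))
})
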