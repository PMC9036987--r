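# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env()

# Small community: 6 samples, 60 reads each — enough for per-stage
# behaviour without the cost of the full default fixture.
small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- simulation_config(seed = 42L, n_samples = 6L,
                             reads_per_sample = 60L,
                             mean_gene_reads = 5L)
    .fixture_cache$small <- simulate_fixture(cfg)
  }
  .fixture_cache$small
}

small_db <- function() {
  if (is.null(.fixture_cache$small_db)) {
    .fixture_cache$small_db <- dedupe(small_fixture()$refs$records, 0.97)
  }
  .fixture_cache$small_db
}

small_screen <- function(sample_id = "S01") {
  key <- paste0("screen_", sample_id)
  if (is.null(.fixture_cache[[key]])) {
    fx <- small_fixture()
    reads <- fx$reads$reads[fx$reads$reads$sample_id == sample_id, ]
    .fixture_cache[[key]] <- screen_sample(reads, small_db(),
                                           sample_id = sample_id)
  }
  .fixture_cache[[key]]
}

# 3-level toy taxonomy: one family holding two genera, plus an
# outgroup genus in its own family.
toy_tree <- function() {
  taxonomy_tree(data.frame(
    tax_id   = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
    parent_id = c(1L, 1L, 2L, 3L, 4L, 5L, 5L, 4L, 8L),
    rank = c("root", "superkingdom", "phylum", "class", "family",
             "genus", "genus", "family", "genus"),
    name = c("root", "Bacteria", "phy", "cls", "famA", "Pseudomonas",
             "Zoogloea", "famB", "Thauera"),
    stringsAsFactors = FALSE))
}

# Hand-made screen_result for abundance tests.
fake_screen_result <- function(sample_id, read_ids, ref_ids, subtypes,
                               total_reads) {
  ann <- data.frame(read_id = read_ids, ref_id = ref_ids,
                    subtype = subtypes, frame = 1L, raw_score = 250,
                    bit_score = 90, identity = 0.9,
                    alignment_length_aa = 30L, evalue = 1e-10,
                    sample_id = sample_id, stringsAsFactors = FALSE)
  structure(list(annotated = ann, top_hits = ann,
                 summary = list(sample_id = sample_id,
                                total_reads = total_reads,
                                annotated_reads = nrow(ann),
                                subtype_counts = as.list(
                                  table(factor(subtypes,
                                               levels = iaa_subtypes())))),
                 sample_id = sample_id),
            class = "screen_result")
}

write_temp_fasta <- function(entries, ext = ".faa") {
  path <- tempfile(fileext = ext)
  writeLines(unlist(lapply(names(entries), function(h) {
    c(paste0(">", h), entries[[h]])
  })), path)
  path
}
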