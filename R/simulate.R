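# Deterministic synthetic communities with planted truth: a toy
# taxonomy, subtype reference proteins with genus-specific variants,
# per-sample reads carrying those genes, and genus abundance series
# with latent-factor correlation structure. Everything is a pure
# function of (config, seed).

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Default genus panel of the synthetic community
#'
#' Bacterial genera observed to carry IAA-synthetase genes in
#' algal-bacterial reactor communities (signaled), common non-signaled
#' reactor bacteria, and phytoplankton with the IAA-regulated cyclin
#' marking the signaled alga.
#'
#' @return `data.frame` with columns `genus`, `kingdom`, `signaled`,
#'   `subtype` (carried gene subtype, `NA` for non-signaled genera).
#' @export
default_genera <- function() {
  data.frame(
    genus = c("Pseudomonas", "Hydrogenophaga", "Zoogloea", "Serratia",
              "Variovorax",
              "Bosea", "Rhizobium", "Hyphomicrobium", "Streptomyces",
              "Acidovorax", "Bradyrhizobium", "Thauera",
              "Chlorella", "Scenedesmus", "Navicula"),
    kingdom = c(rep("BACTERIA", 12), rep("PHYTOPLANKTON", 3)),
    signaled = c(rep(TRUE, 5), rep(FALSE, 7), TRUE, FALSE, FALSE),
    subtype = c("IPA_DEHYDROGENASE", "IAM_HYDROLASE", "IAM_HYDROLASE",
                "IAM_HYDROLASE", "IAN_NITRILASE",
                rep(NA_character_, 7),
                "ALGAL_CYCLIN", NA_character_, NA_character_),
    stringsAsFactors = FALSE)
}

#' Default planted correlation structure
#'
#' Positive latent-factor couplings between the signaled bacteria and
#' the signaled alga Chlorella, two positive couplings from
#' non-signaled bacteria, and three negative couplings — so the planted
#' signaled share of positive associations is 5 of 7.
#'
#' @return `data.frame` with columns `bacterium`, `phytoplankton`,
#'   `loading` and `sign` (`"POSITIVE"`/`"NEGATIVE"`).
#' @export
default_correlation_structure <- function() {
  data.frame(
    bacterium = c("Pseudomonas", "Hydrogenophaga", "Zoogloea",
                  "Serratia", "Variovorax", "Streptomyces",
                  "Acidovorax", "Bosea", "Rhizobium", "Hyphomicrobium"),
    phytoplankton = "Chlorella",
    loading = c(rep(1, 7), rep(-1, 3)),
    sign = c(rep("POSITIVE", 7), rep("NEGATIVE", 3)),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' All knobs of the synthetic community generator. With a fixed seed
#' every generator output is byte-identical across runs.
#'
#' @param seed Integer RNG seed.
#' @param n_samples Number of samples (>= 4; default 12).
#' @param genera Genus panel, see [default_genera()].
#' @param read_length_nt Read length (default 150).
#' @param reads_per_sample Total reads per sample, gene-bearing plus
#'   random background (default 200).
#' @param gene_mutation_rate Amino-acid divergence of a genus's gene
#'   variant from its subtype parent protein (default 0.02).
#' @param sequencing_error_rate Per-base substitution rate applied to
#'   reads (default 0.005).
#' @param mean_gene_reads Mean gene-bearing reads per signaled genus
#'   per sample; per-sample counts scale with the genus's abundance
#'   series (default 25).
#' @param noise_sd Log-scale noise standard deviation of the abundance
#'   model (default 0.3).
#' @param correlation_structure Planted couplings, see
#'   [default_correlation_structure()].
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_samples = 12L,
                              genera = default_genera(),
                              read_length_nt = 150L,
                              reads_per_sample = 200L,
                              gene_mutation_rate = 0.02,
                              sequencing_error_rate = 0.005,
                              mean_gene_reads = 25L,
                              noise_sd = 0.3,
                              correlation_structure =
                                default_correlation_structure()) {
  stopifnot(n_samples >= 4, read_length_nt >= 30,
            gene_mutation_rate >= 0, gene_mutation_rate < 1,
            sequencing_error_rate >= 0, sequencing_error_rate < 1,
            noise_sd > 0)
  if (anyDuplicated(genera$genus)) stop("duplicate genus names")
  cs <- correlation_structure
  bad <- !(cs$bacterium %in% genera$genus[genera$kingdom == "BACTERIA"]) |
    !(cs$phytoplankton %in%
        genera$genus[genera$kingdom == "PHYTOPLANKTON"])
  if (any(bad)) stop("correlation structure names unknown genera")
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 genera = genera, read_length_nt = as.integer(read_length_nt),
                 reads_per_sample = as.integer(reads_per_sample),
                 gene_mutation_rate = gene_mutation_rate,
                 sequencing_error_rate = sequencing_error_rate,
                 mean_gene_reads = mean_gene_reads, noise_sd = noise_sd,
                 correlation_structure = cs),
            class = "simulation_config")
}

.sample_ids <- function(config) {
  sprintf("S%02d", seq_len(config$n_samples))
}

#' Build the toy taxonomy for a simulated community
#'
#' Root - superkingdom - phylum - class - order - family - genus chains
#' for every configured genus; phylum through order are shared within a
#' superkingdom, each genus gets its own family.
#'
#' @param config A [simulation_config()].
#' @param path Optional TSV output path.
#' @return A `taxonomy_tree`.
#' @export
make_taxonomy <- function(config, path = NULL) {
  g <- config$genera
  if (anyDuplicated(g$genus)) stop("duplicate genus names")
  rows <- list(data.frame(tax_id = 1L, parent_id = 1L, rank = "root",
                          name = "root", stringsAsFactors = FALSE))
  nid <- 1L
  add <- function(rank, name, parent) {
    nid <<- nid + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      tax_id = nid, parent_id = parent, rank = rank, name = name,
      stringsAsFactors = FALSE)
    nid
  }
  for (sk in unique(g$kingdom)) {
    skname <- if (sk == "BACTERIA") "Bacteria" else "Eukaryota"
    sk_id <- add("superkingdom", skname, 1L)
    ph_id <- add("phylum", paste0(skname, "_phylum"), sk_id)
    cl_id <- add("class", paste0(skname, "_class"), ph_id)
    or_id <- add("order", paste0(skname, "_order"), cl_id)
    for (i in which(g$kingdom == sk)) {
      fa_id <- add("family", paste0(g$genus[i], "_family"), or_id)
      add("genus", g$genus[i], fa_id)
    }
  }
  tree <- taxonomy_tree(do.call(rbind, rows))
  if (!is.null(path)) {
    write.table(tree$nodes, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tree
}

.AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
           "S","T","V","W","Y")

.random_protein <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

.mutate_protein <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(.AA20, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

# aa -> codons (standard code, stop codons excluded)
.codon_table <- local({
  env <- new.env()
  function() {
    if (is.null(env$tab)) {
      gc <- Biostrings::GENETIC_CODE
      gc <- gc[gc != "*"]
      env$tab <- split(names(gc), unname(gc))
    }
    env$tab
  }
})

.reverse_translate <- function(protein) {
  tab <- .codon_table()
  aas <- strsplit(protein, "")[[1]]
  paste(vapply(aas, function(a) {
    cods <- tab[[a]]
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

#' Generate subtype reference proteins with planted structure
#'
#' For every subtype: two unrelated random proteins (300-500 aa) plus a
#' near-duplicate (about 99% identity) of the first, to exercise
#' non-redundancy clustering; and, for every signaled genus carrying
#' the subtype, a genus-tagged variant derived from a genus-specific
#' parent protein at `gene_mutation_rate` divergence. Parents are not
#' emitted into the reference set (they exist only as the divergence
#' baseline in the manifest). Each emitted reference also receives a
#' deterministic coding nucleotide sequence, the template reads are
#' drawn from.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, one FASTA per subtype is
#'   written (`<subtype>.faa`).
#' @return List with `records` (protein record table), `parents`
#'   (`data.frame` id, variant_id, sequence) and `genes` (named vector
#'   of coding nucleotide sequences per record id).
#' @export
make_references <- function(config, dir = NULL) {
  .with_seed(config$seed + 1L, {
    recs <- list(); parents <- list()
    for (st in .SUBTYPES) {
      pre <- sub("_.*$", "", st)
      for (k in 1:2) {
        recs[[length(recs) + 1L]] <- protein_records(
          paste0(pre, "_ref", k), st,
          .random_protein(sample(300:500, 1L)))
      }
      base <- recs[[length(recs) - 1L]]$sequence
      recs[[length(recs) + 1L]] <- protein_records(
        paste0(pre, "_ref1b"), st, .mutate_protein(base, 0.01))
      carriers <- config$genera$genus[
        !is.na(config$genera$subtype) & config$genera$subtype == st]
      for (g in carriers) {
        parent <- .random_protein(sample(300:500, 1L))
        vid <- paste0(pre, "_", g)
        recs[[length(recs) + 1L]] <- protein_records(
          vid, st, .mutate_protein(parent, config$gene_mutation_rate),
          source_genus = g)
        parents[[length(parents) + 1L]] <- data.frame(
          id = paste0(vid, "_parent"), variant_id = vid,
          sequence = parent, stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, recs)
    genes <- vapply(records$sequence, .reverse_translate, character(1))
    names(genes) <- records$id
    out <- list(records = records,
                parents = do.call(rbind, parents),
                genes = genes)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (st in .SUBTYPES) {
        r <- records[records$subtype == st, ]
        aa <- Biostrings::AAStringSet(r$sequence)
        names(aa) <- paste0(
          r$id, ifelse(is.na(r$source_genus), "",
                       paste0(" genus=", r$source_genus)))
        Biostrings::writeXStringSet(
          aa, file.path(dir, paste0(tolower(st), ".faa")))
      }
    }
    out
  })
}

#' Generate genus abundance series with planted associations
#'
#' Log-normal abundance model with shared latent factors: every
#' phytoplankton genus carries a per-sample factor `F_s ~ N(0,1)`; a
#' planted pair couples its bacterium to that factor with the
#' configured loading (negative loadings give inverse associations);
#' uncoupled genera are pure log-normal noise. Spearman detection of a
#' planted pair is therefore a genuine statistical event, not a rank
#' construction.
#'
#' @param config A [simulation_config()].
#' @param path Optional TSV output path (genus x sample).
#' @return List with `series` (matrix, samples x genera) and `truth`
#'   (planted pairs with intended signs).
#' @export
make_abundance_series <- function(config, path = NULL) {
  .with_seed(config$seed + 2L, {
    g <- config$genera
    cs <- config$correlation_structure
    n <- config$n_samples
    samples <- .sample_ids(config)
    mat <- matrix(0, nrow = n, ncol = nrow(g),
                  dimnames = list(samples, g$genus))
    phyto <- g$genus[g$kingdom == "PHYTOPLANKTON"]
    factors <- matrix(rnorm(n * length(phyto)), nrow = n,
                      dimnames = list(samples, phyto))
    for (ph in phyto) {
      mat[, ph] <- exp(factors[, ph] + rnorm(n, sd = config$noise_sd))
    }
    for (b in g$genus[g$kingdom == "BACTERIA"]) {
      rows <- cs[cs$bacterium == b, , drop = FALSE]
      signal <- if (nrow(rows)) {
        as.vector(factors[, rows$phytoplankton, drop = FALSE] %*%
                    rows$loading)
      } else {
        rnorm(n)
      }
      mat[, b] <- exp(signal + rnorm(n, sd = config$noise_sd))
    }
    if (!is.null(path)) {
      write_abundance_tsv(abundance_table(mat, "RPKM"), path)
    }
    list(series = mat,
         truth = cs[, c("bacterium", "phytoplankton", "sign")])
  })
}

.DNA4 <- c("A", "C", "G", "T")

.sequencing_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(.DNA4, chars[i]), 1L)
  paste(chars, collapse = "")
}

.revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Generate per-sample reads with a planted truth table
#'
#' Gene-bearing reads are substrings of the coding sequences of the
#' signaled genera's gene variants (counts per sample proportional to
#' that genus's abundance series around `mean_gene_reads`), drawn at a
#' random position and strand and perturbed with sequencing errors.
#' The remainder of each sample is uniform-random background
#' nucleotides, guaranteeing no accidental homology with the reference
#' set.
#'
#' @param config A [simulation_config()].
#' @param refs Output of [make_references()].
#' @param series Abundance matrix from [make_abundance_series()].
#' @param dir Optional directory; when given, one FASTQ per sample
#'   (`<sample>.fastq`) and a `truth.tsv` are written.
#' @return List with `reads` (`data.frame` id, sequence, sample_id) and
#'   `truth` (`data.frame` read_id, sample_id, genus, subtype;
#'   background reads carry `"background"`).
#' @export
make_reads <- function(config, refs, series, dir = NULL) {
  .with_seed(config$seed + 3L, {
    g <- config$genera
    carriers <- g[!is.na(g$subtype), , drop = FALSE]
    rl <- config$read_length_nt
    reads <- list(); truth <- list()
    for (sid in .sample_ids(config)) {
      n_read <- 0L
      emit <- function(seq, genus, subtype) {
        n_read <<- n_read + 1L
        id <- sprintf("%s_r%05d", sid, n_read)
        reads[[length(reads) + 1L]] <<- data.frame(
          id = id, sequence = seq, sample_id = sid,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <<- data.frame(
          read_id = id, sample_id = sid, genus = genus,
          subtype = subtype, stringsAsFactors = FALSE)
      }
      gene_total <- 0L
      for (i in seq_len(nrow(carriers))) {
        gn <- carriers$genus[i]
        pre <- sub("_.*$", "", carriers$subtype[i])
        gene <- refs$genes[[paste0(pre, "_", gn)]]
        a <- series[, gn]
        cnt <- if (mean(a) > 0) {
          as.integer(round(config$mean_gene_reads *
                             series[sid, gn] / mean(a)))
        } else 0L
        gene_total <- gene_total + cnt
        L <- nchar(gene)
        if (cnt > 0 && L >= rl) {
          for (k in seq_len(cnt)) {
            start <- sample.int(L - rl + 1L, 1L)
            frag <- substr(gene, start, start + rl - 1L)
            if (runif(1) < 0.5) frag <- .revcomp_chr(frag)
            emit(.sequencing_errors(frag, config$sequencing_error_rate),
                 gn, carriers$subtype[i])
          }
        }
      }
      n_bg <- max(0L, config$reads_per_sample - gene_total)
      for (k in seq_len(n_bg)) {
        emit(paste(sample(.DNA4, rl, replace = TRUE), collapse = ""),
             "background", "background")
      }
    }
    reads <- do.call(rbind, reads)
    truth <- do.call(rbind, truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      qual <- strrep("I", rl)
      for (sid in unique(reads$sample_id)) {
        r <- reads[reads$sample_id == sid, ]
        writeLines(as.vector(rbind(paste0("@", r$id), r$sequence,
                                   "+", qual)),
                   file.path(dir, paste0(sid, ".fastq")))
      }
      write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    list(reads = reads, truth = truth)
  })
}

#' Generate the complete synthetic fixture set
#'
#' One call produces taxonomy, references, abundance series and reads;
#' with `dir` set, all artefacts are written as plain-text files
#' (taxonomy TSV, per-subtype FASTA, abundance TSV, per-sample FASTQ,
#' truth TSVs).
#'
#' @param config A [simulation_config()].
#' @param dir Optional fixture directory.
#' @return List with `config`, `tree`, `refs`, `abundance`, `reads`.
#' @export
simulate_fixture <- function(config = simulation_config(), dir = NULL) {
  tax_path <- if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    file.path(dir, "taxonomy.tsv")
  }
  tree <- make_taxonomy(config, tax_path)
  refs <- make_references(config,
                          if (!is.null(dir)) file.path(dir, "refs"))
  ab <- make_abundance_series(config,
                              if (!is.null(dir))
                                file.path(dir, "abundance.tsv"))
  reads <- make_reads(config, refs, ab$series,
                      if (!is.null(dir)) file.path(dir, "reads"))
  list(config = config, tree = tree, refs = refs, abundance = ab,
       reads = reads)
}

#' Configuration with a planted signaled positive-edge fraction
#'
#' Builds a community whose planted positive couplings give a known
#' signaled share: of ten positive bacterium-alga pairs,
#' `round(10 * f)` involve signaled bacteria; two negative couplings
#' and two uncoupled noise phytoplankton are added.
#'
#' @param f Target signaled fraction of positive edges, in `[0, 1]`.
#' @param n_samples Number of samples (default 24).
#' @param seed RNG seed.
#' @return A [simulation_config()].
#' @export
fraction_config <- function(f, n_samples = 24L, seed = 1L) {
  stopifnot(f >= 0, f <= 1)
  n_pos <- 10L
  n_sig <- as.integer(round(n_pos * f))
  sig <- sprintf("SigBact%02d", seq_len(n_sig))
  nonsig_pos <- sprintf("NonBact%02d", seq_len(n_pos - n_sig))
  nonsig_neg <- c("NegBactA", "NegBactB")
  genera <- data.frame(
    genus = c(sig, nonsig_pos, nonsig_neg,
              "Chlorella", "Scenedesmus", "Navicula"),
    kingdom = c(rep("BACTERIA", n_pos + 2L), rep("PHYTOPLANKTON", 3L)),
    signaled = c(rep(TRUE, n_sig), rep(FALSE, n_pos - n_sig + 2L),
                 TRUE, FALSE, FALSE),
    subtype = c(rep(.BACTERIAL_SUBTYPES, length.out = n_sig),
                rep(NA_character_, n_pos - n_sig + 2L),
                "ALGAL_CYCLIN", NA_character_, NA_character_),
    stringsAsFactors = FALSE)
  cs <- data.frame(
    bacterium = c(sig, nonsig_pos, nonsig_neg),
    phytoplankton = "Chlorella",
    loading = c(rep(1, n_pos), rep(-1, 2L)),
    sign = c(rep("POSITIVE", n_pos), rep("NEGATIVE", 2L)),
    stringsAsFactors = FALSE)
  simulation_config(seed = seed, n_samples = n_samples,
                    genera = genera, correlation_structure = cs)
}
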