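# Independent brute-force oracles, deliberately written without the
# package's code paths: a textbook affine-gap local-alignment DP, a
# root-path-intersection LCA, an exhaustive-BFS metric suite, and an
# all-alignments identity search for short sequences.

.oracle_blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      env$m <- e$BLOSUM62
    }
    env$m
  }
})

# Gotoh local alignment: gap of length k costs open + k * ext.
sw_oracle <- function(a, b, open = 11, ext = 1) {
  S <- .oracle_blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (deletion from a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
      diag <- max(M[i, j], X[i, j], Y[i, j]) + S[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0, diag)
      best <- max(best, M[i + 1, j + 1],
                  X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

# LCA by explicit root-path intersection on the raw node table.
lca_oracle <- function(taxa, nodes) {
  parent <- setNames(nodes$parent_id, as.character(nodes$tax_id))
  path_of <- function(id) {
    p <- id
    while (parent[[as.character(id)]] != id) {
      id <- parent[[as.character(id)]]
      p <- c(id, p)
    }
    p
  }
  paths <- lapply(taxa, path_of)
  common <- Reduce(intersect, paths)
  # deepest common node = last element of any path restricted to common
  keep <- paths[[1]][paths[[1]] %in% common]
  keep[length(keep)]
}

# Random rank-complete taxonomy: root-superkingdom-...-genus, with
# random branching at every level.
random_tree <- function(n_genera = 6) {
  ranks <- c("superkingdom", "phylum", "class", "order", "family",
             "genus")
  nodes <- data.frame(tax_id = 1L, parent_id = 1L, rank = "root",
                      name = "root", stringsAsFactors = FALSE)
  nid <- 1L
  level_ids <- 1L
  for (r in ranks) {
    n_new <- if (r == "genus") n_genera else
      sample(1:max(2, length(level_ids)), 1)
    new_ids <- integer(0)
    for (k in seq_len(n_new)) {
      nid <- nid + 1L
      parent <- if (length(level_ids) == 1L) level_ids else
        sample(level_ids, 1)
      nodes <- rbind(nodes, data.frame(
        tax_id = nid, parent_id = parent, rank = r,
        name = paste0(r, nid), stringsAsFactors = FALSE))
      new_ids <- c(new_ids, nid)
    }
    level_ids <- new_ids
  }
  nodes
}

# --- network metric oracles (edge list + node count in, no igraph) ---

.adj_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      A[edges$i[k], edges$j[k]] <- 1L
      A[edges$j[k], edges$i[k]] <- 1L
    }
  }
  A
}

.bfs_dist <- function(A, start) {
  n <- nrow(A)
  d <- rep(Inf, n)
  d[start] <- 0
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in which(A[v, ] == 1L)) {
      if (!is.finite(d[u])) {
        d[u] <- d[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  d
}

metrics_oracle <- function(n, edges) {
  A <- .adj_from_edges(n, edges)
  deg <- rowSums(A)
  e <- nrow(edges)
  density <- 2 * e / (n * (n - 1))
  het <- if (mean(deg) > 0) sqrt(mean((deg - mean(deg))^2)) / mean(deg)
    else 0
  centr <- (n / (n - 2)) * (max(deg) / (n - 1) - density)
  closeness <- vapply(seq_len(n), function(i) {
    d <- .bfs_dist(A, i)[-i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
  # components by repeated BFS
  membership <- rep(NA_integer_, n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (is.na(membership[i])) {
      comp <- comp + 1L
      membership[is.finite(.bfs_dist(A, i))] <- comp
    }
  }
  info <- numeric(n)
  for (k in seq_len(comp)) {
    idx <- which(membership == k)
    m <- length(idx)
    if (m < 2) { info[idx] <- 0; next }
    Ak <- A[idx, idx, drop = FALSE]
    B <- diag(rowSums(Ak)) - Ak + matrix(1, m, m)
    C <- solve(B)
    info[idx] <- 1 / (diag(C) + (sum(diag(C)) - 2 * rowSums(C)) / m)
  }
  list(density = density, heterogeneity = het, centralization = centr,
       closeness = closeness, information = info)
}

# Random connected-ish simple graph on n nodes as a signaling_network
# (bipartite labels assigned arbitrarily; metrics ignore attributes).
random_network <- function(n, p_edge = 0.45) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p_edge
  # guarantee at least one edge
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  pairs <- pairs[keep, , drop = FALSE]
  genus <- paste0("G", seq_len(n))
  nodes <- data.frame(genus = genus,
                      kingdom = rep(c("BACTERIA", "PHYTOPLANKTON"),
                                    length.out = n),
                      signaled = rep(c(TRUE, FALSE), length.out = n),
                      stringsAsFactors = FALSE)
  rho <- runif(nrow(pairs), 0.61, 0.99) *
    sample(c(-1, 1), nrow(pairs), replace = TRUE)
  edges <- data.frame(genus_a = genus[pairs[, 1]],
                      genus_b = genus[pairs[, 2]],
                      rho = rho, p = 0.001,
                      sign = ifelse(rho > 0, "POSITIVE", "NEGATIVE"),
                      stringsAsFactors = FALSE)
  list(net = signaling_network(nodes, edges),
       idx = data.frame(i = pairs[, 1], j = pairs[, 2]))
}

random_peptide <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                 "Q","R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}
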