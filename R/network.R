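#' Spearman rank correlation with small-sample exact p-value
#'
#' Tie-corrected Spearman correlation (Pearson correlation of ranks).
#' The two-sided p-value uses the exact permutation distribution of the
#' statistic when `n <= 9` (all `n!` permutations are enumerated) and
#' the t approximation with `n - 2` degrees of freedom otherwise. The
#' exact route avoids the anti-conservative t approximation in the
#' very-small-n regime typical of reactor time-series designs.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`; neither may be
#'   constant.
#' @return List with elements `rho` and `p`.
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("correlation undefined for a constant series")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    sx <- (rx - mean(rx)) / stats::sd(rx)
    sy <- (ry - mean(ry)) / stats::sd(ry)
    perms <- .perm_matrix(n)
    rho_perm <- (matrix(sy[perms], nrow = nrow(perms)) %*% sx) / (n - 1)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    r2 <- min(abs(rho), 1 - 1e-15)
    tstat <- r2 * sqrt((n - 2) / (1 - r2^2))
    p <- 2 * stats::pt(-tstat, df = n - 2)
  }
  list(rho = rho, p = p)
}

# All permutations of 1..n as an (n! x n) integer matrix, built by
# insertion; n is capped at 9 (362,880 rows).
.perm_matrix <- function(n) {
  stopifnot(n >= 1, n <= 9)
  p <- matrix(1L, 1, 1)
  for (k in 2:n) {
    rows <- nrow(p)
    out <- matrix(0L, rows * k, k)
    for (pos in seq_len(k)) {
      block <- (pos - 1L) * rows + seq_len(rows)
      if (pos > 1L) out[block, seq_len(pos - 1L)] <-
          p[, seq_len(pos - 1L), drop = FALSE]
      out[block, pos] <- k
      if (pos < k) out[block, (pos + 1L):k] <-
          p[, pos:(k - 1L), drop = FALSE]
    }
    p <- out
  }
  p
}

#' Build a thresholded bacteria-phytoplankton co-occurrence network
#'
#' Computes Spearman correlations between every bacterial and every
#' phytoplankton genus abundance series and keeps an edge when
#' `|rho| > rho_threshold` and `p < p_threshold` (both strict). Only
#' interkingdom pairs are tested; bacteria-bacteria and
#' phytoplankton-phytoplankton edges never occur. Negative correlations
#' are retained with sign `NEGATIVE`.
#'
#' @param profiles Numeric matrix of abundance series, samples as rows
#'   and genera as columns (column names are genus names); `>= 4`
#'   samples required.
#' @param flags `data.frame` with columns `genus`, `kingdom`
#'   (`"BACTERIA"` or `"PHYTOPLANKTON"`) and `signaled` (logical).
#' @param rho_threshold Correlation-magnitude threshold (default 0.6).
#' @param p_threshold Significance threshold (default 0.01).
#' @return A `signaling_network`: list with `nodes` (genus, kingdom,
#'   signaled; only genera incident to an edge), `edges` (genus_a =
#'   bacterium, genus_b = phytoplankton, rho, p, sign), `thresholds`.
#' @export
build_network <- function(profiles, flags, rho_threshold = 0.6,
                          p_threshold = 0.01) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 4) {
    stop("need at least 4 samples for correlation inference")
  }
  req <- c("genus", "kingdom", "signaled")
  if (!all(req %in% names(flags))) {
    stop("flags needs columns: ", paste(req, collapse = ", "))
  }
  if (!all(flags$kingdom %in% c("BACTERIA", "PHYTOPLANKTON"))) {
    stop("kingdom must be BACTERIA or PHYTOPLANKTON")
  }
  flags <- flags[flags$genus %in% colnames(profiles), , drop = FALSE]
  bact <- flags$genus[flags$kingdom == "BACTERIA"]
  phyto <- flags$genus[flags$kingdom == "PHYTOPLANKTON"]
  edges <- list()
  for (b in bact) {
    for (ph in phyto) {
      xs <- profiles[, b]; ys <- profiles[, ph]
      if (length(unique(xs)) == 1L || length(unique(ys)) == 1L) next
      sp <- spearman(xs, ys)
      if (abs(sp$rho) > rho_threshold && sp$p < p_threshold) {
        edges[[length(edges) + 1L]] <- data.frame(
          genus_a = b, genus_b = ph, rho = sp$rho, p = sp$p,
          sign = if (sp$rho > 0) "POSITIVE" else "NEGATIVE",
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(genus_a = character(0), genus_b = character(0),
               rho = numeric(0), p = numeric(0), sign = character(0),
               stringsAsFactors = FALSE)
  used <- unique(c(edges$genus_a, edges$genus_b))
  nodes <- flags[flags$genus %in% used,
                 c("genus", "kingdom", "signaled")]
  rownames(nodes) <- NULL
  signaling_network(nodes, edges, rho_threshold, p_threshold)
}

#' Construct a signaling network from node and edge tables
#'
#' Lower-level constructor used by [build_network()] and useful for
#' assembling a network from published edge counts or an external edge
#' list.
#'
#' @param nodes `data.frame`: `genus`, `kingdom`, `signaled`.
#' @param edges `data.frame`: `genus_a`, `genus_b`, `rho`, `p`, `sign`.
#' @param rho_threshold,p_threshold The thresholds the edges satisfy.
#' @return A `signaling_network` object.
#' @export
signaling_network <- function(nodes, edges, rho_threshold = 0.6,
                              p_threshold = 0.01) {
  if (nrow(edges)) {
    if (any(edges$genus_a == edges$genus_b)) stop("self-loop edge")
    sgn <- ifelse(edges$rho > 0, "POSITIVE", "NEGATIVE")
    if (!all(edges$sign == sgn)) {
      stop("edge sign must match the sign of rho")
    }
    missing <- setdiff(unique(c(edges$genus_a, edges$genus_b)),
                       nodes$genus)
    if (length(missing)) {
      stop("edge endpoints missing from nodes: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(rho = rho_threshold,
                                   p = p_threshold)),
            class = "signaling_network")
}

#' Convert a signaling network to an igraph graph
#'
#' @param net A `signaling_network`.
#' @return An undirected `igraph` graph with node attributes `kingdom`
#'   and `signaled` and edge attributes `rho`, `p`, `sign`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("genus_a", "genus_b", "rho", "p", "sign"),
              drop = FALSE],
    directed = FALSE, vertices = net$nodes)
}

#' @export
print.signaling_network <- function(x, ...) {
  cat("Signaling network:", nrow(x$nodes), "genera,",
      nrow(x$edges), "edges",
      sprintf("(|rho| > %g, p < %g)\n", x$thresholds$rho,
              x$thresholds$p))
  if (nrow(x$edges)) {
    cat("  positive:", sum(x$edges$sign == "POSITIVE"),
        " negative:", sum(x$edges$sign == "NEGATIVE"), "\n")
  }
  invisible(x)
}

#' @export
#' @method summary signaling_network
summary.signaling_network <- function(object, ...) {
  print(object)
  if (nrow(object$edges) >= 1 && nrow(object$nodes) >= 3) {
    m <- network_metrics(object)
    cat(sprintf("  density %.3f  heterogeneity %.3f  centralization %.3f\n",
                m$density, m$heterogeneity, m$centralization))
  }
  if (any(object$edges$sign == "POSITIVE")) {
    f <- signaled_positive_fraction(object)
    cat(sprintf("  signaled positive-edge fraction: %.2f%% (%d vs %d)\n",
                f$fraction, f$n_signaled_pos, f$n_nonsignaled_pos))
  }
  invisible(object)
}

#' @export
#' @method plot signaling_network
plot.signaling_network <- function(x, ...) {
  g <- as_igraph(x)
  shape <- ifelse(igraph::V(g)$kingdom == "PHYTOPLANKTON", "square",
                  "circle")
  col <- ifelse(igraph::V(g)$signaled, "palegreen3", "grey80")
  ecol <- ifelse(igraph::E(g)$sign == "POSITIVE", "firebrick",
                 "steelblue")
  igraph::plot.igraph(g, vertex.shape = shape, vertex.color = col,
                      edge.color = ecol, ...)
  invisible(x)
}

#' Degree-based and current-flow metrics of a network
#'
#' Computes the metric suite used to characterise co-occurrence
#' networks, with the NetworkAnalyzer definitions: density
#' `2E / (N (N-1))`; heterogeneity, the coefficient of variation of the
#' degree distribution (population variance); degree centralization
#' `(N / (N-2)) * (max degree / (N-1) - density)`; closeness centrality
#' per node as (number of reachable nodes) / (sum of shortest-path
#' distances to them), computed within connected components; and
#' Stephenson-Zelen information centrality per node, from the inverse
#' of `B = D - A + J` per component (`D` degree matrix, `A` adjacency,
#' `J` all-ones): `I_i = 1 / (C_ii + (trace(C) - 2 rowsum_i(C)) / N)`.
#' Isolated nodes have closeness and information centrality 0.
#'
#' @param net A `signaling_network` or an `igraph` graph.
#' @return A `network_metrics` list: `density`, `heterogeneity`,
#'   `centralization`, `information_centrality` and
#'   `closeness_centrality` (each `c(mean, sd)`), and `per_node`
#'   (`data.frame` of node-level values).
#' @export
network_metrics <- function(net) {
  g <- if (inherits(net, "signaling_network")) as_igraph(net) else net
  n <- igraph::vcount(g)
  if (n < 1) stop("network has no nodes")
  e <- igraph::ecount(g)
  deg <- igraph::degree(g)
  density <- if (n > 1) 2 * e / (n * (n - 1)) else 0
  mean_deg <- mean(deg)
  heterogeneity <- if (mean_deg > 0) {
    sqrt(mean((deg - mean_deg)^2)) / mean_deg
  } else 0
  if (n < 3) stop("centralization undefined for fewer than 3 nodes")
  centralization <- (n / (n - 2)) * (max(deg) / (n - 1) - density)

  d <- igraph::distances(g)
  closeness <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0L) 0 else length(di) / sum(di)
  }, numeric(1))

  info <- .information_centrality(g)

  structure(list(
    density = density,
    heterogeneity = heterogeneity,
    centralization = centralization,
    information_centrality = c(mean = mean(info), sd = stats::sd(info)),
    closeness_centrality = c(mean = mean(closeness),
                             sd = stats::sd(closeness)),
    per_node = data.frame(node = igraph::V(g)$name, degree = deg,
                          closeness = closeness,
                          information = info,
                          stringsAsFactors = FALSE)
  ), class = "network_metrics")
}

# Stephenson-Zelen information centrality, per connected component.
.information_centrality <- function(g) {
  n <- igraph::vcount(g)
  out <- numeric(n)
  comp <- igraph::components(g)
  for (k in seq_len(comp$no)) {
    idx <- which(comp$membership == k)
    m <- length(idx)
    if (m < 2) { out[idx] <- 0; next }
    sub <- igraph::induced_subgraph(g, idx)
    A <- as.matrix(igraph::as_adjacency_matrix(sub))
    B <- diag(igraph::degree(sub)) - A + 1
    C <- solve(B)
    tr <- sum(diag(C))
    rs <- rowSums(C)
    out[idx] <- 1 / (diag(C) + (tr - 2 * rs) / m)
  }
  out
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("density          %.3f\n", x$density))
  cat(sprintf("heterogeneity    %.3f\n", x$heterogeneity))
  cat(sprintf("centralization   %.3f\n", x$centralization))
  cat(sprintf("information centrality  %.3f +/- %.3f\n",
              x$information_centrality[["mean"]],
              x$information_centrality[["sd"]]))
  cat(sprintf("closeness centrality    %.3f +/- %.3f\n",
              x$closeness_centrality[["mean"]],
              x$closeness_centrality[["sd"]]))
  invisible(x)
}

#' Fraction of positive edges carried by signaled bacteria
#'
#' Partitions the network's positive edges by the signaled status of
#' their bacterial endpoint and reports the share contributed by
#' signaled bacteria, as a percentage with two decimals. This is the
#' summary statistic of the relative importance of IAA signaling in the
#' algal-bacterial interaction network.
#'
#' @param net A `signaling_network` with at least one positive edge.
#' @return List with `n_signaled_pos`, `n_nonsignaled_pos` and
#'   `fraction` (percent, rounded to 2 decimals).
#' @export
signaled_positive_fraction <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  pos <- net$edges[net$edges$sign == "POSITIVE", , drop = FALSE]
  if (nrow(pos) == 0L) {
    stop("no positive edges: fraction undefined")
  }
  kingdom <- setNames(net$nodes$kingdom, net$nodes$genus)
  signaled <- setNames(net$nodes$signaled, net$nodes$genus)
  bact_end <- ifelse(kingdom[pos$genus_a] == "BACTERIA",
                     pos$genus_a, pos$genus_b)
  s <- sum(signaled[bact_end])
  ns <- nrow(pos) - s
  list(n_signaled_pos = as.integer(s),
       n_nonsignaled_pos = as.integer(ns),
       fraction = round(100 * s / (s + ns), 2))
}

#' Write network artefacts
#'
#' Exports the edge list (with the bacterial endpoint's signaled flag),
#' node attributes, a GraphML file for external visualisation, and the
#' metric suite as JSON.
#'
#' @param net A `signaling_network`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param header_comment Optional `#`-prefixed first line for the TSVs.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_network <- function(net, dir, prefix = "network",
                          header_comment = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(dir, paste0(prefix, "_edges.tsv")),
             nodes = file.path(dir, paste0(prefix, "_nodes.tsv")),
             graphml = file.path(dir, paste0(prefix, ".graphml")),
             metrics = file.path(dir, paste0(prefix, "_metrics.json")))
  signaled <- setNames(net$nodes$signaled, net$nodes$genus)
  kingdom <- setNames(net$nodes$kingdom, net$nodes$genus)
  edges <- net$edges
  if (nrow(edges)) {
    bact_end <- ifelse(kingdom[edges$genus_a] == "BACTERIA",
                       edges$genus_a, edges$genus_b)
    edges$signaled_flag <- unname(signaled[bact_end])
  }
  .write_tsv_commented(edges, paths[["edges"]], header_comment)
  .write_tsv_commented(net$nodes, paths[["nodes"]], header_comment)
  igraph::write_graph(as_igraph(net), paths[["graphml"]],
                      format = "graphml")
  if (nrow(net$nodes) >= 3 && nrow(net$edges) >= 1) {
    m <- network_metrics(net)
    jsonlite::write_json(
      list(density = m$density, heterogeneity = m$heterogeneity,
           centralization = m$centralization,
           information_centrality_mean = m$information_centrality[["mean"]],
           information_centrality_sd = m$information_centrality[["sd"]],
           closeness_centrality_mean = m$closeness_centrality[["mean"]],
           closeness_centrality_sd = m$closeness_centrality[["sd"]]),
      paths[["metrics"]], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

.write_tsv_commented <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
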