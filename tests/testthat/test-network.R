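test_that("spearman handles monotone, reversed and hand-ranked series", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman(x, x * 3 + 1)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  # hand computation: d = (-1,1,-1,1,0), sum d^2 = 4,
  # rho = 1 - 6*4/(5*24) = 0.8
  sp <- spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(sp$rho, 0.8)
  expect_error(spearman(x, rep(2, 6)), "constant")
  expect_error(spearman(1:3, 3:1), "at least 4")
  expect_error(spearman(1:5, 1:4), "equal length")
})

test_that("spearman is symmetric and rank-transform invariant", {
  set.seed(19)
  for (k in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    a <- spearman(x, y); b <- spearman(y, x)
    expect_equal(a$rho, b$rho)
    expect_equal(a$p, b$p)
    # strictly monotone transforms leave ranks untouched
    expect_equal(spearman(exp(x), y^3 + 5 * y)$rho,
                 ifelse(all(y^3 + 5 * y == sort(y^3 + 5 * y)),
                        a$rho, a$rho))
    expect_equal(spearman(exp(x), y)$rho, a$rho)
  }
})

test_that("exact small-n p-values match the reference distribution", {
  set.seed(23)
  # n = 7, no ties: cor.test's exact Spearman p is the oracle
  for (k in 1:10) {
    x <- sample(1:7); y <- sample(1:7)
    sp <- spearman(x, y)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = TRUE))
    expect_equal(sp$rho, unname(ct$estimate))
    expect_equal(sp$p, min(1, ct$p.value), tolerance = 1e-10)
  }
  # large n falls back to the t approximation
  x <- 1:20; y <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11, 14, 13,
                    16, 15, 18, 17, 20, 19)
  sp <- spearman(x, y)
  r <- sp$rho
  tstat <- r * sqrt((20 - 2) / (1 - r^2))
  expect_equal(sp$p, 2 * stats::pt(-abs(tstat), 18))
})

test_that("network construction is bipartite and strictly thresholded", {
  set.seed(31)
  n <- 12
  f <- rnorm(n)
  series <- cbind(
    bactA = exp(f + rnorm(n, sd = 0.1)),     # planted positive
    bactB = exp(-f + rnorm(n, sd = 0.1)),    # planted negative
    bactC = exp(rnorm(n)),                   # independent
    algaX = exp(f + rnorm(n, sd = 0.1)),
    algaY = exp(rnorm(n)))
  rownames(series) <- paste0("S", 1:n)
  flags <- data.frame(
    genus = colnames(series),
    kingdom = c("BACTERIA", "BACTERIA", "BACTERIA",
                "PHYTOPLANKTON", "PHYTOPLANKTON"),
    signaled = c(TRUE, FALSE, FALSE, TRUE, FALSE))
  net <- build_network(series, flags)
  key <- paste(net$edges$genus_a, net$edges$genus_b)
  expect_true("bactA algaX" %in% key)
  expect_equal(net$edges$sign[key == "bactA algaX"], "POSITIVE")
  expect_true(all(net$edges$genus_a %in% c("bactA", "bactB", "bactC")))
  expect_true(all(net$edges$genus_b %in% c("algaX", "algaY")))
  expect_true(all(abs(net$edges$rho) > 0.6 & net$edges$p < 0.01))
  if ("bactB algaX" %in% key) {
    expect_equal(net$edges$sign[key == "bactB algaX"], "NEGATIVE")
  }
  expect_error(build_network(series[1:3, ], flags), "at least 4")
})

test_that("independent series essentially never produce an edge", {
  set.seed(37)
  n_rep <- 2000
  hits <- 0
  for (k in seq_len(n_rep)) {
    x <- rnorm(12); y <- rnorm(12)
    sp <- spearman(x, y)
    if (abs(sp$rho) > 0.6 && sp$p < 0.01) hits <- hits + 1
  }
  expect_lte(hits / n_rep, 0.025)
})

test_that("constructor rejects malformed networks", {
  nodes <- data.frame(genus = c("b", "p"),
                      kingdom = c("BACTERIA", "PHYTOPLANKTON"),
                      signaled = c(TRUE, FALSE))
  edge <- data.frame(genus_a = "b", genus_b = "p", rho = 0.9,
                     p = 0.001, sign = "NEGATIVE")
  expect_error(signaling_network(nodes, edge), "sign must match")
  loop <- data.frame(genus_a = "b", genus_b = "b", rho = 0.9,
                     p = 0.001, sign = "POSITIVE")
  expect_error(signaling_network(nodes, loop), "self-loop")
  ghost <- data.frame(genus_a = "b", genus_b = "q", rho = 0.9,
                      p = 0.001, sign = "POSITIVE")
  expect_error(signaling_network(nodes, ghost), "missing from nodes")
})

.k4 <- function() {
  nodes <- data.frame(genus = paste0("G", 1:4),
                      kingdom = rep(c("BACTERIA", "PHYTOPLANKTON"), 2),
                      signaled = TRUE)
  pairs <- t(combn(4, 2))
  edges <- data.frame(genus_a = paste0("G", pairs[, 1]),
                      genus_b = paste0("G", pairs[, 2]),
                      rho = 0.9, p = 0.001, sign = "POSITIVE")
  signaling_network(nodes, edges)
}

.star4 <- function() {
  nodes <- data.frame(genus = c("hub", "l1", "l2", "l3"),
                      kingdom = c("PHYTOPLANKTON", rep("BACTERIA", 3)),
                      signaled = c(TRUE, TRUE, FALSE, FALSE))
  edges <- data.frame(genus_a = "hub", genus_b = c("l1", "l2", "l3"),
                      rho = 0.9, p = 0.001, sign = "POSITIVE")
  signaling_network(nodes, edges)
}

test_that("metric closed forms hold on K4 and the 4-star", {
  mk4 <- network_metrics(.k4())
  expect_equal(mk4$density, 1.0)
  expect_equal(mk4$heterogeneity, 0.0)
  expect_equal(mk4$centralization, 0.0)
  ms <- network_metrics(.star4())
  expect_equal(ms$density, 0.5)
  expect_equal(ms$centralization, 1.0)
  # degrees {3,1,1,1}: sd_pop/mean = sqrt(0.75)/1.5
  expect_equal(ms$heterogeneity, sqrt(0.75) / 1.5, tolerance = 1e-12)
  expect_equal(ms$heterogeneity, 0.577, tolerance = 1e-3)
  # closeness of the hub is 3/3 = 1, of a leaf 3/(1+2+2) = 0.6
  expect_equal(sort(unique(round(ms$per_node$closeness, 10))),
               c(0.6, 1))
})

test_that("metrics agree with the brute-force oracle on random graphs", {
  set.seed(41)
  for (k in 1:20) {
    n <- sample(4:8, 1)
    rn <- random_network(n)
    m <- network_metrics(rn$net)
    o <- metrics_oracle(n, rn$idx)
    expect_equal(m$density, o$density)
    expect_equal(m$heterogeneity, o$heterogeneity)
    expect_equal(m$centralization, o$centralization)
    expect_equal(sort(m$per_node$closeness), sort(o$closeness),
                 tolerance = 1e-12)
    expect_equal(sort(m$per_node$information), sort(o$information),
                 tolerance = 1e-9)
    expect_equal(m$closeness_centrality[["mean"]], mean(o$closeness))
    expect_equal(m$information_centrality[["sd"]], sd(o$information))
  }
})

test_that("density rises with added edges; hub removal drops centralization", {
  star <- .star4()
  m0 <- network_metrics(star)
  more <- star
  more$edges <- rbind(more$edges,
                      data.frame(genus_a = "l1", genus_b = "l2",
                                 rho = 0.8, p = 0.001,
                                 sign = "POSITIVE"))
  expect_gt(network_metrics(more)$density, m0$density)
  expect_error(network_metrics(signaling_network(
    star$nodes[1:2, ],
    star$edges[1, , drop = FALSE])), "fewer than 3")
})

test_that("signaled positive-edge fraction partitions by the bacterial endpoint", {
  mk <- function(n_sig, n_non, n_neg = 0) {
    sig <- sprintf("sb%02d", seq_len(n_sig))
    non <- sprintf("nb%02d", seq_len(n_non))
    neg <- sprintf("gb%02d", seq_len(n_neg))
    nodes <- data.frame(
      genus = c(sig, non, neg, "Alga"),
      kingdom = c(rep("BACTERIA", n_sig + n_non + n_neg),
                  "PHYTOPLANKTON"),
      signaled = c(rep(TRUE, n_sig), rep(FALSE, n_non + n_neg), TRUE))
    edges <- data.frame(
      genus_a = c(sig, non, neg), genus_b = "Alga",
      rho = c(rep(0.9, n_sig + n_non), rep(-0.9, n_neg)),
      p = 0.001,
      sign = c(rep("POSITIVE", n_sig + n_non), rep("NEGATIVE", n_neg)))
    signaling_network(nodes, edges)
  }
  f <- signaled_positive_fraction(mk(26, 11))
  expect_equal(f$n_signaled_pos, 26L)
  expect_equal(f$n_nonsignaled_pos, 11L)
  expect_equal(f$fraction, 70.27)
  expect_equal(signaled_positive_fraction(mk(5, 0))$fraction, 100.00)
  expect_equal(signaled_positive_fraction(mk(4, 4))$fraction, 50.00)
  # negative edges are excluded from the fraction
  expect_equal(signaled_positive_fraction(mk(4, 4, 3))$fraction, 50.00)
  expect_error(signaled_positive_fraction(mk(0, 0, 3)),
               "no positive edges")
  # invariance under edge insertion order
  net <- mk(7, 3)
  shuf <- net
  set.seed(2)
  shuf$edges <- shuf$edges[sample(nrow(shuf$edges)), ]
  expect_equal(signaled_positive_fraction(shuf),
               signaled_positive_fraction(net))
})

test_that("network export writes edges, nodes, graphml and metrics", {
  dir <- tempfile("netout")
  paths <- write_network(.star4(), dir, header_comment = "cfg")
  expect_true(all(file.exists(paths)))
  edges <- read.delim(paths[["edges"]], comment.char = "#")
  expect_true("signaled_flag" %in% names(edges))
  # the bacterial endpoint's flag drives the partition
  expect_equal(edges$signaled_flag,
               c(TRUE, FALSE, FALSE))
  mj <- jsonlite::read_json(paths[["metrics"]])
  expect_equal(mj$density, 0.5)
  expect_true(grepl("graphml", readLines(paths[["graphml"]],
                                         n = 2)[2]))
})
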