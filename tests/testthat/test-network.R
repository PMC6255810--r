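path_net <- function() {
  suppressMessages(build_signaling_network(
    data.frame(source = c("A", "B", "C"), target = c("B", "C", "C"))))
}

test_that("network construction dedups edges and counts nodes", {
  el <- data.frame(source = c("A", "B", "A"), target = c("B", "C", "B"))
  expect_message(net <- build_signaling_network(el), "3 nodes, 2 edges")
  expect_equal(net$n_nodes, 3)
  expect_equal(net$n_edges, 2)

  expect_warning(suppressMessages(
    empty <- build_signaling_network(data.frame(source = character(),
                                                target = character()))),
    "empty")
  expect_equal(empty$n_nodes, 0)

  # 200-edge random file: counts match an independent line-wise tally
  set.seed(2)
  g <- random_edges(40, 200)
  f <- tempfile()
  write_sif(g$edges, f)
  parsed <- read_sif(f)
  expect_equal(nrow(parsed), nrow(g$edges))
  net <- suppressMessages(build_signaling_network(parsed))
  expect_equal(net$n_edges,
               nrow(unique(g$edges[, c("source", "target")])))
  expect_equal(net$n_nodes,
               length(unique(c(g$edges$source, g$edges$target))))
})

test_that("malformed SIF rows raise an error naming the line", {
  f <- tempfile()
  writeLines(c("A\tstimulation\tB", "oops"), f)
  expect_error(read_sif(f), "line 2")
})

test_that("RWR trivial fixed points", {
  # single node with self-loop: all mass stays at the seed
  net1 <- suppressMessages(build_signaling_network(
    data.frame(source = "A", target = "A")))
  p <- rwr_visiting_probabilities(net1, "A", r = 0.5, iterations = 7)
  expect_equal(unname(p["A"]), 1)

  # full return probability: p = e_seed on any graph
  net <- path_net()
  p <- rwr_visiting_probabilities(net, "A", r = 1, iterations = 15)
  expect_equal(unname(p[c("A", "B", "C")]), c(1, 0, 0))

  expect_error(rwr_visiting_probabilities(net, "ZZ"), "not in network")
})

test_that("path A->B->C with self-loop on C reaches (0.5, 0.25, 0.25)", {
  net <- path_net()
  p <- rwr_visiting_probabilities(net, "A", r = 0.5, iterations = 15)
  expect_equal(unname(p[c("A", "B", "C")]), c(0.5, 0.25, 0.25),
               tolerance = 1e-10)
  # monotone decrease with hop count along the path at low iteration count
  p3 <- rwr_visiting_probabilities(net, "A", r = 0.5, iterations = 3)
  expect_true(p3["A"] > p3["B"])
})

test_that("RWR conserves mass on random graphs with dangling nodes", {
  set.seed(8)
  for (i in 1:25) {
    g <- random_edges(sample(10:60, 1), sample(15:120, 1))
    net <- suppressMessages(build_signaling_network(g$edges,
                                                    nodes = g$nodes))
    seed <- sample(net$nodes, 1)
    p <- rwr_visiting_probabilities(net, seed, r = 0.5, iterations = 15)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("proximity matrix equals the truncated-series oracle", {
  set.seed(21)
  g <- random_edges(30, 80, no_dangling = TRUE)
  net <- suppressMessages(build_signaling_network(g$edges,
                                                  nodes = g$nodes))
  W <- dense_transition(g$edges, net$nodes)
  seeds <- sample(net$nodes, 5)
  tfs <- sample(net$nodes, 6)
  prox <- proximity_matrix(net, seeds, tfs, r = 0.5, iterations = 15)
  for (s in rownames(prox$probability)) {
    oracle <- rwr_series_oracle(W, match(s, net$nodes), 0.5, 15)
    expect_equal(unname(prox$probability[s, ]),
                 oracle[match(colnames(prox$probability), net$nodes)],
                 tolerance = 1e-12)
  }
  # distance transform: -log10, Inf exactly at probability 0
  expect_equal(prox$distance[prox$probability > 0],
               -log10(prox$probability[prox$probability > 0]))
  expect_true(all(is.infinite(prox$distance[prox$probability == 0])))
})

test_that("seed TF gets at least the return mass; unreachable TFs get 0", {
  net <- path_net()
  prox <- proximity_matrix(net, "A", c("A", "B"), r = 0.5)
  expect_gte(prox$probability["A", "A"], 0.5)
  # C cannot reach A or B
  prox2 <- proximity_matrix(net, "C", c("A", "B"), r = 0.5)
  expect_equal(unname(prox2$probability["C", ]), c(0, 0))
  expect_true(all(is.infinite(prox2$distance["C", ])))
  expect_warning(proximity_matrix(net, c("A", "NOPE"), "C"), "dropped")
})

test_that("gene distance aggregates over the gene's TFs", {
  net <- path_net()
  regs <- data.frame(tf = c("B", "C"), target = "VEGFA", mode = 1,
                     confidence = "A")
  prox <- proximity_matrix(net, "A", c("B", "C"), r = 0.5)
  # singleton TF: distance equals the protein->TF distance
  regs1 <- regs[1, ]
  expect_equal(gene_distance("A", "VEGFA", regs1, prox),
               prox$distance["A", "B"])
  # min and mean aggregation over a 2-TF row
  expect_equal(gene_distance("A", "VEGFA", regs, prox),
               min(prox$distance["A", c("B", "C")]))
  expect_equal(gene_distance("A", "VEGFA", regs, prox, aggregate = "mean"),
               mean(prox$distance["A", c("B", "C")]))
  expect_error(gene_distance("A", "NRG4", regs, prox), "no TFs")
  # all TFs unreachable -> Inf
  prox2 <- proximity_matrix(net, "C", c("B"), r = 0.5)
  expect_equal(gene_distance("C", "VEGFA", regs1, prox2), Inf)
})

test_that("protein ranking matches a full-sort oracle", {
  set.seed(33)
  g <- random_edges(40, 120, no_dangling = TRUE)
  net <- suppressMessages(build_signaling_network(g$edges,
                                                  nodes = g$nodes))
  tfs <- sample(net$nodes, 4)
  seeds <- setdiff(net$nodes, tfs)
  regs <- data.frame(tf = tfs, target = "VEGFA", mode = 1,
                     confidence = "B")
  prox <- proximity_matrix(net, seeds, tfs)
  rk <- rank_proteins_by_gene_proximity("VEGFA", prox, regs, k = 40)
  oracle_d <- apply(prox$distance, 1, min)
  oracle <- names(sort(oracle_d))  # ties: names already sorted by rowname
  expect_equal(rk$protein, oracle[seq_len(nrow(rk))])
  expect_true(!is.unsorted(rk$distance))
  # k larger than #proteins returns everything
  expect_equal(nrow(rank_proteins_by_gene_proximity("VEGFA", prox, regs,
                                                    k = 1000)),
               nrow(prox$distance))
  expect_error(rank_proteins_by_gene_proximity("VEGFA", prox, regs, k = 0),
               "positive")
})

test_that("a unique 1-hop regulator of the gene's only TF ranks first", {
  el <- data.frame(source = c("X", "A", "B", "TF1"),
                   target = c("TF1", "B", "A", "TF1"))
  el <- el[el$source != el$target, ]
  net <- suppressMessages(build_signaling_network(el))
  regs <- data.frame(tf = "TF1", target = "VEGFA", mode = 1,
                     confidence = "A")
  prox <- proximity_matrix(net, c("X", "A", "B"), "TF1")
  rk <- rank_proteins_by_gene_proximity("VEGFA", prox, regs, k = 3)
  expect_equal(rk$protein[1], "X")
})

test_that("ranking attaches representative-site ratio fold changes", {
  net <- path_net()
  regs <- data.frame(tf = "C", target = "VEGFA", mode = 1,
                     confidence = "A")
  prox <- proximity_matrix(net, c("A", "B"), "C")
  fcs <- data.frame(protein = c("A", "A", "B"),
                    site = c("S1", "S2", "S3"), treatment = "T",
                    log2fc = c(1, 2, -1))
  rk <- rank_proteins_by_gene_proximity("VEGFA", prox, regs, k = 2,
                                        fcs = fcs)
  expect_equal(rk$fold_change[rk$protein == "A"], 4)   # best site 2^2
  expect_equal(rk$fold_change[rk$protein == "B"], 0.5)
})

test_that("Mann-Whitney closeness test: exact enumeration and symmetry", {
  # altered {1,2} vs unaltered {3,4,5}: U = 0, one-sided p = 1/10
  prox <- list(distance = matrix(c(1, 2, 3, 4, 5), ncol = 1,
                                 dimnames = list(c("A", "B", "C", "D", "E"),
                                                 "TF1")),
               probability = NULL)
  class(prox) <- "proximity_matrix"
  fcs <- data.frame(protein = c("A", "B"), site = "S1", treatment = "T",
                    log2fc = 1)   # ratio 2 > 1.5 -> altered
  res <- compare_altered_vs_unaltered_distances(prox, fcs, tfs = "TF1")
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1 / 10)
  expect_equal(res$n_altered, 2)

  # both groups drawn from identical distance values: one-sided p ~ 1/2
  # (tie-corrected normal approximation sits just above it)
  prox2 <- list(distance = matrix(c(1, 2, 3, 1, 2, 3), ncol = 1,
                                  dimnames = list(LETTERS[1:6], "TF1")))
  class(prox2) <- "proximity_matrix"
  fcs2 <- data.frame(protein = c("A", "B", "C"), site = "S1",
                     treatment = "T", log2fc = 1)
  res2 <- compare_altered_vs_unaltered_distances(prox2, fcs2, tfs = "TF1")
  expect_lt(abs(res2$p.value - 0.5), 0.15)

  # empty group errors name the group
  fcs_none <- data.frame(protein = "A", site = "S1", treatment = "T",
                         log2fc = 0)
  expect_error(compare_altered_vs_unaltered_distances(prox, fcs_none,
                                                      tfs = "TF1"),
               "altered")
})

test_that("adding a direct seed->TF edge never lowers the visiting mass", {
  set.seed(77)
  for (i in 1:10) {
    g <- random_edges(25, 60, no_dangling = TRUE)
    net <- suppressMessages(build_signaling_network(g$edges,
                                                    nodes = g$nodes))
    seed <- sample(g$nodes, 1)
    tf <- sample(setdiff(g$nodes, seed), 1)
    if (any(g$edges$source == seed & g$edges$target == tf)) next
    p0 <- rwr_visiting_probabilities(net, seed, iterations = 50)
    g2 <- rbind(g$edges, data.frame(source = seed, target = tf))
    net2 <- suppressMessages(build_signaling_network(g2,
                                                     nodes = g$nodes))
    p1 <- rwr_visiting_probabilities(net2, seed, iterations = 50)
    expect_gte(p1[tf], p0[tf] - 1e-12)
  }
})
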