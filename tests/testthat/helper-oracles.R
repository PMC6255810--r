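# Independent oracles and small fixture builders. Everything here is
# deliberately naive (dense matrices, explicit loops) and shares no code
# with the implementation paths it checks.

# dense column-stochastic transition matrix from an edge data.frame;
# dangling columns stay zero
dense_transition <- function(edges, nodes) {
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    W[edges$target[i], edges$source[i]] <- 1
  }
  cs <- colSums(W)
  for (j in which(cs > 0)) W[, j] <- W[, j] / cs[j]
  W
}

# exact T-step iterate: r * sum_{t<T} (1-r)^t W^t e  +  (1-r)^T W^T e
rwr_series_oracle <- function(W, seed_idx, r, iterations) {
  n <- nrow(W)
  e <- numeric(n); e[seed_idx] <- 1
  acc <- numeric(n)
  term <- e
  for (t in 0:(iterations - 1)) {
    acc <- acc + (1 - r)^t * term
    term <- as.numeric(W %*% term)
  }
  r * acc + (1 - r)^iterations * term
}

# fixed point r (I - (1-r) W)^{-1} e
rwr_solve_oracle <- function(W, seed_idx, r) {
  n <- nrow(W)
  e <- numeric(n); e[seed_idx] <- 1
  as.numeric(r * solve(diag(n) - (1 - r) * W, e))
}

# random directed graph as an edge data.frame over named nodes;
# no_dangling appends a self-loop to every out-degree-0 node
random_edges <- function(n_nodes, n_edges, no_dangling = FALSE) {
  nodes <- sprintf("V%03d", seq_len(n_nodes))
  pairs <- unique(data.frame(
    source = sample(nodes, n_edges * 2, replace = TRUE),
    target = sample(nodes, n_edges * 2, replace = TRUE)))
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- utils::head(pairs, n_edges)
  if (no_dangling) {
    dang <- setdiff(nodes, pairs$source)
    if (length(dang) > 0) {
      pairs <- rbind(pairs, data.frame(source = dang, target = dang))
    }
  }
  list(nodes = nodes, edges = pairs)
}

# naive complete-linkage agglomeration; returns the sorted merge heights
naive_complete_heights <- function(m) {
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(j, i) }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# permutation null for the TF activity statistic: shuffle which genes are
# the targets, keeping the modes; two-sided p with add-one smoothing
perm_pvalue <- function(signature, target_genes, modes, n_draws = 10000) {
  G <- length(signature)
  q <- stats::qnorm(rank(signature, ties.method = "average") / (G + 1))
  names(q) <- names(signature)
  n <- length(target_genes)
  obs <- abs(sum(modes * q[target_genes]) / sqrt(n))
  stat <- replicate(n_draws, abs(sum(modes * sample(q, n)) / sqrt(n)))
  (sum(stat >= obs) + 1) / (n_draws + 1)
}

# small signed fold-change fixture
make_signed_table <- function(proteins, treatments, values) {
  d <- expand.grid(protein = proteins, treatment = treatments,
                   stringsAsFactors = FALSE)
  d$site <- "S1"
  d$log2fc <- values
  d$sign <- 1
  d$adjusted_log2fc <- values
  d[, c("protein", "site", "treatment", "log2fc", "sign",
        "adjusted_log2fc")]
}

# regulon fixture builder
make_regulons <- function(tfs, targets_per_tf, genes, modes = NULL) {
  do.call(rbind, lapply(seq_along(tfs), function(i) {
    tg <- genes[((i - 1) * targets_per_tf + seq_len(targets_per_tf) - 1) %%
                  length(genes) + 1]
    data.frame(tf = tfs[i], target = tg,
               mode = if (is.null(modes)) rep(1, targets_per_tf) else modes,
               confidence = "A")
  }))
}
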