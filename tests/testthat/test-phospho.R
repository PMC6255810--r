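make_records <- function(proteins, sites, conditions, signals) {
  data.frame(protein = proteins, site = sites, condition = conditions,
             signal = signals)
}

test_that("site fold changes equal the log ratio of condition means", {
  rec <- rbind(
    make_records("AKT1", "S473", c("CTRL", "BMP8"), c(100, 100)),
    make_records("AKT1", "T308", c("CTRL", "BMP8"), c(50, 100)),
    make_records("TP53", "S15", c("CTRL", "BMP8"), c(200, 50)))
  fc <- compute_site_fold_changes(rec, "CTRL", "BMP8")
  expect_equal(fc$log2fc[fc$site == "S473"], 0)      # identity case
  expect_equal(fc$log2fc[fc$site == "T308"], 1)      # doubled signal
  expect_equal(fc$log2fc[fc$site == "S15"], -2)

  # randomized 5-site fixture against a hand-computed log-ratio oracle
  set.seed(11)
  prot <- sprintf("P%d", 1:5)
  sites <- sprintf("S%d", 11:15)
  ctrl <- runif(5, 10, 1000)
  tr1 <- runif(5, 10, 1000)
  tr2 <- runif(5, 10, 1000)
  rec <- rbind(
    make_records(prot, sites, "CTRL", ctrl),
    make_records(prot, sites, "A", tr1),
    make_records(prot, sites, "B", tr2))
  fc <- compute_site_fold_changes(rec, "CTRL", c("A", "B"))
  for (i in 1:5) {
    expect_equal(fc$log2fc[fc$protein == prot[i] & fc$treatment == "A"],
                 log(tr1[i] / ctrl[i], base = 2))
    expect_equal(fc$log2fc[fc$protein == prot[i] & fc$treatment == "B"],
                 log(tr2[i] / ctrl[i], base = 2))
  }
})

test_that("replicates are averaged per condition before ratioing", {
  rec <- make_records(rep("AKT1", 4), rep("S473", 4),
                      c("CTRL", "CTRL", "BMP8", "BMP8"),
                      c(90, 110, 150, 250))
  fc <- compute_site_fold_changes(rec, "CTRL", "BMP8")
  expect_equal(fc$log2fc, log2(200 / 100))
})

test_that("fold-change edge cases: zero control, bad labels, empty table", {
  rec <- rbind(make_records("A1", "S1", c("CTRL", "T"), c(0, 10)),
               make_records("B1", "S2", c("CTRL", "T"), c(5, 10)))
  expect_message(fc <- compute_site_fold_changes(rec, "CTRL", "T"),
                 "zero control")
  expect_equal(fc$protein, "B1")
  expect_error(compute_site_fold_changes(rec, "CTRL", "NOPE"),
               "not present")
  expect_warning(
    out <- compute_site_fold_changes(rec[0, ], "CTRL", "T"), "empty")
  expect_equal(nrow(out), 0)
})

test_that("sign adjustment preserves, flips, and excludes", {
  fcs <- data.frame(protein = c("A1", "A1", "B1", "C1"),
                    site = c("S1", "S2", "S3", "S4"),
                    treatment = "T",
                    log2fc = c(1.68, 1.68, 2.3, -0.7))
  eff <- data.frame(protein = c("A1", "A1", "C1"),
                    site = c("S1", "S2", "S4"),
                    sign = c(1, -1, -1))
  expect_message(adj <- adjust_fold_change_signs(fcs, eff), "excluded")
  expect_equal(adj$adjusted_log2fc[adj$site == "S1"], 1.68)
  expect_equal(adj$adjusted_log2fc[adj$site == "S2"], -1.68)
  expect_equal(adj$adjusted_log2fc[adj$site == "S4"], 0.7)
  expect_false("S3" %in% adj$site)   # unannotated site treated as unknown
  expect_equal(attr(adj, "n_excluded"), 1L)
})

test_that("sign adjustment is an involution on randomized tables", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    fcs <- data.frame(protein = sprintf("P%02d", sample(1:15, n, TRUE)),
                      site = sprintf("S%d", seq_len(n)),
                      treatment = sample(c("A", "B"), n, TRUE),
                      log2fc = rnorm(n, 0, 1.5))
    eff <- data.frame(protein = fcs$protein, site = fcs$site,
                      sign = sample(c(1, -1, NA), n, TRUE))
    adj <- suppressMessages(adjust_fold_change_signs(fcs, eff))
    # |adjusted| == |raw| on every retained row
    expect_equal(abs(adj$adjusted_log2fc), abs(adj$log2fc))
    # flipping twice restores the raw value
    expect_equal(adj$adjusted_log2fc * adj$sign, adj$log2fc)
    # unknown rows excluded
    expect_equal(nrow(adj), sum(!is.na(eff$sign)))
  }
})

test_that("representative site maximizes |log2fc| per protein/treatment", {
  fcs <- data.frame(protein = "A1", site = c("S1", "S2", "S3"),
                    treatment = "T", log2fc = c(0.2, -1.5, 0.9))
  expect_equal(representative_site_per_protein(fcs)$site, "S2")

  one <- data.frame(protein = "B1", site = "S9", treatment = "T",
                    log2fc = 0.1)
  expect_equal(representative_site_per_protein(one)$site, "S9")

  # 50-protein random fixture vs brute-force scan
  set.seed(7)
  fcs <- do.call(rbind, lapply(sprintf("P%02d", 1:50), function(p) {
    k <- sample(1:4, 1)
    data.frame(protein = p, site = sprintf("S%d", seq_len(k)),
               treatment = rep(c("A", "B"), each = k),
               log2fc = rnorm(2 * k))
  }))
  rep_tab <- representative_site_per_protein(fcs)
  expect_equal(nrow(rep_tab),
               nrow(unique(fcs[, c("protein", "treatment")])))
  for (p in unique(fcs$protein)) {
    for (tr in c("A", "B")) {
      sub <- fcs[fcs$protein == p & fcs$treatment == tr, ]
      got <- rep_tab[rep_tab$protein == p & rep_tab$treatment == tr, ]
      expect_equal(abs(got$log2fc), max(abs(sub$log2fc)))
    }
  }
  expect_error(representative_site_per_protein(fcs[0, ]), "empty")
})

test_that("treatment response sets follow the 2x any-site rule", {
  fcs <- make_signed_table("A1", "BMP8", log2(2.5))
  v <- treatment_response_sets(fcs, 2)
  expect_equal(v$up, list(BMP8 = "A1"))
  expect_length(v$down, 0)

  fcs <- make_signed_table("B1", "NE", log2(0.4))  # below half
  v <- treatment_response_sets(fcs, 2)
  expect_equal(v$down, list(NE = "B1"))

  expect_error(treatment_response_sets(fcs, 1), "> 1")

  # all entries strictly inside (1/2, 2) -> empty sets
  set.seed(3)
  fcs <- make_signed_table(sprintf("P%d", 1:8), c("A", "B"),
                           runif(16, -0.99, 0.99))
  v <- treatment_response_sets(fcs, 2)
  expect_length(v$up, 0)
  expect_length(v$down, 0)
})

test_that("planted 12-protein fixture recovers exact Venn memberships", {
  set.seed(19)
  prots <- sprintf("P%02d", 1:12)
  treatments <- c("A", "B", "C")
  # plant a direction per protein/treatment: -1 down, 0 null, +1 up
  plant <- matrix(sample(c(-1, 0, 1), 36, TRUE), 12, 3,
                  dimnames = list(prots, treatments))
  rows <- list()
  for (p in prots) for (tr in treatments) {
    val <- plant[p, tr] * runif(1, 1.2, 2) +
      (plant[p, tr] == 0) * runif(1, -0.9, 0.9)
    rows[[length(rows) + 1]] <-
      data.frame(protein = p, site = "S1", treatment = tr, log2fc = val,
                 sign = 1, adjusted_log2fc = val)
  }
  fcs <- do.call(rbind, rows)
  v <- treatment_response_sets(fcs, 2)

  # enumeration oracle over all proteins x treatments
  for (dir in c("up", "down")) {
    want <- list()
    for (p in prots) {
      hits <- treatments[plant[p, ] == if (dir == "up") 1 else -1]
      if (length(hits) > 0) {
        fld <- paste(hits, collapse = "+")
        want[[fld]] <- sort(c(want[[fld]], p))
      }
    }
    expect_equal(v[[dir]], want[order(names(want))])
  }

  # per-treatment disjointness and partition property
  s <- summarize_venn(v)
  for (dir in c("up", "down")) {
    all_members <- unlist(v[[dir]], use.names = FALSE)
    expect_false(any(duplicated(all_members)))
    expect_equal(s[[dir]]$total, length(all_members))
  }
  for (tr in treatments) {
    up_tr <- unlist(v$up[grepl(tr, names(v$up))], use.names = FALSE)
    dn_tr <- unlist(v$down[grepl(tr, names(v$down))], use.names = FALSE)
    expect_length(intersect(up_tr, dn_tr), 0)
  }
})

test_that("summarize_venn tallies hand-built memberships", {
  fcs <- rbind(make_signed_table(c("A1", "B1"), "X", c(1.5, 1.2)),
               make_signed_table("C1", "Y", -1.4))
  v <- treatment_response_sets(fcs, 2)
  s <- summarize_venn(v)
  expect_equal(s$up$total, 2)
  expect_equal(s$up$fields$X, 2)
  expect_equal(s$down$total, 1)
  expect_equal(s$down$fields$Y, 1)
  empty <- treatment_response_sets(make_signed_table("A1", "X", 0), 2)
  se <- summarize_venn(empty)
  expect_equal(se$up$total + se$down$total, 0)
})
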