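#' Define a synthetic integration scenario
#'
#' Bundles every knob of the synthetic world: a directed signaling network
#' with a planted regulator wired just upstream of a target gene's TFs, a
#' phospho-antibody array readout with planted treatment responses, curated
#' effect signs with a configurable unknown fraction, TF regulons with
#' confidence grades, and an expression signature with planted active TFs.
#' Every generator is a deterministic function of (scenario, seed).
#'
#' Defaults describe a mid-size curated signaling network (200 nodes, 600
#' edges, heavy-tailed in-degree), an assay of 40 proteins with 1-4 sites
#' each, log2 background noise of 0.25 (modest antibody-array noise), 20%
#' of sites without curated effect signs, 25-target regulons and planted
#' activity shifts of 1 signature-SD.
#'
#' @param seed integer master seed; sub-streams are derived from it.
#' @param n_nodes,n_edges network size.
#' @param n_tfs number of TF nodes.
#' @param n_target_tfs how many TFs regulate the target gene.
#' @param planted_hops 1 (direct regulator->TF edges) or 2 (via one
#'   intermediate).
#' @param n_assay_proteins proteins on the synthetic array.
#' @param n_genes expression-signature gene universe size.
#' @param regulon_size targets per TF.
#' @param n_planted_active_tfs TFs with planted activity in the signature.
#' @param active_effect planted shift in signature-SD units per target.
#' @param noise_sd background log2 fold-change s.d. on the array.
#' @param fraction_unknown fraction of sites with unknown effect sign.
#' @param treatments treatment labels (control is always "CTRL").
#' @param graph_model "pa" (preferential attachment, default) or "er"
#'   (Erdos-Renyi).
#' @param tfs_on_assay if TRUE, the target gene's TFs are also placed on the
#'   antibody panel with planted responses under the first treatment (needed
#'   by fixtures exercising the TF-phosphorylation filter); by default the
#'   panel holds signaling proteins only.
#' @param plant_responses if FALSE no treatment responses are planted at all
#'   (pure-noise array; with `noise_sd = 0` every fold change is exactly 1).
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 1, n_nodes = 200, n_edges = 600,
                               n_tfs = 15, n_target_tfs = 3,
                               planted_hops = 1, n_assay_proteins = 40,
                               n_genes = 300, regulon_size = 25,
                               n_planted_active_tfs = 2, active_effect = 1,
                               noise_sd = 0.25, fraction_unknown = 0.2,
                               treatments = c("BMP8", "NE", "BMP8_NE"),
                               graph_model = c("pa", "er"),
                               tfs_on_assay = FALSE,
                               plant_responses = TRUE) {
  graph_model <- match.arg(graph_model)
  stopifnot(n_nodes > n_tfs + 2, n_edges >= n_nodes - 1,
            n_target_tfs <= n_tfs, planted_hops %in% c(1, 2),
            n_assay_proteins <= n_nodes, fraction_unknown >= 0,
            fraction_unknown <= 1, noise_sd >= 0)
  sc <- list(seed = as.integer(seed), n_nodes = n_nodes, n_edges = n_edges,
             n_tfs = n_tfs, n_target_tfs = n_target_tfs,
             planted_hops = planted_hops,
             n_assay_proteins = n_assay_proteins, n_genes = n_genes,
             regulon_size = regulon_size,
             n_planted_active_tfs = n_planted_active_tfs,
             active_effect = active_effect, noise_sd = noise_sd,
             fraction_unknown = fraction_unknown, treatments = treatments,
             graph_model = graph_model, tfs_on_assay = tfs_on_assay,
             plant_responses = plant_responses,
             target_gene = "TGENE", planted_regulator = "KREG",
             tf_names = sprintf("TF%02d", seq_len(n_tfs)))
  sc$target_tfs <- sc$tf_names[seq_len(n_target_tfs)]
  class(sc) <- "synthetic_scenario"
  sc
}

#' Simulate the directed signaling network with a planted regulator
#'
#' Wires `n_edges` directed edges over named nodes, by preferential
#' attachment on in-degree by default, and plants the regulator
#' `planted_hops` upstream of the target gene's TFs. The planted regulator
#' emits only its planted edges, so its walk mass is not diluted.
#'
#' @param scenario a `synthetic_scenario`.
#' @return list: `network` (a `signaling_network`), `edges` (data.frame) and
#'   `truth` (planted regulator, target TFs, planted paths).
#' @export
simulate_signaling_network <- function(scenario) {
  sc <- scenario
  set.seed(derive_seed(sc$seed, 1L))
  n_other <- sc$n_nodes - sc$n_tfs - 1L
  others <- sprintf("PRT%03d", seq_len(n_other))
  nodes <- c(sc$planted_regulator, others, sc$tf_names)

  planted <- if (sc$planted_hops == 1) {
    data.frame(source = sc$planted_regulator, target = sc$target_tfs)
  } else {
    mid <- others[1]
    rbind(data.frame(source = sc$planted_regulator, target = mid),
          data.frame(source = mid, target = sc$target_tfs))
  }
  n_random <- sc$n_edges - nrow(planted)
  if (n_random < 0) stop("n_edges too small for the planted wiring")

  # random sources exclude the planted regulator; targets by preferential
  # attachment on in-degree (or uniform under the ER model)
  src_pool <- setdiff(nodes, sc$planted_regulator)
  indeg <- stats::setNames(rep(1, length(nodes)), nodes)
  seen <- paste(planted$source, planted$target, sep = "\r")
  src <- character(n_random); tgt <- character(n_random)
  k <- 0L
  while (k < n_random) {
    s <- sample(src_pool, 1)
    w <- if (sc$graph_model == "pa") indeg else rep(1, length(nodes))
    t <- sample(nodes, 1, prob = w)
    key <- paste(s, t, sep = "\r")
    if (s == t || key %in% seen) next
    k <- k + 1L
    src[k] <- s; tgt[k] <- t
    seen <- c(seen, key)
    indeg[t] <- indeg[t] + 1
  }
  edges <- rbind(planted, data.frame(source = src, target = tgt))
  edges <- edges[order_lex(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  net <- suppressMessages(build_signaling_network(edges, nodes = nodes))
  list(network = net, edges = edges,
       truth = list(planted_regulator = sc$planted_regulator,
                    target_gene = sc$target_gene,
                    target_tfs = sc$target_tfs,
                    planted_edges = planted))
}

#' Simulate the phospho-antibody array with planted responses
#'
#' Generates per-condition signals for 1-4 sites per assay protein. Planted
#' (protein, treatment) responses get one site with sign-adjusted log2 fold
#' change drawn uniformly in (1.1, 2.2) (up) or its negative (down) —
#' comfortably past the 2x rule — with a known effect sign; background sites
#' get Normal(0, noise_sd) log2 changes and a sign that is unknown with
#' probability `fraction_unknown`. The planted-pathway proteins are on the
#' assay and respond to the first treatment; the target gene's TFs join the
#' panel (also responding) only when the scenario sets `tfs_on_assay`.
#'
#' @param scenario a `synthetic_scenario`.
#' @param network output of [simulate_signaling_network()].
#' @return list: `records` (signal table), `effects`, `kinases`, and
#'   `truth` (planted memberships per direction/treatment, assay proteins,
#'   altered proteins per the 1.5x rule, and the true per-site table).
#' @export
simulate_phosphoassay <- function(scenario, network) {
  sc <- scenario
  set.seed(derive_seed(sc$seed, 2L))
  nodes <- network$network$nodes
  # planted-pathway proteins respond to the first treatment; the antibody
  # panel holds signaling proteins (the TFs only when tfs_on_assay is set)
  core <- sc$planted_regulator
  if (sc$planted_hops == 2) {
    core <- c(core, network$truth$planted_edges$target[1])
  }
  if (sc$tfs_on_assay) core <- c(core, sc$target_tfs)
  pool <- setdiff(nodes, c(core, sc$tf_names))
  assay <- sort(c(core, sample(pool, sc$n_assay_proteins - length(core))))

  # planted response plan: core proteins go up under the first treatment;
  # a few additional proteins are planted up/down under each treatment
  plan <- data.frame(protein = core, treatment = sc$treatments[1],
                     direction = "up")
  extra_pool <- setdiff(assay, core)
  for (tr in sc$treatments) {
    ups <- sample(extra_pool, 3)
    downs <- sample(setdiff(extra_pool, ups), 2)
    plan <- rbind(plan,
                  data.frame(protein = ups, treatment = tr,
                             direction = "up"),
                  data.frame(protein = downs, treatment = tr,
                             direction = "down"))
  }
  plan <- plan[!duplicated(paste(plan$protein, plan$treatment)), ]
  if (!sc$plant_responses) plan <- plan[0, , drop = FALSE]

  sites_per <- stats::setNames(sample(1:4, length(assay), replace = TRUE),
                               assay)
  rows <- list(); effect_rows <- list()
  for (pr in assay) {
    n_sites <- sites_per[pr]
    sites <- paste0(sample(c("S", "T", "Y"), n_sites, replace = TRUE),
                    sort(sample(20:999, n_sites)))
    planted_here <- plan[plan$protein == pr, , drop = FALSE]
    for (j in seq_len(n_sites)) {
      site <- sites[j]
      # site 1 carries the planted signal: an activating site whose raw
      # phosphorylation goes up (planted "up") or down (planted "down");
      # the unknown-sign fraction applies to planted and background alike
      is_planted_site <- j == 1 && nrow(planted_here) > 0
      unknown <- stats::runif(1) < sc$fraction_unknown
      sgn <- if (unknown) NA_real_ else if (is_planted_site) 1 else
        sample(c(-1, 1), 1)
      raw <- stats::rnorm(length(sc$treatments), 0, sc$noise_sd)
      names(raw) <- sc$treatments
      if (is_planted_site) {
        mag <- stats::runif(nrow(planted_here), 1.1, 2.2)
        raw[planted_here$treatment] <-
          ifelse(planted_here$direction == "up", mag, -mag)
      }
      base <- 1000 * 2^stats::rnorm(1, 0, 0.5)
      rows[[length(rows) + 1]] <- data.frame(
        protein = pr, site = site,
        condition = c("CTRL", sc$treatments),
        signal = base * 2^c(0, raw))
      n_partners <- sample(0:3, 1)
      partners <- if (n_partners > 0) {
        data.frame(partner = sample(nodes, n_partners),
                   label = sample(c("induce", "disrupt"), n_partners,
                                  replace = TRUE))
      } else {
        data.frame(partner = character(), label = character())
      }
      er <- data.frame(protein = pr, site = site, sign = sgn)
      er$partners <- list(partners)
      effect_rows[[length(effect_rows) + 1]] <- er
    }
  }
  records <- do.call(rbind, rows)
  effects <- do.call(rbind, effect_rows)

  # kinase annotations: 0-4 kinases per site from the network nodes
  kin_rows <- lapply(seq_len(nrow(effects)), function(i) {
    nk <- sample(0:4, 1)
    if (nk == 0) return(NULL)
    data.frame(protein = effects$protein[i], site = effects$site[i],
               kinase = sample(nodes, nk),
               source = sample(c("dbPTM", "HPRD", "PELM", "PSP", "SIGNOR"),
                               nk, replace = TRUE))
  })
  kinases <- do.call(rbind, kin_rows)

  # exact ground truth by direct enumeration of the generated table
  fcs <- compute_site_fold_changes(records, "CTRL", sc$treatments)
  signed <- suppressMessages(adjust_fold_change_signs(fcs, effects))
  truth_venn <- enumerate_venn_truth(signed, 2)
  altered <- sort(unique(fcs$protein[fcs$treatment == sc$treatments[1] &
                                       2^fcs$log2fc > 1.5]))
  list(records = records, effects = effects, kinases = kinases,
       truth = list(assay_proteins = assay, plan = plan,
                    venn = truth_venn, altered_proteins = altered))
}

# independent brute-force enumeration of Venn memberships (generator-side
# truth; intentionally naive loops, no shared code with
# treatment_response_sets beyond the rule statement)
enumerate_venn_truth <- function(signed, ratio_threshold) {
  cut <- log2(ratio_threshold)
  out <- list(up = list(), down = list())
  for (pr in sort(unique(signed$protein))) {
    for (dir in c("up", "down")) {
      hits <- character()
      for (tr in sort(unique(signed$treatment))) {
        v <- signed$adjusted_log2fc[signed$protein == pr &
                                      signed$treatment == tr]
        if (length(v) == 0) next
        up_any <- any(v >= cut); dn_any <- any(v <= -cut)
        if (up_any && dn_any) {       # dominant site decides, ties up
          if ((v[which.max(abs(v))] >= 0) == (dir == "up")) {
            hits <- c(hits, tr)
          }
        } else if ((dir == "up" && up_any) || (dir == "down" && dn_any)) {
          hits <- c(hits, tr)
        }
      }
      if (length(hits) > 0) {
        fld <- paste(sort(hits), collapse = "+")
        out[[dir]][[fld]] <- sort(c(out[[dir]][[fld]], pr))
      }
    }
  }
  if (length(out$up) > 0) out$up <- out$up[order(names(out$up))]
  if (length(out$down) > 0) out$down <- out$down[order(names(out$down))]
  out
}

#' Simulate TF regulons with modes and confidence grades
#'
#' Random TF-to-target assignment over the signature gene universe; the
#' target gene is added to the regulons of its designated TFs with grades
#' within the default confidence filter (A-D).
#'
#' @param scenario a `synthetic_scenario`.
#' @return list: `table` (unfiltered `tf target mode confidence` rows) and
#'   `truth` (per-TF planted content).
#' @export
simulate_regulons <- function(scenario) {
  sc <- scenario
  set.seed(derive_seed(sc$seed, 3L))
  genes <- sprintf("G%03d", seq_len(sc$n_genes))
  rows <- lapply(sc$tf_names, function(tf) {
    tg <- sample(genes, sc$regulon_size)
    data.frame(tf = tf, target = tg,
               mode = sample(c(1, -1), sc$regulon_size, replace = TRUE,
                             prob = c(0.7, 0.3)),
               confidence = sample(.grade_levels, sc$regulon_size,
                                   replace = TRUE,
                                   prob = c(0.15, 0.25, 0.25, 0.25, 0.1)))
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(
    tf = sc$target_tfs, target = sc$target_gene, mode = 1,
    confidence = sample(c("A", "B", "C", "D"), length(sc$target_tfs),
                        replace = TRUE)))
  tab <- tab[order_lex(tab$tf, tab$target), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       truth = list(target_gene_tfs = sc$target_tfs,
                    gene_universe = genes))
}

#' Simulate an expression signature with planted active TFs
#'
#' Background log2 fold changes are standard normal; each planted active
#' TF shifts its (confidence-filtered) targets by `active_effect` times the
#' target's mode of regulation.
#'
#' @param scenario a `synthetic_scenario`.
#' @param regulons filtered regulon table (see [build_regulons()]); planted
#'   shifts follow exactly the regulon the estimator will see.
#' @param active_tfs which TFs are planted active; defaults to the first
#'   `n_planted_active_tfs` TFs regulating the target gene.
#' @return list: `signature` (named numeric) and `truth` (active TFs and
#'   effect size).
#' @export
simulate_expression_signature <- function(scenario, regulons,
                                          active_tfs = NULL) {
  sc <- scenario
  set.seed(derive_seed(sc$seed, 4L))
  if (is.null(active_tfs)) {
    active_tfs <- utils::head(sc$target_tfs, sc$n_planted_active_tfs)
  }
  genes <- c(sprintf("G%03d", seq_len(sc$n_genes)), sc$target_gene)
  sig <- stats::rnorm(length(genes))
  names(sig) <- genes
  for (tf in active_tfs) {
    sub <- regulons[regulons$tf == tf & regulons$target %in% genes, ]
    sig[sub$target] <- sig[sub$target] + sc$active_effect * sub$mode
  }
  list(signature = sig,
       truth = list(active_tfs = active_tfs,
                    active_effect = sc$active_effect))
}

#' Simulate functional-category gene sets
#'
#' Five categories (A, I, L, N, C) drawn from the network node symbols; the
#' planted regulator and target TFs are guaranteed members of category A so
#' downstream annotation has signal.
#'
#' @param scenario a `synthetic_scenario`.
#' @param network output of [simulate_signaling_network()].
#' @return named list of gene-symbol sets.
#' @export
simulate_categories <- function(scenario, network) {
  sc <- scenario
  set.seed(derive_seed(sc$seed, 5L))
  nodes <- network$network$nodes
  sets <- lapply(c(A = 1, I = 2, L = 3, N = 4, C = 5), function(i) {
    sort(sample(nodes, 30))
  })
  sets$A <- sort(unique(c(sets$A, sc$planted_regulator, sc$target_tfs)))
  sets
}

#' Generate and write every pipeline input plus ground truth
#'
#' Writes phospho signals, effect annotations, kinase table, network SIF,
#' regulon table, expression signature, category GMT, seed/TF symbol lists
#' and a `truth.json` with all planted ground truth to `dir`.
#'
#' @param scenario a `synthetic_scenario`.
#' @param dir output directory (created if absent).
#' @return invisibly, the in-memory bundle of all generated objects.
#' @export
simulate_all <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  netsim <- simulate_signaling_network(scenario)
  assay <- simulate_phosphoassay(scenario, netsim)
  regsim <- simulate_regulons(scenario)
  regs <- build_regulons(regsim$table)
  sigsim <- simulate_expression_signature(scenario, regs)
  cats <- simulate_categories(scenario, netsim)

  write_tsv(assay$records, file.path(dir, "phospho_signals.tsv"))
  write_effects(assay$effects, file.path(dir, "effects.tsv"))
  write_tsv(assay$kinases, file.path(dir, "kinases.tsv"))
  write_sif(netsim$edges, file.path(dir, "network.sif"))
  write_tsv(regsim$table, file.path(dir, "regulons.tsv"))
  write_signature(sigsim$signature, file.path(dir, "signature.tsv"))
  write_gmt(cats, file.path(dir, "categories.gmt"))
  writeLines(assay$truth$assay_proteins, file.path(dir, "seeds.txt"))
  writeLines(scenario$tf_names, file.path(dir, "tfs.txt"))

  truth <- c(netsim$truth, assay$truth[c("venn", "altered_proteins",
                                         "assay_proteins")],
             regsim$truth, sigsim$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(scenario = scenario, network = netsim, assay = assay,
                 regulons = regsim, signature = sigsim, categories = cats,
                 truth = truth))
}
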