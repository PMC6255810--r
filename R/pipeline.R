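#' Assemble a pipeline configuration
#'
#' Collects the input paths, walk parameters, thresholds and flags of a full
#' integration run. Thresholds default to the canonical analysis values:
#' 2x Venn rule, 1.5x phospho-alteration rule, p < 0.2 TF display cut,
#' top 30 proteins per gene, top 50 heatmap sites, walk r = 0.5 with 15
#' iterations, regulon confidence up to D.
#'
#' @param phospho,effects,kinases,network,regulons,signature,categories
#'   input file paths (formats per the `read_*` functions).
#' @param seeds,tfs paths to plain-text symbol lists: assay proteins used as
#'   walk seeds, and the TF universe.
#' @param genes_of_interest genes to rank proteins against.
#' @param control_label control condition label in the phospho table.
#' @param treatments treatment labels; inferred from the table if NULL.
#' @param primary_treatment treatment used for the 1.5x alteration rule and
#'   attached fold changes; defaults to the first treatment.
#' @param r,iterations walk parameters.
#' @param venn_ratio,phospho_fold,p_cut,top_k,top_sites thresholds.
#' @param max_confidence worst regulon grade retained.
#' @param aggregate gene-distance aggregation, "min" or "mean".
#' @param alternative Mann-Whitney sidedness, "less" or "two.sided".
#' @param out_dir output directory.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(phospho, effects, kinases, network, regulons,
                            signature, categories, seeds, tfs,
                            genes_of_interest,
                            control_label = "CTRL", treatments = NULL,
                            primary_treatment = NULL,
                            r = 0.5, iterations = 15,
                            venn_ratio = 2, phospho_fold = 1.5,
                            p_cut = 0.2, top_k = 30, top_sites = 50,
                            max_confidence = "D",
                            aggregate = "min", alternative = "less",
                            out_dir = "results", seed = 1) {
  stopifnot(venn_ratio > 1, phospho_fold > 0, p_cut > 0, top_k > 0,
            top_sites > 0)
  cfg <- as.list(environment())
  paths <- c(phospho, effects, kinases, network, regulons, signature,
             categories, seeds, tfs)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full integration pipeline
#'
#' Executes phospho processing, annotation layers, network proximity, TF
#' activity estimation and the integration/selection rules, writing all
#' declared outputs plus a run manifest to `config$out_dir`.
#'
#' Outputs: `venn.json`, `layer_matrix.tsv`, `layer_tree.nwk`,
#' `proximity.tsv`, `distance.tsv`, `ranking_<gene>.tsv`,
#' `tf_activity.tsv`, `tf_selection_<gene>.json`, `mw_test.json`,
#' `manifest.json`.
#'
#' @param config a `pipeline_config`.
#' @return invisibly, the in-memory result bundle.
#' @export
run_all <- function(config) {
  cfg <- config
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  outp <- function(f) file.path(cfg$out_dir, f)

  records <- run_stage("read_phospho", read_phospho_signals(cfg$phospho))
  treatments <- cfg$treatments
  if (is.null(treatments)) {
    treatments <- sort(setdiff(unique(records$condition),
                               cfg$control_label))
  }
  primary <- if (is.null(cfg$primary_treatment)) treatments[1] else
    cfg$primary_treatment

  effects <- run_stage("read_effects", read_effects(cfg$effects))
  kinases <- run_stage("read_kinases", read_kinase_table(cfg$kinases))
  cats <- run_stage("read_categories", read_gmt(cfg$categories))
  seeds <- run_stage("read_seeds", normalize_symbols(readLines(cfg$seeds)))
  tf_universe <- run_stage("read_tfs",
                           normalize_symbols(readLines(cfg$tfs)))

  # --- phospho processing
  fcs <- run_stage("fold_changes",
                   compute_site_fold_changes(records, cfg$control_label,
                                             treatments))
  signed <- run_stage("sign_adjustment",
                      suppressMessages(adjust_fold_change_signs(fcs,
                                                                effects)))
  venn <- run_stage("venn", treatment_response_sets(signed,
                                                    cfg$venn_ratio))
  write_venn_json(venn, outp("venn.json"))

  # --- annotation layers on the top sites
  top <- run_stage("top_sites", top_phosphosites(signed, cfg$top_sites))
  layers <- run_stage("layers",
                      annotate_functional_layers(top, cats, kinases,
                                                 effects))
  lt <- run_stage("clustering", cluster_rows(layers))
  write_tsv(data.frame(row = rownames(layers), as.data.frame(layers),
                       check.names = FALSE),
            outp("layer_matrix.tsv"))
  writeLines(lt$newick, outp("layer_tree.nwk"))

  # --- network proximity
  net <- run_stage("network",
                   suppressWarnings(suppressMessages(
                     build_signaling_network(read_sif(cfg$network)))))
  regs <- run_stage("regulons",
                    build_regulons(read_regulon_table(cfg$regulons),
                                   cfg$max_confidence))
  prox <- run_stage("proximity",
                    suppressWarnings(
                      proximity_matrix(net, seeds,
                                       intersect(tf_universe, net$nodes),
                                       r = cfg$r,
                                       iterations = cfg$iterations)))
  write_tsv(data.frame(seed = rownames(prox$probability),
                       as.data.frame(prox$probability),
                       check.names = FALSE), outp("proximity.tsv"))
  write_tsv(data.frame(seed = rownames(prox$distance),
                       as.data.frame(prox$distance),
                       check.names = FALSE), outp("distance.tsv"))

  fcs_primary <- fcs[fcs$treatment == primary, , drop = FALSE]
  rankings <- list()
  for (g in cfg$genes_of_interest) {
    rk <- run_stage(paste0("ranking_", g),
                    rank_proteins_by_gene_proximity(
                      g, prox, regs, k = cfg$top_k, fcs = fcs_primary))
    rankings[[g]] <- rk
    write_tsv(rk, outp(paste0("ranking_", g, ".tsv")))
  }

  mw <- run_stage("mann_whitney",
                  compare_altered_vs_unaltered_distances(
                    prox, fcs_primary, fold_threshold = cfg$phospho_fold,
                    alternative = cfg$alternative))
  jsonlite::write_json(mw, outp("mw_test.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  # --- TF activity and integration
  signature <- run_stage("read_signature", read_signature(cfg$signature))
  acts <- run_stage("tf_activity",
                    suppressMessages(estimate_tf_activities(signature,
                                                            regs)))
  write_tsv(acts, outp("tf_activity.tsv"))
  selections <- list()
  for (g in cfg$genes_of_interest) {
    sel <- run_stage(paste0("tf_selection_", g),
                     select_gene_tfs(g, acts, regs, p_cut = cfg$p_cut))
    phos_up <- run_stage(paste0("tf_phospho_", g),
                         tfs_with_phospho_increase(
                           g, regs, fcs, treatment = primary,
                           fold_threshold = cfg$phospho_fold))
    selections[[g]] <- list(selected = sel,
                            phospho_increased = phos_up,
                            intersection = intersect(sel$tf, phos_up))
    jsonlite::write_json(selections[[g]],
                         outp(paste0("tf_selection_", g, ".json")),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  manifest <- list(
    package = "phosphowalk",
    version = as.character(utils::packageVersion("phosphowalk")),
    seed = cfg$seed,
    parameters = cfg[c("control_label", "primary_treatment", "r",
                       "iterations", "venn_ratio", "phospho_fold", "p_cut",
                       "top_k", "top_sites", "max_confidence", "aggregate",
                       "alternative")],
    treatments = treatments, primary_treatment = primary,
    inputs = cfg[c("phospho", "effects", "kinases", "network", "regulons",
                   "signature", "categories", "seeds", "tfs")],
    genes_of_interest = cfg$genes_of_interest)
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(fold_changes = fcs, signed = signed, venn = venn,
                 top_sites = top, layers = layers, clustering = lt,
                 network = net, regulons = regs, proximity = prox,
                 rankings = rankings, mw = mw, activities = acts,
                 selections = selections, manifest = manifest))
}
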