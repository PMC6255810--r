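#' Normalize expression values to housekeeping genes
#'
#' Divides every gene's value in each sample by the geometric mean of the
#' housekeeping genes' values in that sample (the usual qPCR reference-gene
#' normalization; the canonical panel has four housekeepers).
#'
#' @param raw numeric matrix or data.frame, genes x samples, rownames are
#'   gene symbols.
#' @param housekeepers character vector of housekeeping gene symbols, all of
#'   which must be present with strictly positive values.
#' @return matrix of the same shape, normalized per sample.
#' @export
normalize_expression <- function(raw, housekeepers) {
  raw <- as.matrix(raw)
  rownames(raw) <- normalize_symbols(rownames(raw))
  housekeepers <- normalize_symbols(housekeepers)
  missing <- setdiff(housekeepers, rownames(raw))
  if (length(missing) > 0) {
    stop("housekeeping gene(s) missing: ", paste(missing, collapse = ", "))
  }
  hk <- raw[housekeepers, , drop = FALSE]
  if (any(hk <= 0)) stop("nonpositive housekeeper value")
  divisor <- exp(colMeans(log(hk)))
  sweep(raw, 2, divisor, "/")
}

#' Filter and merge transcription-factor regulons by confidence grade
#'
#' Keeps TF-target rows whose curation confidence is at least
#' `max_confidence` (grades run A best to E worst; the default keeps grades
#' up to D). Duplicate (TF, target) rows are merged keeping the best grade.
#' The operation is idempotent.
#'
#' @param tf_target_table data.frame with columns `tf`, `target`, `mode`
#'   (+1/-1) and `confidence` (single letters A-E).
#' @param max_confidence worst grade retained (default "D").
#' @return filtered, deduplicated regulon data.frame sorted by (tf, target).
#' @export
build_regulons <- function(tf_target_table, max_confidence = "D") {
  stopifnot(all(c("tf", "target", "mode", "confidence") %in%
                  names(tf_target_table)))
  assert_grades(tf_target_table$confidence)
  assert_grades(max_confidence)
  d <- tf_target_table
  d$tf <- normalize_symbols(d$tf)
  d$target <- normalize_symbols(d$target)
  if (!all(d$mode %in% c(-1, 1))) stop("mode must be +1 or -1")
  keep <- match(d$confidence, .grade_levels) <=
    match(max_confidence, .grade_levels)
  d <- d[keep, , drop = FALSE]
  # best (lowest-index) grade wins on duplicates
  d <- d[order_lex(d$tf, d$target, match(d$confidence, .grade_levels)), ,
         drop = FALSE]
  d <- d[!duplicated(paste(d$tf, d$target, sep = "\r")), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Estimate transcription-factor activities from an expression signature
#'
#' Analytic rank enrichment: the signature is rank-transformed to scores
#' q_g = qnorm(rank_g / (G + 1)), symmetric about zero; a TF's normalized
#' enrichment score is sum(mode_g * q_g) / sqrt(n) over its targets present
#' in the signature, and the two-sided p-value is the standard normal tail.
#' Positive NES means the TF's activating targets sit high in the signature
#' (up-regulated TF); negative means down-regulated.
#'
#' @param signature named numeric vector, gene -> log2 fold change (or any
#'   per-gene statistic; only ranks are used).
#' @param regulons regulon table from [build_regulons()].
#' @param min_targets regulons with fewer targets present in the signature
#'   are skipped with a message (default 3).
#' @return data.frame `tf`, `nes`, `p`, `n_targets`, sorted by tf.
#' @export
estimate_tf_activities <- function(signature, regulons, min_targets = 3) {
  if (length(signature) == 0) stop("empty expression signature")
  names(signature) <- normalize_symbols(names(signature))
  if (any(duplicated(names(signature)))) stop("duplicate gene symbols")
  if (any(!is.finite(signature))) stop("non-finite signature values")
  G <- length(signature)
  q <- stats::qnorm(rank(signature, ties.method = "average") / (G + 1))
  names(q) <- names(signature)

  tfs <- sort(unique(regulons$tf))
  rows <- lapply(tfs, function(tf) {
    sub <- regulons[regulons$tf == tf, ]
    present <- sub$target %in% names(q)
    n <- sum(present)
    if (n < min_targets) {
      message("regulon ", tf, " skipped: only ", n,
              " target(s) in signature")
      return(NULL)
    }
    nes <- sum(sub$mode[present] * q[sub$target[present]]) / sqrt(n)
    data.frame(tf = tf, nes = nes, p = 2 * stats::pnorm(-abs(nes)),
               n_targets = n)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf = character(), nes = numeric(), p = numeric(),
                      n_targets = integer())
  }
  rownames(out) <- NULL
  out
}

#' Select a gene's transcription factors by activity p-value
#'
#' Restricts the activity table to TFs whose regulon contains the gene,
#' keeps those with p below the cut (no multiple-testing correction, a
#' display rule), and orders ascending by p.
#'
#' @param gene gene symbol.
#' @param activities output of [estimate_tf_activities()].
#' @param regulons regulon table.
#' @param p_cut p-value cutoff (default 0.2).
#' @return subset of `activities`, sorted by p then tf; zero rows (with a
#'   warning) if the gene is absent from all regulons.
#' @export
select_gene_tfs <- function(gene, activities, regulons, p_cut = 0.2) {
  tfs <- gene_tfs(gene, regulons)
  if (length(tfs) == 0) {
    warning("gene ", gene, " absent from all regulons")
    return(activities[0, , drop = FALSE])
  }
  out <- activities[activities$tf %in% tfs & activities$p < p_cut, ,
                    drop = FALSE]
  out <- out[order_lex(out$p, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcription factors of a gene with increased phosphorylation
#'
#' Returns the TFs that regulate the gene and whose best phosphosite fold
#' change under the named treatment exceeds `fold_threshold` on the ratio
#' scale (e.g. 1.5 means +50% phosphorylation).
#'
#' @param gene gene symbol.
#' @param regulons regulon table.
#' @param fcs fold-change table with `log2fc` (log2 of treated/control).
#' @param treatment optional treatment label to restrict `fcs`.
#' @param fold_threshold ratio cutoff (default 1.5).
#' @return sorted character vector of TF symbols.
#' @export
tfs_with_phospho_increase <- function(gene, regulons, fcs, treatment = NULL,
                                      fold_threshold = 1.5) {
  tfs <- gene_tfs(gene, regulons)
  if (!is.null(treatment)) fcs <- fcs[fcs$treatment == treatment, ]
  fcs <- fcs[fcs$protein %in% tfs, , drop = FALSE]
  if (nrow(fcs) == 0) return(character())
  best <- tapply(fcs$log2fc, fcs$protein, max)
  sort(names(best)[2^best > fold_threshold])
}
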