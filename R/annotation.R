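#' Look up the potential kinases of a phosphosite
#'
#' Returns the union over all configured kinase-substrate sources of the
#' kinases annotated for the given site.
#'
#' @param protein,site substrate gene symbol and residue position.
#' @param kinase_table data.frame with columns `protein`, `site`, `kinase`
#'   and optionally `source`.
#' @param sources optional character vector restricting which sources are
#'   used; default all.
#' @return sorted character vector of kinase gene symbols (empty if the site
#'   is unannotated).
#' @export
lookup_kinases <- function(protein, site, kinase_table, sources = NULL) {
  protein <- normalize_symbols(protein)
  hit <- kinase_table$protein == protein & kinase_table$site == site
  if (!is.null(sources) && "source" %in% names(kinase_table)) {
    hit <- hit & kinase_table$source %in% sources
  }
  sort(unique(normalize_symbols(kinase_table$kinase[hit])))
}

#' Look up the interaction partners regulated by a phosphosite
#'
#' The regulatory-sites annotation records, for some phosphosites, which
#' protein-protein interactions the phosphorylation is known to induce or
#' disrupt.
#'
#' @param protein,site substrate gene symbol and residue position.
#' @param effects effect annotation table (see [read_effects()]); its
#'   `partners` list-column holds per-site data.frames with columns
#'   `partner`, `label`.
#' @return data.frame with columns `partner`, `label` (label is "induce" or
#'   "disrupt"); zero rows if the site has no regulated partners.
#' @export
lookup_regulated_partners <- function(protein, site, effects) {
  protein <- normalize_symbols(protein)
  empty <- data.frame(partner = character(), label = character())
  if (!"partners" %in% names(effects)) return(empty)
  i <- which(effects$protein == protein & effects$site == site)
  if (length(i) == 0) return(empty)
  p <- effects$partners[[i[1]]]
  if (is.null(p) || nrow(p) == 0) return(empty)
  p <- unique(p)
  p[order_lex(p$partner, p$label), , drop = FALSE]
}

#' Layered functional annotation matrix
#'
#' For each phosphosite row and each functional category, computes three
#' values: whether the substrate itself belongs to the category ("self",
#' binary), the proportion of its annotated kinases in the category
#' ("kinases"), and the proportion of its regulated interaction partners in
#' the category ("regulated"). Proportions use the row's own kinase (resp.
#' partner) set as denominator and are 0 when that set is empty.
#'
#' @param rows data.frame with columns `protein`, `site` (the phosphosites to
#'   annotate, e.g. from [top_phosphosites()]).
#' @param categories named list of gene-symbol sets; names are the category
#'   codes (e.g. A, I, L, N, C). See [read_gmt()].
#' @param kinase_table kinase-substrate table (see [lookup_kinases()]).
#' @param effects effect annotation table (see
#'   [lookup_regulated_partners()]).
#' @return numeric matrix, one row per phosphosite (rownames
#'   `PROTEIN_site`), columns `<code>.self`, `<code>.kinases`,
#'   `<code>.regulated` for each category code.
#' @export
annotate_functional_layers <- function(rows, categories, kinase_table, effects) {
  if (length(categories) == 0) stop("no functional categories supplied")
  if (any(vapply(categories, length, 0L) == 0)) {
    stop("empty category gene set")
  }
  categories <- lapply(categories, normalize_symbols)
  codes <- names(categories)
  layers <- c("self", "kinases", "regulated")
  m <- matrix(0, nrow = nrow(rows),
              ncol = length(codes) * length(layers),
              dimnames = list(paste(rows$protein, rows$site, sep = "_"),
                              as.vector(t(outer(codes, layers, paste,
                                                sep = ".")))))
  prop_in <- function(set, genes) {
    if (length(set) == 0) return(0)
    mean(set %in% genes)
  }
  for (i in seq_len(nrow(rows))) {
    kin <- lookup_kinases(rows$protein[i], rows$site[i], kinase_table)
    par <- unique(lookup_regulated_partners(rows$protein[i], rows$site[i],
                                            effects)$partner)
    for (cc in codes) {
      gs <- categories[[cc]]
      m[i, paste0(cc, ".self")] <-
        as.numeric(normalize_symbols(rows$protein[i]) %in% gs)
      m[i, paste0(cc, ".kinases")] <- prop_in(kin, gs)
      m[i, paste0(cc, ".regulated")] <- prop_in(normalize_symbols(par), gs)
    }
  }
  m
}

#' Top phosphosites by sign-adjusted fold-change magnitude
#'
#' Ranks phosphosites by the maximum of `|adjusted_log2fc|` across
#' treatments and keeps the top `n` (the rows of the annotation heatmap).
#' Ties break lexicographically by (protein, site).
#'
#' @param fcs sign-adjusted fold-change table.
#' @param n number of sites to keep (default 50).
#' @return data.frame with columns `protein`, `site`, `score`.
#' @export
top_phosphosites <- function(fcs, n = 50) {
  stopifnot("adjusted_log2fc" %in% names(fcs))
  key <- paste(fcs$protein, fcs$site, sep = "\r")
  score <- tapply(abs(fcs$adjusted_log2fc), key, max)
  first <- !duplicated(key)
  d <- data.frame(protein = fcs$protein[first], site = fcs$site[first],
                  score = as.numeric(score[key[first]]))
  d <- d[order_lex(-d$score, d$protein, d$site), , drop = FALSE]
  d <- utils::head(d, n)
  rownames(d) <- NULL
  d
}

#' Hierarchical clustering of annotation/fold-change rows
#'
#' Agglomerative clustering with Euclidean distance and complete linkage.
#' The returned leaf order is deterministic: at every merge the subtree with
#' the lower merge height comes first, ties resolved by the lexicographically
#' smallest leaf label.
#'
#' @param m numeric matrix; rows are clustered. Needs >= 2 rows and rownames.
#' @return object of class `row_clustering`: list with the `hclust` tree,
#'   `order` (leaf indices), `labels` (leaf labels in display order) and
#'   `newick` (the merge tree as a Newick string with merge heights as branch
#'   lengths).
#' @export
cluster_rows <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 rows to cluster")
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "complete")

  # deterministic leaf order: tighter (lower) subtree first, then lexicographic
  n <- nrow(m)
  height_of <- function(k) if (k < 0) 0 else hc$height[k]
  leaves <- function(k) {
    if (k < 0) return(hc$labels[-k])
    sort(c(leaves(hc$merge[k, 1]), leaves(hc$merge[k, 2])))
  }
  walk <- function(k) {
    if (k < 0) return(-k)
    a <- hc$merge[k, 1]; b <- hc$merge[k, 2]
    ha <- height_of(a); hb <- height_of(b)
    first_a <- if (ha != hb) ha < hb else leaves(a)[1] <= leaves(b)[1]
    if (first_a) c(walk(a), walk(b)) else c(walk(b), walk(a))
  }
  ord <- walk(n - 1)
  hc$order <- ord

  structure(list(hclust = hc, order = ord, labels = hc$labels[ord],
                 newick = ape::write.tree(ape::as.phylo(hc))),
            class = "row_clustering")
}

#' @export
print.row_clustering <- function(x, ...) {
  cat("Row clustering (Euclidean / complete linkage), ",
      length(x$order), " leaves\n", sep = "")
  cat("leaf order:", paste(utils::head(x$labels, 10), collapse = ", "),
      if (length(x$labels) > 10) "..." else "", "\n")
  invisible(x)
}
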