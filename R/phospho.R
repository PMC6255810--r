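#' Per-site log2 fold changes from phospho-antibody array signals
#'
#' Reduces replicate-averaged per-condition intensities to one log2 fold
#' change per (site, treatment) against the control condition. Sites whose
#' control intensity is zero cannot be ratioed and are dropped with a message.
#'
#' @param records data.frame with columns `protein`, `site`, `condition`,
#'   `signal` (nonnegative intensities, replicate-averaged or raw replicates
#'   which are averaged per condition here).
#' @param control_label condition label used as denominator.
#' @param treatment_labels character vector of treatment condition labels.
#' @return data.frame with columns `protein`, `site`, `treatment`, `log2fc`.
#'   `sign` and `adjusted_log2fc` are not yet set (see
#'   [adjust_fold_change_signs()]).
#' @export
compute_site_fold_changes <- function(records, control_label, treatment_labels) {
  if (nrow(records) == 0) {
    warning("empty phosphosite table; returning empty fold-change table")
    return(data.frame(protein = character(), site = character(),
                      treatment = character(), log2fc = numeric()))
  }
  stopifnot(all(c("protein", "site", "condition", "signal") %in% names(records)))
  records$protein <- normalize_symbols(records$protein)
  bad_site <- !is_valid_site(records$site)
  if (any(bad_site)) {
    stop("malformed site identifier(s): ",
         paste(utils::head(unique(records$site[bad_site]), 5), collapse = ", "))
  }
  if (any(records$signal < 0)) stop("negative intensities are not allowed")
  known <- unique(records$condition)
  unknown <- setdiff(c(control_label, treatment_labels), known)
  if (length(unknown) > 0) {
    stop("condition label(s) not present in the table: ",
         paste(unknown, collapse = ", "))
  }

  # replicates averaged per condition before ratioing (mean, for linearity)
  agg <- stats::aggregate(signal ~ protein + site + condition, data = records,
                          FUN = mean)
  key <- function(d) paste(d$protein, d$site, sep = "\r")
  ctrl <- agg[agg$condition == control_label, ]
  zero_ctrl <- ctrl[ctrl$signal <= 0, c("protein", "site")]
  if (nrow(zero_ctrl) > 0) {
    message(nrow(zero_ctrl), " site(s) dropped: zero control signal")
    drop_keys <- paste(zero_ctrl$protein, zero_ctrl$site, sep = "\r")
    agg <- agg[!(key(agg) %in% drop_keys), ]
    ctrl <- ctrl[ctrl$signal > 0, ]
  }
  ctrl_map <- stats::setNames(ctrl$signal, key(ctrl))

  out <- do.call(rbind, lapply(treatment_labels, function(tr) {
    tt <- agg[agg$condition == tr, ]
    cs <- ctrl_map[key(tt)]
    keep <- !is.na(cs)
    data.frame(protein = tt$protein[keep], site = tt$site[keep],
               treatment = tr, log2fc = log2(tt$signal[keep] / cs[keep]))
  }))
  if (is.null(out)) {
    out <- data.frame(protein = character(), site = character(),
                      treatment = character(), log2fc = numeric())
  }
  out <- out[order_lex(out$protein, out$site, out$treatment), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Adjust fold-change signs by known phosphosite regulatory effects
#'
#' Multiplies each site's log2 fold change by its curated regulatory sign
#' (+1 activating, -1 inhibitory), so that positive adjusted values mean
#' functional activation. Sites without a known effect sign are excluded from
#' the returned table, with the excluded count reported.
#'
#' @param fcs fold-change table from [compute_site_fold_changes()].
#' @param effects effect annotation table with columns `protein`, `site`,
#'   `sign` (+1, -1 or NA for unknown); see [read_effects()].
#' @return `fcs` restricted to signed sites, with columns `sign` and
#'   `adjusted_log2fc` added. Attribute `n_excluded` holds the count of rows
#'   dropped for unknown sign.
#' @export
adjust_fold_change_signs <- function(fcs, effects) {
  stopifnot("log2fc" %in% names(fcs))
  effects$protein <- normalize_symbols(effects$protein)
  sign_map <- stats::setNames(effects$sign,
                              paste(effects$protein, effects$site, sep = "\r"))
  s <- sign_map[paste(fcs$protein, fcs$site, sep = "\r")]
  s[!is.na(s) & !(s %in% c(-1, 1))] <- NA
  n_excluded <- sum(is.na(s))
  if (n_excluded > 0) {
    message(n_excluded, " row(s) excluded: unknown effect sign")
  }
  out <- fcs[!is.na(s), , drop = FALSE]
  out$sign <- s[!is.na(s)]
  out$adjusted_log2fc <- out$log2fc * out$sign
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Representative phosphosite per protein
#'
#' For each (protein, treatment) keeps the single phosphosite with the highest
#' absolute log2 fold change (so 2x and 0.5x are equally extreme). Ties are
#' broken lexicographically by site.
#'
#' @param fcs fold-change table; ranking uses `|log2fc|` of the raw (unsigned)
#'   value.
#' @return one row per (protein, treatment) present in the input.
#' @export
representative_site_per_protein <- function(fcs) {
  if (nrow(fcs) == 0) stop("empty fold-change table")
  o <- order_lex(fcs$protein, fcs$treatment, -abs(fcs$log2fc), fcs$site)
  fcs <- fcs[o, , drop = FALSE]
  keep <- !duplicated(paste(fcs$protein, fcs$treatment, sep = "\r"))
  out <- fcs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Treatment response sets (Venn fields) from sign-adjusted fold changes
#'
#' A protein is "up" under a treatment if any of its phosphosites has a
#' sign-adjusted fold-change ratio of at least `ratio_threshold` (i.e.
#' `adjusted_log2fc >= log2(ratio_threshold)`), and "down" if any site is at
#' most the reciprocal. Proteins are then grouped by the exact combination of
#' treatments in which they respond, which are the fields of a Venn diagram.
#'
#' If different sites push a protein past both cutoffs under the same
#' treatment, the site with the larger `|adjusted_log2fc|` decides the
#' direction (ties go to "up"), keeping up and down disjoint per treatment.
#'
#' @param fcs table carrying `adjusted_log2fc` (see
#'   [adjust_fold_change_signs()]).
#' @param ratio_threshold ratio cutoff, must be > 1 (default 2).
#' @return object of class `venn_sets`: list with `up` and `down`, each a
#'   named list mapping a treatment combination (labels sorted, joined with
#'   "+") to a character vector of proteins, plus `treatments` and
#'   `threshold`.
#' @export
treatment_response_sets <- function(fcs, ratio_threshold = 2) {
  if (ratio_threshold <= 1) stop("ratio_threshold must be > 1")
  stopifnot("adjusted_log2fc" %in% names(fcs))
  cut <- log2(ratio_threshold)
  treatments <- sort(unique(fcs$treatment))

  # direction per (protein, treatment): any site past the cutoff; if both
  # directions are hit, the largest |adjusted| site decides (ties -> up)
  pt <- paste(fcs$protein, fcs$treatment, sep = "\r")
  up_hit <- tapply(fcs$adjusted_log2fc >= cut, pt, any)
  dn_hit <- tapply(fcs$adjusted_log2fc <= -cut, pt, any)
  dom_up <- tapply(seq_len(nrow(fcs)), pt, function(idx) {
    v <- fcs$adjusted_log2fc[idx]
    v[which.max(abs(v))] >= 0
  })
  both <- up_hit & dn_hit
  up_hit[both] <- dom_up[both]
  dn_hit[both] <- !dom_up[both]
  info <- data.frame(protein = fcs$protein[!duplicated(pt)],
                     treatment = fcs$treatment[!duplicated(pt)],
                     key = pt[!duplicated(pt)])

  member_combos <- function(dir) {
    hit_map <- if (dir == "up") up_hit else dn_hit
    hf <- info[hit_map[info$key], c("protein", "treatment")]
    if (nrow(hf) == 0) return(list())
    per_prot <- split(hf$treatment, hf$protein)
    combos <- vapply(per_prot,
                     function(tr) paste(sort(unique(tr)), collapse = "+"), "")
    fields <- split(names(per_prot), combos)
    fields <- lapply(fields, function(p) sort(unique(p)))
    fields[order(names(fields))]
  }

  structure(list(up = member_combos("up"), down = member_combos("down"),
                 treatments = treatments, threshold = ratio_threshold),
            class = "venn_sets")
}

#' Summarize Venn fields
#'
#' @param vennsets a `venn_sets` object.
#' @return list with per-direction `total` and named `fields` counts; totals
#'   equal the sum of field counts by construction (fields partition the
#'   responding proteins).
#' @export
summarize_venn <- function(vennsets) {
  stopifnot(inherits(vennsets, "venn_sets"))
  one <- function(fields) {
    counts <- vapply(fields, length, 0L)
    list(total = length(unique(unlist(fields, use.names = FALSE))),
         fields = as.list(counts))
  }
  list(up = one(vennsets$up), down = one(vennsets$down))
}

#' @export
print.venn_sets <- function(x, ...) {
  s <- summarize_venn(x)
  cat("Treatment response sets (ratio threshold ", x$threshold, ")\n", sep = "")
  for (d in c("up", "down")) {
    cat("  ", d, ": ", s[[d]]$total, " protein(s)\n", sep = "")
    for (f in names(x[[d]])) {
      cat("    ", f, ": ", length(x[[d]][[f]]), "\n", sep = "")
    }
  }
  invisible(x)
}
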