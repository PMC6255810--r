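# Readers and writers for the small TSV/GMT/SIF/JSON dialects the pipeline
# consumes. All are plain text; writers are deterministic (fixed column
# order, fixed number formatting) so reruns are byte-identical.

read_tsv_checked <- function(path, required, what) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop(what, " file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  d
}

#' Read a phospho-antibody array signal table
#'
#' Tab-separated with header `protein  site  condition  signal`.
#'
#' @param path file path.
#' @return data.frame suitable for [compute_site_fold_changes()].
#' @export
read_phospho_signals <- function(path) {
  d <- read_tsv_checked(path, c("protein", "site", "condition", "signal"),
                        "phospho signal")
  d$protein <- normalize_symbols(d$protein)
  d$signal <- as.numeric(d$signal)
  d
}

#' Read precomputed phosphosite fold changes
#'
#' Tab-separated with header `protein  site  treatment  fold_change`
#' (positive treated/control ratios); converted to log2.
#'
#' @param path file path.
#' @return data.frame with `protein`, `site`, `treatment`, `log2fc`.
#' @export
read_phospho_foldchanges <- function(path) {
  d <- read_tsv_checked(path, c("protein", "site", "treatment",
                                "fold_change"), "phospho fold-change")
  if (any(d$fold_change <= 0)) stop("fold_change must be positive")
  data.frame(protein = normalize_symbols(d$protein), site = d$site,
             treatment = d$treatment, log2fc = log2(d$fold_change))
}

#' Read a phosphosite regulatory-effect annotation table
#'
#' Tab-separated with header `protein  site  sign  partners`; `sign` is
#' `+1`, `-1` or `unknown`; `partners` is a semicolon-separated list of
#' `PARTNER:induce` / `PARTNER:disrupt` entries (may be empty).
#'
#' @param path file path.
#' @return data.frame with columns `protein`, `site`, `sign` (numeric, NA
#'   for unknown) and list-column `partners` of data.frames
#'   (`partner`, `label`).
#' @export
read_effects <- function(path) {
  d <- read_tsv_checked(path, c("protein", "site", "sign"), "effects")
  sgn <- suppressWarnings(as.numeric(d$sign))
  sgn[!sgn %in% c(-1, 1)] <- NA
  partners <- rep(list(data.frame(partner = character(),
                                  label = character())), nrow(d))
  if ("partners" %in% names(d)) {
    partners <- lapply(as.character(d$partners), parse_partner_field)
  }
  out <- data.frame(protein = normalize_symbols(d$protein), site = d$site,
                    sign = sgn)
  if (any(duplicated(paste(out$protein, out$site)))) {
    stop("duplicate (protein, site) rows in effects table")
  }
  out$partners <- partners
  out
}

parse_partner_field <- function(s) {
  empty <- data.frame(partner = character(), label = character())
  if (is.na(s) || !nzchar(s)) return(empty)
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, 0L) != 2
  if (any(bad)) stop("malformed partner entry: ", parts[bad][1])
  lab <- vapply(kv, `[`, "", 2)
  if (!all(lab %in% c("induce", "disrupt"))) {
    stop("partner label must be induce or disrupt")
  }
  data.frame(partner = normalize_symbols(vapply(kv, `[`, "", 1)),
             label = lab)
}

format_partner_field <- function(p) {
  if (is.null(p) || nrow(p) == 0) return("")
  paste(paste0(p$partner, ":", p$label), collapse = ";")
}

#' Write a regulatory-effect annotation table
#' @param effects data.frame as returned by [read_effects()].
#' @param path output path.
#' @export
write_effects <- function(effects, path) {
  d <- data.frame(protein = effects$protein, site = effects$site,
                  sign = ifelse(is.na(effects$sign), "unknown",
                                sprintf("%+d", effects$sign)),
                  partners = vapply(effects$partners, format_partner_field,
                                    ""))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a kinase-substrate table
#'
#' Tab-separated with header `protein  site  kinase  source`.
#' @param path file path.
#' @return data.frame.
#' @export
read_kinase_table <- function(path) {
  d <- read_tsv_checked(path, c("protein", "site", "kinase"), "kinase")
  d$protein <- normalize_symbols(d$protein)
  d$kinase <- normalize_symbols(d$kinase)
  d
}

#' Read a directed network edge list (SIF or 2/3-column TSV)
#'
#' Three columns are read as `source  relation  target` (SIF dialect), two
#' as `source  target`. No header. Malformed rows raise an error naming the
#' line.
#'
#' @param path file path.
#' @return data.frame with `source`, `target` and (for SIF) `sign` mapped
#'   from the relation (`inhibition`/`-1` -> -1, else +1).
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty network file ", path)
    return(data.frame(source = character(), target = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 0L)
  if (!all(nf %in% c(2L, 3L)) || length(unique(nf)) != 1) {
    bad <- which(nf != nf[1] | !(nf %in% c(2L, 3L)))[1]
    stop("malformed network row at line ", bad, ": ", lines[bad])
  }
  if (nf[1] == 2L) {
    data.frame(source = vapply(fields, `[`, "", 1),
               target = vapply(fields, `[`, "", 2))
  } else {
    rel <- vapply(fields, `[`, "", 2)
    data.frame(source = vapply(fields, `[`, "", 1),
               target = vapply(fields, `[`, "", 3),
               sign = ifelse(rel %in% c("inhibition", "-1"), -1, 1))
  }
}

#' Write a network edge list in SIF dialect
#' @param edges data.frame with `source`, `target`, optional `sign`.
#' @param path output path.
#' @export
write_sif <- function(edges, path) {
  rel <- if ("sign" %in% names(edges)) {
    ifelse(edges$sign < 0, "inhibition", "stimulation")
  } else "interaction"
  writeLines(paste(edges$source, rel, edges$target, sep = "\t"), path)
}

#' Read a TF-target regulon table
#'
#' Tab-separated with header `tf  target  mode  confidence`.
#' @param path file path.
#' @return data.frame (unfiltered; see [build_regulons()]).
#' @export
read_regulon_table <- function(path) {
  d <- read_tsv_checked(path, c("tf", "target", "mode", "confidence"),
                        "regulon")
  d$mode <- as.numeric(d$mode)
  d
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", l)
    normalize_symbols(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional descriptions (defaults to set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, ""), path)
}

#' Read an expression signature
#'
#' Tab-separated with header `gene  log2fc`.
#' @param path file path.
#' @return named numeric vector.
#' @export
read_signature <- function(path) {
  d <- read_tsv_checked(path, c("gene", "log2fc"), "signature")
  stats::setNames(as.numeric(d$log2fc), normalize_symbols(d$gene))
}

#' Write an expression signature
#' @param signature named numeric vector.
#' @param path output path.
#' @export
write_signature <- function(signature, path) {
  utils::write.table(data.frame(gene = names(signature),
                                log2fc = format_num(signature)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# fixed-format numbers: full precision for lossless round trips,
# fixed rendering for byte-identical reruns
format_num <- function(x) {
  ifelse(is.finite(x), sprintf("%.17g", x),
         ifelse(is.infinite(x) & x > 0, "Inf",
                ifelse(is.infinite(x), "-Inf", "NA")))
}

#' Write a data.frame as deterministic TSV
#' @param d data.frame; numeric columns are formatted at full precision
#'   with a fixed rendering.
#' @param path output path.
#' @export
write_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], format_num)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write Venn set memberships and cardinalities as JSON
#' @param vennsets a `venn_sets` object.
#' @param path output path.
#' @export
write_venn_json <- function(vennsets, path) {
  s <- summarize_venn(vennsets)
  payload <- list(
    threshold = vennsets$threshold,
    treatments = vennsets$treatments,
    up = list(total = s$up$total, fields = s$up$fields,
              membership = vennsets$up),
    down = list(total = s$down$total, fields = s$down$fields,
                membership = vennsets$down))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}
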