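#' @keywords internal
#' @importFrom Matrix Diagonal
#' @importFrom stats aggregate setNames dist hclust qnorm pnorm rnorm runif
#'   wilcox.test
#' @importFrom utils head read.delim write.table packageVersion
"_PACKAGE"

#' Normalize gene symbols
#'
#' Protein and gene identifiers are represented as uppercase human-style gene
#' symbols throughout; this is the single normalization code path run at every
#' ingest boundary.
#'
#' @param x character vector of symbols.
#' @return uppercased, whitespace-trimmed character vector.
#' @export
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

# residue-position strings look like "S463", "T180Y182" is not allowed:
# single letter followed by an integer
is_valid_site <- function(site) {
  grepl("^[A-Za-z][0-9]+$", site)
}

# grade ordering: A best .. E worst
.grade_levels <- c("A", "B", "C", "D", "E")

assert_grades <- function(g) {
  bad <- setdiff(unique(g), .grade_levels)
  if (length(bad) > 0) {
    stop("unknown confidence grade(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

# deterministic ordering used everywhere ties are broken
order_lex <- function(...) order(..., method = "radix")

# derive a stream-specific 32-bit seed from a base seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 97L + as.integer(stream) * 1009L) %% 2147483587L
}
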