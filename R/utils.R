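# internal helpers shared across modules

#' @importFrom stats runif rgeom
#' @importFrom utils head tail read.delim write.table
NULL

# condition constructors used by the CLI for exit-code mapping
ighd_usage_error <- function(msg) {
  stop(structure(class = c("ighd_usage_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

ighd_format_error <- function(msg) {
  stop(structure(class = c("ighd_format_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# round-half-up at `digits` decimals; base round() is banker's rounding
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

hamming <- function(x, y) {
  if (nchar(x) != nchar(y)) ighd_usage_error("hamming: unequal lengths")
  sum(strsplit(x, "", fixed = TRUE)[[1]] != strsplit(y, "", fixed = TRUE)[[1]])
}

# "IGHD8-2" -> family 8; placeholder names ("D3") give NA
gene_family <- function(name) {
  name <- canonical_gene_name(name)
  m <- regmatches(name, regexec("^IGHD([0-9]+)-[0-9]+$", name))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else NA_integer_
}

# the literature mixes ASCII hyphen and en-dash in gene symbols
canonical_gene_name <- function(name) {
  gsub("–", "-", name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
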