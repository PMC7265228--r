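# Sequence and annotation IO on a single coordinate convention.
#
# All coordinates inside the package are 0-based half-open on the top strand;
# conversion to 1-based happens only at the GFF3 boundary.

#' DNA sequence container
#'
#' A named DNA string with provenance. Residues are normalized on
#' construction: uppercased, `U` mapped to `T`, and any character outside
#' `{A,C,G,T,N}` mapped to `N` with a warning.
#'
#' @param residues Character scalar of DNA residues.
#' @param id Sequence identifier.
#' @param source Free-text provenance (file path or accession).
#' @return An object of class `nuc_sequence`.
#' @export
nuc_sequence <- function(residues, id = "seq", source = NA_character_) {
  if (!is.character(residues) || length(residues) != 1L)
    ighd_usage_error("residues must be a single character string")
  r <- toupper(residues)
  r <- chartr("U", "T", r)
  bad <- gsub("[ACGTN]", "", r)
  if (nchar(bad) > 0L) {
    warning(sprintf("sequence '%s': %d non-ACGTN character(s) mapped to N",
                    id, nchar(bad)))
    r <- gsub("[^ACGTN]", "N", r)
  }
  if (nchar(r) < 1L) ighd_usage_error("sequence must have length >= 1")
  structure(list(id = id, residues = r, source = source),
            class = "nuc_sequence")
}

#' @export
length.nuc_sequence <- function(x) nchar(x$residues)

#' @export
print.nuc_sequence <- function(x, ...) {
  n <- length(x)
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<nuc_sequence> %s (%d nt)\n  %s\n", x$id, n, shown))
  invisible(x)
}

as_residues <- function(x) {
  if (inherits(x, "nuc_sequence")) x$residues
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else ighd_usage_error("expected a nuc_sequence or a character scalar")
}

#' Genomic interval (0-based half-open)
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `interval`.
#' @export
interval <- function(start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    ighd_usage_error(sprintf("invalid interval [%s,%s)", start, end))
  if (!strand %in% c("+", "-")) ighd_usage_error("strand must be '+' or '-'")
  structure(list(start = start, end = end, strand = strand),
            class = "interval")
}

iv_width <- function(iv) iv$end - iv$start

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("[%d,%d)(%s)\n", x$start, x$end, x$strand)); invisible(x)
}

#' Read sequences from FASTA or GenBank
#'
#' One `nuc_sequence` per record, normalized as by [nuc_sequence()]. GenBank
#' parsing is a minimal flat-file reader (LOCUS / ORIGIN) adequate for
#' nucleotide records; no preinstalled package reads local GenBank files
#' offline.
#'
#' @param path File path.
#' @param format `"fasta"` or `"genbank"`.
#' @return List of `nuc_sequence`.
#' @export
read_sequences <- function(path, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path))
    ighd_format_error(sprintf("cannot read '%s': no such file", path))
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e)
                      ighd_format_error(sprintf("'%s': %s", path,
                                                conditionMessage(e))))
    if (length(set) == 0L)
      ighd_format_error(sprintf("'%s': no FASTA records", path))
    ids <- sub("\\s.*$", "", names(set))
    lapply(seq_along(set), function(i)
      nuc_sequence(as.character(set[[i]]), id = ids[i], source = path))
  } else {
    lines <- readLines(path, warn = FALSE)
    rec_end <- grep("^//", lines)
    rec_start <- c(1L, head(rec_end, -1) + 1L)
    if (length(rec_end) == 0L)
      ighd_format_error(sprintf("'%s': no GenBank records (missing '//')", path))
    out <- list()
    for (k in seq_along(rec_end)) {
      block <- lines[rec_start[k]:rec_end[k]]
      locus <- grep("^LOCUS", block, value = TRUE)
      if (length(locus) == 0L)
        ighd_format_error(sprintf("'%s': record %d has no LOCUS line", path, k))
      id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
      ori <- grep("^ORIGIN", block)
      if (length(ori) == 0L)
        ighd_format_error(sprintf("'%s': record %d has no ORIGIN section",
                                  path, k))
      seq_lines <- block[(ori[1] + 1L):(length(block) - 1L)]
      res <- gsub("[0-9 /]", "", paste(seq_lines, collapse = ""))
      if (nchar(res) == 0L)
        ighd_format_error(sprintf("'%s': record %d is empty", path, k))
      out[[k]] <- nuc_sequence(res, id = id, source = path)
    }
    out
  }
}

#' Extract a subsequence
#'
#' Minus-strand extraction returns the reverse complement. The new id is
#' `"<parent_id>:<start>-<end>(<strand>)"`.
#'
#' @param seq A `nuc_sequence`.
#' @param iv An [interval()] within `seq`.
#' @return A `nuc_sequence`.
#' @export
extract <- function(seq, iv) {
  n <- length(seq)
  if (iv$start < 0L || iv$end > n)
    ighd_usage_error(sprintf("interval [%d,%d) out of bounds for '%s' (%d nt)",
                             iv$start, iv$end, seq$id, n))
  sub <- substr(seq$residues, iv$start + 1L, iv$end)
  if (iv$strand == "-") sub <- revcomp(sub)
  nuc_sequence(sub,
               id = sprintf("%s:%d-%d(%s)", seq$id, iv$start, iv$end,
                            iv$strand),
               source = seq$source)
}

FEATURE_TYPES <- c("gene", "rss5", "rss3", "coding", "cluster", "intergenic")

#' Build an annotation table
#'
#' @param seqid Sequence id the records refer to.
#' @param name Feature names.
#' @param start,end 0-based half-open coordinates.
#' @param strand Strands.
#' @param feature_type One of `r paste(FEATURE_TYPES, collapse=", ")`.
#' @return A data.frame of class `annotation_frame`.
#' @export
annotation_frame <- function(seqid, name, start, end, strand = "+",
                             feature_type = "gene") {
  df <- data.frame(seqid = seqid, name = canonical_gene_name(name),
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, feature_type = feature_type,
                   stringsAsFactors = FALSE)
  validate_annotations(df)
  class(df) <- c("annotation_frame", "data.frame")
  df
}

validate_annotations <- function(df) {
  stopifnot(all(c("seqid", "name", "start", "end", "strand",
                  "feature_type") %in% names(df)))
  if (any(!nzchar(df$name))) ighd_usage_error("annotation names must be nonempty")
  if (any(!df$feature_type %in% FEATURE_TYPES))
    ighd_usage_error("feature_type outside the allowed vocabulary")
  if (any(df$start < 0L | df$start >= df$end))
    ighd_usage_error("annotation intervals must satisfy 0 <= start < end")
  invisible(df)
}

#' Write annotations as BED or GFF3
#'
#' BED is written 0-based half-open as BED6 plus a seventh `feature_type`
#' column (the closed feature vocabulary cannot ride in standard BED6, so the
#' extra column keeps the round trip lossless). GFF3 is 1-based inclusive
#' with the feature type in column 3 and `Name=` in the attributes.
#'
#' @param records An `annotation_frame` (or compatible data.frame).
#' @param path Output path.
#' @param format `"bed"` or `"gff3"`.
#' @export
write_annotations <- function(records, path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  validate_annotations(records)
  if (format == "bed") {
    out <- data.frame(records$seqid, records$start, records$end, records$name,
                      0L, records$strand, records$feature_type)
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    attrs <- sprintf("Name=%s", records$name)
    out <- data.frame(records$seqid, "ighdarch", records$feature_type,
                      records$start + 1L, records$end, ".", records$strand,
                      ".", attrs)
    con <- file(path, "w"); on.exit(close(con))
    writeLines("##gff-version 3", con)
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#'
#' @inheritParams write_annotations
#' @return An `annotation_frame` in internal 0-based coordinates.
#' @export
read_annotations <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path))
    ighd_format_error(sprintf("cannot read '%s': no such file", path))
  if (format == "bed") {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 7L) ighd_format_error("BED file lacks the feature_type column")
    annotation_frame(df[[1]], df[[4]], df[[2]], df[[3]], df[[6]], df[[7]])
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    if (length(lines) == 0L)
      return(annotation_frame(character(0), character(0), integer(0),
                              integer(0), character(0), character(0)))
    df <- read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE)
    name <- sub("^.*Name=([^;]+).*$", "\\1", df[[9]])
    annotation_frame(df[[1]], name, df[[4]] - 1L, df[[5]], df[[7]], df[[3]])
  }
}
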