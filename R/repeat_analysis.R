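# Decompose D-gene coding regions into short tandem repeat units and compare
# expansion states across paralogs and orthologs.

#' Canonical cyclic rotation of a repeat unit
#'
#' Lexicographically smallest rotation; idempotent. Units are compared by
#' canonical rotation only (all compared genes are on the same strand).
#'
#' @param u DNA string.
#' @return The canonical rotation.
#' @export
canonical_unit <- function(u) {
  if (nchar(u) == 0L) ighd_usage_error("empty unit")
  u <- toupper(u)
  n <- nchar(u)
  rots <- vapply(seq_len(n) - 1L, function(k)
    paste0(substr(u, k + 1L, n), substr(u, 1L, k)), "")
  min(rots)
}

new_repeat_array <- function(unit, unit_len, copies, span, mismatches) {
  structure(list(unit = unit, unit_len = unit_len, copies = copies,
                 span = span, mismatches = mismatches),
            class = "repeat_array")
}

#' Decompose a coding region into tandem repeat arrays
#'
#' Exhaustive period scan over unit lengths `[min_unit, max_unit]`, then
#' greedy highest-coverage-first selection of non-overlapping maximal
#' arrays. Ties break by longer span, then fewer mismatches, then smaller
#' unit length, then leftmost start: mismatch parsimony must precede the
#' unit-length rule, otherwise a perfect hexamer array loses its span tie
#' to a mismatch-riddled trimer re-parse of the same bases (and a shifted
#' anchor absorbing one flank character outranks the true array by
#' leftmost position). Mismatch tolerance is per copy (vs the anchor
#' copy). Fractional trailing copies are floored to half-unit resolution.
#'
#' @param coding A `nuc_sequence`, `dh_gene` or DNA string.
#' @param min_unit,max_unit Unit length bounds (nt).
#' @param max_mm_per_copy Mismatches tolerated per whole copy.
#' @return A `repeat_profile`: ordered non-overlapping arrays plus the
#'   unexplained fraction of the coding length.
#' @export
decompose <- function(coding, min_unit = 3L, max_unit = 12L,
                      max_mm_per_copy = 1L) {
  gene_name <- if (inherits(coding, "dh_gene")) coding$name else
    if (inherits(coding, "nuc_sequence")) coding$id else "seq"
  res <- if (inherits(coding, "dh_gene")) coding$coding_seq else
    as_residues(coding)
  n <- nchar(res)
  if (n < 2L * min_unit)
    ighd_usage_error("coding too short to hold two repeat copies")
  cand <- scan_tandem_cpp(res, as.integer(min_unit), as.integer(max_unit),
                          as.integer(max_mm_per_copy))
  arrays <- list()
  if (nrow(cand) > 0L) {
    cand$span_len <- cand$unit_len * cand$whole + cand$partial
    ord <- order(-cand$span_len, cand$mismatches, cand$unit_len, cand$start)
    cand <- cand[ord, , drop = FALSE]
    covered <- logical(n)
    for (r in seq_len(nrow(cand))) {
      s <- cand$start[r]; e <- s + cand$span_len[r]
      if (any(covered[(s + 1L):e])) next
      covered[(s + 1L):e] <- TRUE
      unit0 <- substr(res, s + 1L, s + cand$unit_len[r])
      copies <- cand$whole[r] +
        floor(2 * cand$partial[r] / cand$unit_len[r]) / 2
      arrays[[length(arrays) + 1L]] <-
        new_repeat_array(canonical_unit(unit0), cand$unit_len[r], copies,
                         interval(s, e), cand$mismatches[r])
    }
    starts <- vapply(arrays, function(x) x$span$start, 0L)
    arrays <- arrays[order(starts)]
  }
  covered_nt <- sum(vapply(arrays, function(x) iv_width(x$span), 0L))
  structure(list(gene = gene_name, arrays = arrays,
                 coding_len = n,
                 unexplained = 1 - covered_nt / n),
            class = "repeat_profile")
}

#' @export
print.repeat_profile <- function(x, ...) {
  cat(sprintf("<repeat_profile> %s (%d nt, %.0f%% unexplained)\n", x$gene,
              x$coding_len, 100 * x$unexplained))
  for (a in x$arrays)
    cat(sprintf("  [%d,%d) %s x %.1f (%d mm)\n", a$span$start, a$span$end,
                a$unit, a$copies, a$mismatches))
  invisible(x)
}

#' Plain-text rendering of a repeat profile
#'
#' Arrays are bracketed in the coding sequence, e.g.
#' `acg[TGGTTA*3.0]tt`.
#'
#' @param profile A `repeat_profile`.
#' @param residues The coding residues the profile was computed from.
#' @return A character scalar.
#' @export
render_profile <- function(profile, residues) {
  res <- as_residues(residues)
  out <- ""; pos <- 0L
  for (a in profile$arrays) {
    if (a$span$start > pos)
      out <- paste0(out, tolower(substr(res, pos + 1L, a$span$start)))
    out <- paste0(out, sprintf("[%s*%.1f]", a$unit, a$copies))
    pos <- a$span$end
  }
  if (pos < nchar(res)) out <- paste0(out, tolower(substr(res, pos + 1L,
                                                          nchar(res))))
  out
}

#' Compare two repeat profiles
#'
#' Arrays sharing a canonical unit are paired; copy-number deltas, units
#' private to each gene, and the total coding length delta are reported.
#' Deltas are antisymmetric: `compare_profiles(a,b)` negates
#' `compare_profiles(b,a)`.
#'
#' @param a,b `repeat_profile` objects.
#' @return A list with `units` (data.frame of per-unit copy totals and
#'   deltas), `private_a`, `private_b`, `length_delta`.
#' @export
compare_profiles <- function(a, b) {
  tot <- function(p) {
    units <- vapply(p$arrays, `[[`, "", "unit")
    copies <- vapply(p$arrays, `[[`, 0, "copies")
    tapply(copies, units, sum)
  }
  ta <- tot(a); tb <- tot(b)
  units <- sort(union(names(ta), names(tb)))
  ca <- ifelse(units %in% names(ta), ta[units], 0)
  cb <- ifelse(units %in% names(tb), tb[units], 0)
  df <- data.frame(unit = units, copies_a = as.numeric(ca),
                   copies_b = as.numeric(cb),
                   copy_delta = as.numeric(ca) - as.numeric(cb),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  list(gene_a = a$gene, gene_b = b$gene, units = df,
       private_a = units[cb == 0 & ca > 0],
       private_b = units[ca == 0 & cb > 0],
       length_delta = a$coding_len - b$coding_len)
}
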