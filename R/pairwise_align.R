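# Native affine-gap pairwise alignment: the numeric engine behind every
# percent-identity statement in the package.

#' Alignment parameters
#'
#' Defaults follow the EMBOSS Matcher DNA scoring (+5/-4, gap open -16,
#' extend -4) so that local end-identities over D-gene codings land on the
#' same scale as the published comparisons; weaker gap penalties let local
#' alignments of unrelated DNA chain matches into long low-identity spans,
#' which corrupts coverage-based deletion calls. A gap of length k costs
#' `gap_open + (k-1)*gap_extend`.
#'
#' @param match Positive match score.
#' @param mismatch Non-positive mismatch score.
#' @param gap_open,gap_extend Non-positive gap penalties,
#'   `gap_open <= gap_extend`.
#' @param mode `"global"`, `"local"` or `"semiglobal"` (free end gaps,
#'   overhangs excluded from the alignment and from the identity
#'   denominator).
#' @return An `align_params` object.
#' @export
align_params <- function(match = 5, mismatch = -4, gap_open = -16,
                         gap_extend = -4,
                         mode = c("global", "local", "semiglobal")) {
  mode <- match.arg(mode)
  if (match <= 0) ighd_usage_error("match score must be > 0")
  if (mismatch > 0) ighd_usage_error("mismatch score must be <= 0")
  if (gap_open > 0 || gap_extend > 0 || gap_open > gap_extend)
    ighd_usage_error("need gap_open <= gap_extend <= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, mode = mode),
            class = "align_params")
}

count_matches <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) == 0L) return(0L)
  x <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  y <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  sum(x == y & x != "-" & x != "N")
}

#' Pairwise alignment
#'
#' Optimal global, local or semiglobal alignment under affine gap costs,
#' with deterministic tie-breaking (diagonal, then gap-in-b, then gap-in-a).
#' A column is a match iff both characters are equal and neither is a gap or
#' `N`; `identity_pct = 100 * matches / columns` over the emitted columns.
#'
#' @param a,b `nuc_sequence` objects (or plain DNA strings).
#' @param params An [align_params()] object.
#' @param anchor For local mode only: `"none"` (default), or constrain the
#'   alignment to touch `b`'s start (`"b_start"`) or end (`"b_end"`) within
#'   `anchor_slack` nt, returning the best-scoring such alignment.
#' @param anchor_slack Anchor tolerance in nt.
#' @return A `pairwise_alignment` with aligned strings, score, 0-based
#'   half-open spans on each input, match/column counts and `identity_pct`
#'   (`NA` for an empty local alignment).
#' @export
align <- function(a, b, params = align_params(),
                  anchor = c("none", "b_start", "b_end"),
                  anchor_slack = 5L) {
  anchor <- match.arg(anchor)
  ra <- as_residues(a); rb <- as_residues(b)
  if (nchar(ra) == 0L || nchar(rb) == 0L)
    ighd_usage_error("align: empty input sequence")
  if (anchor != "none" && params$mode != "local")
    ighd_usage_error("anchored alignment requires local mode")
  mode_code <- match(params$mode, c("global", "local", "semiglobal")) - 1L
  rev_str <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = "")
  if (anchor == "b_start") {
    # anchor at b's start == anchor at the end of the reversed problem
    res <- align_cpp(rev_str(ra), rev_str(rb), params$match, params$mismatch,
                     params$gap_open, params$gap_extend, mode_code,
                     1L, as.integer(anchor_slack))
    res$aligned_a <- rev_str(res$aligned_a)
    res$aligned_b <- rev_str(res$aligned_b)
    tmp <- res
    res$a_start <- nchar(ra) - tmp$a_end; res$a_end <- nchar(ra) - tmp$a_start
    res$b_start <- nchar(rb) - tmp$b_end; res$b_end <- nchar(rb) - tmp$b_start
  } else {
    res <- align_cpp(ra, rb, params$match, params$mismatch, params$gap_open,
                     params$gap_extend, mode_code,
                     if (anchor == "b_end") 1L else 0L,
                     as.integer(anchor_slack))
  }
  columns <- nchar(res$aligned_a)
  matches <- count_matches(res$aligned_a, res$aligned_b)
  structure(list(
    aligned_a = res$aligned_a, aligned_b = res$aligned_b,
    score = res$score,
    span_a = if (columns > 0) interval(res$a_start, res$a_end) else NULL,
    span_b = if (columns > 0) interval(res$b_start, res$b_end) else NULL,
    matches = matches, columns = columns,
    identity_pct = if (columns > 0) 100 * matches / columns else NA_real_,
    params = params,
    id_a = if (inherits(a, "nuc_sequence")) a$id else "a",
    id_b = if (inherits(b, "nuc_sequence")) b$id else "b"
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s (%s)\n", x$id_a, x$id_b,
              x$params$mode))
  cat(sprintf("  score %.1f, columns %d, matches %d, identity %.1f%%\n",
              x$score, x$columns, x$matches,
              if (x$columns > 0) x$identity_pct else NA))
  invisible(x)
}

#' Percent identity of an alignment
#'
#' `100 * matches / columns`; gap columns count in the denominator, `N`
#' never counts as a match. Errors on a zero-column alignment.
#'
#' @param aln A `pairwise_alignment`.
#' @return Numeric percent in `[0, 100]`.
#' @export
percent_identity <- function(aln) {
  if (!inherits(aln, "pairwise_alignment"))
    ighd_usage_error("percent_identity expects a pairwise_alignment")
  if (aln$columns == 0L)
    ighd_usage_error("percent identity undefined for a zero-column alignment")
  100 * aln$matches / aln$columns
}

# X-drop trim of an alignment from its anchored side: walk column scores
# from the anchored end, stop once the running score falls more than
# `xdrop` below its maximum, and cut at the maximum. Score-optimal local
# alignments otherwise overshoot homology boundaries through net-positive
# low-identity extensions, diluting terminal identities.
trim_alignment_xdrop <- function(aln, anchored = c("left", "right"),
                                 xdrop = 20, params = aln$params) {
  anchored <- match.arg(anchored)
  if (aln$columns <= 1L) return(aln)
  xa <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  xb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  ord <- if (anchored == "left") seq_along(xa) else rev(seq_along(xa))
  cum <- 0; best <- -Inf; best_at <- 0L
  in_gap_a <- FALSE; in_gap_b <- FALSE
  for (t in seq_along(ord)) {
    k <- ord[t]
    if (xa[k] == "-") {
      cum <- cum + if (in_gap_a) params$gap_extend else params$gap_open
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (xb[k] == "-") {
      cum <- cum + if (in_gap_b) params$gap_extend else params$gap_open
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      in_gap_a <- in_gap_b <- FALSE
      cum <- cum + if (xa[k] == xb[k] && xa[k] != "N") params$match else
        params$mismatch
    }
    if (cum > best) { best <- cum; best_at <- t }
    if (best - cum > xdrop) break
  }
  if (best_at == length(ord)) return(aln)
  keep <- sort(ord[seq_len(best_at)])
  cut_a <- sum(xa[setdiff(seq_along(xa), keep)] != "-")
  cut_b <- sum(xb[setdiff(seq_along(xb), keep)] != "-")
  out <- aln
  out$aligned_a <- paste(xa[keep], collapse = "")
  out$aligned_b <- paste(xb[keep], collapse = "")
  out$columns <- length(keep)
  out$matches <- count_matches(out$aligned_a, out$aligned_b)
  out$identity_pct <- 100 * out$matches / out$columns
  out$score <- best
  if (anchored == "left") {
    out$span_a <- interval(aln$span_a$start, aln$span_a$end - cut_a)
    out$span_b <- interval(aln$span_b$start, aln$span_b$end - cut_b)
  } else {
    out$span_a <- interval(aln$span_a$start + cut_a, aln$span_a$end)
    out$span_b <- interval(aln$span_b$start + cut_b, aln$span_b$end)
  }
  out
}

#' Terminal identity of a donor against one end of a target gene
#'
#' Local (Matcher-style) alignment of the donor coding region against the
#' target coding region, anchored so that the alignment touches the
#' requested target terminus (within `slack` nt); the best-scoring such
#' alignment supplies `identity_pct` and `window_nt` (the aligned span on
#' the target). Extension away from the terminus is X-drop-limited
#' (`xdrop`): it stops once the running score falls `xdrop` below its
#' maximum, so the window does not overrun the homologous region into
#' low-identity chance alignment. If no positive-scoring alignment touches
#' the terminus, the best unanchored local alignment is reported with
#' `at_terminus = FALSE`.
#'
#' @param donor,target `dh_gene` objects (or sequences).
#' @param end `"five_prime"` or `"three_prime"`: which target terminus is
#'   interrogated.
#' @param params Alignment parameters; mode is forced to `"local"`.
#' @param slack Maximum distance (nt) from the terminus still counted as
#'   abutting.
#' @param xdrop Score drop terminating extension away from the terminus.
#' @param min_window Minimum aligned target span (nt) for the anchored
#'   alignment to count as terminal homology evidence; shorter windows are
#'   chance-level (a handful of matching nucleotides at a terminus reaches
#'   100\% identity by chance) and are reported with
#'   `at_terminus = FALSE`.
#' @return An `end_identity` object.
#' @export
end_identity <- function(donor, target, end = c("five_prime", "three_prime"),
                         params = align_params(mode = "local"), slack = 5L,
                         xdrop = 20, min_window = 12L) {
  end <- match.arg(end)
  dseq <- if (inherits(donor, "dh_gene")) donor$coding_seq else as_residues(donor)
  tseq <- if (inherits(target, "dh_gene")) target$coding_seq else as_residues(target)
  if (is.null(dseq) || is.null(tseq))
    ighd_usage_error("end_identity: both genes must carry coding sequences")
  params$mode <- "local"
  aln <- align(dseq, tseq, params,
               anchor = if (end == "five_prime") "b_start" else "b_end",
               anchor_slack = slack)
  at_term <- aln$columns > 0L
  if (at_term) {
    aln <- trim_alignment_xdrop(aln,
                                if (end == "five_prime") "left" else "right",
                                xdrop, params)
  } else { # nothing touches the terminus: report the best span anywhere
    aln <- align(dseq, tseq, params)
  }
  window <- if (aln$columns > 0L) iv_width(aln$span_b) else 0L
  if (window < min_window) at_term <- FALSE
  structure(list(
    donor = if (inherits(donor, "dh_gene")) donor$name else "donor",
    target = if (inherits(target, "dh_gene")) target$name else "target",
    end = end, window_nt = window,
    identity_pct = aln$identity_pct,
    at_terminus = at_term,
    alignment = aln
  ), class = "end_identity")
}

#' @export
print.end_identity <- function(x, ...) {
  cat(sprintf("<end_identity> %s vs %s %s end: %.1f%% over %d nt%s\n",
              x$donor, x$target, sub("_prime", "'", x$end),
              x$identity_pct, x$window_nt,
              if (x$at_terminus) "" else " (not at terminus)"))
  invisible(x)
}
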