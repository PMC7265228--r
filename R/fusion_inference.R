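# Score candidate (5' donor, 3' donor) pairs for the fusion origin of a
# target D gene, combining terminal coding identities with RSS agreement.
# The module scores sequence compatibility only: fusion, gene conversion
# followed by fusion, and deletion-plus-repeat-insertion all leave the same
# terminal-identity signature and are not distinguished here.

#' Score donor pairs for a DH-DH fusion origin
#'
#' For every ordered candidate pair (d5, d3) with d5 != d3 (sharing a family
#' is allowed) the composite score is
#' `w1*prefix/100 + w2*suffix/100 + w3*(1 - rss5/28) + w4*(1 - rss3/28)`
#' where prefix/suffix are local end identities of each donor coding
#' against the target and rss5/rss3 are total RSS Hamming distances between
#' the target and the respective donor. An end identity whose alignment
#' does not constitute terminal homology evidence (flagged
#' `at_terminus = FALSE` by [end_identity()], e.g. a chance-level short
#' window) contributes 0 to its term. The list is sorted by composite
#' descending with deterministic tie-break by donor names.
#'
#' @param target A `dh_gene` with coding and both RSSs.
#' @param candidates List of `dh_gene` donors (>= 2); candidates missing an
#'   RSS are excluded with a warning.
#' @param weights Four non-negative weights (defaults 0.35/0.35/0.15/0.15).
#' @param params Local alignment parameters for the end identities.
#' @return A `fusion_ranking`: a ranked data.frame (`$table`) plus per-pair
#'   `fusion_hypothesis` details (`$hypotheses`).
#' @export
score_fusion <- function(target, candidates,
                         weights = c(0.35, 0.35, 0.15, 0.15),
                         params = align_params(mode = "local")) {
  if (length(weights) != 4L || any(weights < 0))
    ighd_usage_error("weights must be four non-negative numbers")
  keep <- vapply(candidates, function(g)
    !is.null(g$rss5) && !is.null(g$rss3) && !is.null(g$coding_seq), TRUE)
  if (any(!keep)) {
    warning(sprintf("%d candidate(s) missing an RSS excluded", sum(!keep)))
    candidates <- candidates[keep]
  }
  candidates <- candidates[vapply(candidates, `[[`, "", "name") != target$name]
  if (length(candidates) < 2L)
    ighd_usage_error("need at least two usable candidates")
  # per-candidate evidence, computed once
  ev <- lapply(candidates, function(g) list(
    prefix = end_identity(g, target, "five_prime", params),
    suffix = end_identity(g, target, "three_prime", params),
    rss5 = compare_rss(target$rss5, g$rss5)$total_diffs,
    rss3 = compare_rss(target$rss3, g$rss3)$total_diffs))
  names(ev) <- vapply(candidates, `[[`, "", "name")
  nm <- names(ev)
  rows <- list(); hyps <- list()
  for (i5 in seq_along(candidates)) {
    for (i3 in seq_along(candidates)) {
      if (i5 == i3) next
      p <- ev[[i5]]$prefix; s <- ev[[i3]]$suffix
      pid <- if (is.na(p$identity_pct) || !p$at_terminus) 0 else p$identity_pct
      sid <- if (is.na(s$identity_pct) || !s$at_terminus) 0 else s$identity_pct
      comp <- weights[1] * pid / 100 + weights[2] * sid / 100 +
        weights[3] * (1 - ev[[i5]]$rss5 / 28) +
        weights[4] * (1 - ev[[i3]]$rss3 / 28)
      bp <- breakpoint_from_ends(p, s, target)
      key <- paste(nm[i5], nm[i3], sep = "|")
      rows[[key]] <- data.frame(
        donor5 = nm[i5], donor3 = nm[i3],
        prefix_identity = pid, prefix_window = p$window_nt,
        suffix_identity = sid, suffix_window = s$window_nt,
        rss5_diffs = ev[[i5]]$rss5, rss3_diffs = ev[[i3]]$rss3,
        breakpoint_start = bp$start, breakpoint_end = bp$end,
        breakpoint_status = bp$status,
        composite = comp, stringsAsFactors = FALSE)
      hyps[[key]] <- structure(list(
        target = target$name, donor5 = nm[i5], donor3 = nm[i3],
        prefix = p, suffix = s,
        rss5_diffs = ev[[i5]]$rss5, rss3_diffs = ev[[i3]]$rss3,
        breakpoint = bp, composite = comp), class = "fusion_hypothesis")
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$composite, tab$donor5, tab$donor3)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(target = target$name, table = tab,
                 hypotheses = hyps[paste(tab$donor5, tab$donor3, sep = "|")]),
            class = "fusion_ranking")
}

#' @export
print.fusion_ranking <- function(x, ...) {
  cat(sprintf("<fusion_ranking> target %s, %d hypotheses; top: %s + %s (%.3f)\n",
              x$target, nrow(x$table), x$table$donor5[1], x$table$donor3[1],
              x$table$composite[1]))
  invisible(x)
}

breakpoint_from_ends <- function(prefix, suffix, target) {
  pa <- prefix$alignment; sa <- suffix$alignment
  if (pa$columns == 0L || sa$columns == 0L)
    return(structure(list(start = NA_integer_, end = NA_integer_,
                          status = "no-alignment"),
                     class = "breakpoint_interval"))
  e1 <- pa$span_b$end # end of prefix span on target
  s2 <- sa$span_b$start # start of suffix span on target
  if (e1 <= s2)
    structure(list(start = e1, end = s2, status = "clean"),
              class = "breakpoint_interval")
  else
    structure(list(start = s2, end = e1, status = "ambiguous-overlap"),
              class = "breakpoint_interval")
}

#' Locate the fusion breakpoint interval on a target gene
#'
#' The interval on the target coding between the end of the 5' donor's
#' prefix alignment span and the start of the 3' donor's suffix span; if the
#' spans overlap (repeats make the junction ambiguous) their intersection is
#' returned flagged `"ambiguous-overlap"`. Breakpoints are reported at
#' interval resolution, never as a single base: near-identical repeats make
#' a base-precise breakpoint unknowable.
#'
#' @param target,d5,d3 `dh_gene` objects.
#' @param params Local alignment parameters.
#' @return A `breakpoint_interval` (start/end on the target coding, status).
#' @export
locate_breakpoint <- function(target, d5, d3,
                              params = align_params(mode = "local")) {
  breakpoint_from_ends(end_identity(d5, target, "five_prime", params),
                       end_identity(d3, target, "three_prime", params),
                       target)
}

#' @export
print.breakpoint_interval <- function(x, ...) {
  cat(sprintf("<breakpoint> [%s,%s) %s\n", x$start, x$end, x$status))
  invisible(x)
}

#' Check a conserved residue between donor and target codings
#'
#' Both codings are translated in the supplied frame (default frame 1 of
#' the heptamer-delimited coding segment). Within the prefix local
#' alignment, target codons encoding `residue` are mapped to the aligned
#' donor positions; a codon is comparable when its three positions align
#' gaplessly to a donor codon in the same frame.
#'
#' @param target,donor `dh_gene` objects.
#' @param residue Single amino-acid letter (default `"C"`, the knob-domain
#'   cysteine).
#' @param frame Reading frame 1-3 on the coding segment.
#' @param params Local alignment parameters.
#' @return A list: `positions` data.frame (target codon, donor codon,
#'   residues, agreement), `shared` (any agreeing position), and
#'   `stop_in_window` flag.
#' @export
conserved_codon_check <- function(target, donor, residue = "C", frame = 1L,
                                  params = align_params(mode = "local")) {
  if (!frame %in% 1:3) ighd_usage_error("frame must be 1, 2 or 3")
  tr <- function(seqchr) {
    s <- substr(seqchr, frame, nchar(seqchr))
    s <- substr(s, 1L, 3L * (nchar(s) %/% 3L))
    if (nchar(s) < 3L) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X"))
  }
  taa <- tr(target$coding_seq); daa <- tr(donor$coding_seq)
  ei <- end_identity(donor, target, "five_prime", params)
  aln <- ei$alignment
  map <- integer(0) # target 0-based pos -> donor 0-based pos
  if (aln$columns > 0L) {
    xa <- strsplit(aln$aligned_a, "")[[1]] # donor
    xb <- strsplit(aln$aligned_b, "")[[1]] # target
    dpos <- aln$span_a$start; tpos <- aln$span_b$start
    map <- rep(NA_integer_, nchar(target$coding_seq))
    for (k in seq_along(xa)) {
      da <- xa[k] != "-"; db <- xb[k] != "-"
      if (da && db) map[tpos + 1L] <- dpos
      if (da) dpos <- dpos + 1L
      if (db) tpos <- tpos + 1L
    }
  }
  rows <- list()
  for (ci in seq_len(nchar(taa))) {
    if (substr(taa, ci, ci) != residue) next
    # 0-based coding positions of this codon
    tstart <- (frame - 1L) + 3L * (ci - 1L)
    pos <- tstart + 0:2
    if (length(map) == 0L || any(pos + 1L > length(map))) next
    d <- map[pos + 1L]
    if (any(is.na(d)) || !all(diff(d) == 1L)) next
    if ((d[1] - (frame - 1L)) %% 3L != 0L) next # donor frame disagrees
    dci <- (d[1] - (frame - 1L)) %/% 3L + 1L
    if (dci > nchar(daa)) next
    rows[[length(rows) + 1L]] <- data.frame(
      target_codon = ci, donor_codon = dci,
      target_aa = substr(taa, ci, ci), donor_aa = substr(daa, dci, dci),
      agree = substr(daa, dci, dci) == residue, stringsAsFactors = FALSE)
  }
  positions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_codon = integer(0), donor_codon = integer(0),
               target_aa = character(0), donor_aa = character(0),
               agree = logical(0), stringsAsFactors = FALSE)
  win_aa <- if (aln$columns > 0L && nchar(taa) > 0L)
    substr(taa, 1L, max(1L, aln$span_b$end %/% 3L)) else ""
  list(target = target$name, donor = donor$name, residue = residue,
       frame = frame, positions = positions,
       shared = any(positions$agree),
       stop_in_window = grepl("*", win_aa, fixed = TRUE))
}
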