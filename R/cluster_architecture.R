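# Segment the locus into D-gene clusters, map paralogs across clusters and
# detect deletions, transpositions and missing family members.

new_dh_gene <- function(name, rss5, rss3, coding, coding_seq,
                        cluster_id = NA_integer_, ordinal = NA_integer_) {
  structure(list(name = canonical_gene_name(name), cluster_id = cluster_id,
                 rss5 = rss5, rss3 = rss3, coding = coding,
                 coding_seq = coding_seq, ordinal = ordinal,
                 family = gene_family(name)),
            class = "dh_gene")
}

#' Construct a D gene from its parts
#'
#' Coding segment convention: the sequence strictly between the 5' heptamer's
#' 3' edge and the 3' heptamer's 5' edge.
#'
#' @param name Gene symbol (e.g. `"IGHD8-2"`); en-dash variants are
#'   canonicalized.
#' @param rss5,rss3 `rss_site` objects flanking the gene.
#' @param coding [interval()] of the coding segment on the parent sequence.
#' @param coding_seq Coding residues (character).
#' @param cluster_id,ordinal Position bookkeeping, optional.
#' @return A `dh_gene`.
#' @export
dh_gene <- function(name, rss5, rss3, coding, coding_seq,
                    cluster_id = NA_integer_, ordinal = NA_integer_) {
  if (!is.null(rss5) && !is.null(coding) && rss5$interval$end > coding$start)
    ighd_usage_error("5' RSS must end at or before the coding start")
  if (nchar(coding_seq) < 9L)
    ighd_usage_error("coding segment must be at least 9 nt")
  new_dh_gene(name, rss5, rss3, coding, coding_seq, cluster_id, ordinal)
}

#' @export
print.dh_gene <- function(x, ...) {
  cat(sprintf("<dh_gene> %s cluster %s coding [%d,%d) (%d nt)\n", x$name,
              x$cluster_id, x$coding$start, x$coding$end, nchar(x$coding_seq)))
  invisible(x)
}

#' Call D genes from RSS pairs
#'
#' Scans both RSS sides and pairs each 5' site with the nearest downstream
#' 3' site such that the enclosed coding segment is `min_coding`-`max_coding`
#' nt; greedy left-to-right, non-overlapping. Unpaired sites are skipped.
#'
#' @param cluster_seq A `nuc_sequence` (a cluster or a whole locus).
#' @param motif5,motif3 RSS consensus motifs.
#' @param max_heptamer_mm,max_nonamer_mm Scan mismatch maxima.
#' @param min_coding,max_coding Coding length bounds (nt).
#' @param names_table Optional data.frame (`name`, `start`, `end`) assigning
#'   symbols by overlap with the called gene footprint; unnamed genes get
#'   `"D<n>"` placeholders.
#' @return List of `dh_gene`, coordinate-sorted and non-overlapping.
#' @export
call_genes <- function(cluster_seq, motif5 = rss_motif_5p(),
                       motif3 = rss_motif_3p(),
                       max_heptamer_mm = 3L, max_nonamer_mm = 3L,
                       min_coding = 9L, max_coding = 200L,
                       names_table = NULL) {
  sites5 <- scan_rss(cluster_seq, motif5, max_heptamer_mm, max_nonamer_mm)
  sites3 <- scan_rss(cluster_seq, motif3, max_heptamer_mm, max_nonamer_mm)
  genes <- list()
  used3 <- logical(length(sites3))
  cursor <- -1L # end of the last accepted gene footprint
  starts3 <- vapply(sites3, function(s) s$interval$start, 0L)
  for (s5 in sites5) {
    if (s5$interval$start < cursor) next
    cstart <- s5$interval$end
    ok <- which(!used3 & starts3 >= cstart + min_coding &
                  starts3 <= cstart + max_coding)
    if (length(ok) == 0L) next
    k <- ok[which.min(starts3[ok])]
    s3 <- sites3[[k]]
    used3[k] <- TRUE
    coding <- interval(cstart, s3$interval$start)
    genes[[length(genes) + 1L]] <-
      new_dh_gene(sprintf("D%d", length(genes) + 1L), s5, s3, coding,
                  extract(cluster_seq, coding)$residues)
    cursor <- s3$interval$end
  }
  if (!is.null(names_table)) {
    for (i in seq_along(genes)) {
      g <- genes[[i]]
      hit <- which(names_table$start < g$rss3$interval$end &
                     names_table$end > g$rss5$interval$start)
      if (length(hit) >= 1L) {
        genes[[i]]$name <- canonical_gene_name(names_table$name[hit[1]])
        genes[[i]]$family <- gene_family(genes[[i]]$name)
      }
    }
  }
  genes
}

new_cluster <- function(cluster_id, span, genes, intergenic,
                        intergenic_seq, seq = NULL) {
  structure(list(cluster_id = cluster_id, span = span, genes = genes,
                 intergenic = intergenic, intergenic_seq = intergenic_seq,
                 seq = seq),
            class = "dh_cluster")
}

#' @export
print.dh_cluster <- function(x, ...) {
  cat(sprintf("<dh_cluster> %d: %d genes, span [%d,%d) (%d nt)\n",
              x$cluster_id, length(x$genes), x$span$start, x$span$end,
              iv_width(x$span)))
  invisible(x)
}

#' Segment called genes into clusters
#'
#' Genes separated by more than `max_intergene_gap` nt start a new cluster.
#' A cluster span runs from the first gene's 5' RSS start to the last gene's
#' 3' RSS end; intergenic intervals lie between consecutive gene footprints.
#'
#' @param locus The `nuc_sequence` the genes were called on.
#' @param genes Coordinate-sorted list of `dh_gene`.
#' @param max_intergene_gap Segmentation gap (nt); intra-cluster gaps at the
#'   bovine locus are ~300-700 nt, so any value between ~1 kb and the
#'   inter-cluster distance works.
#' @return List of `dh_cluster`; genes gain `cluster_id` and `ordinal`.
#' @export
segment_clusters <- function(locus, genes, max_intergene_gap = 2000L) {
  if (length(genes) == 0L) return(list())
  fp_start <- vapply(genes, function(g) g$rss5$interval$start, 0L)
  fp_end <- vapply(genes, function(g) g$rss3$interval$end, 0L)
  if (is.unsorted(fp_start))
    ighd_usage_error("genes must be coordinate-sorted")
  breaks <- which(fp_start[-1L] - fp_end[-length(genes)] > max_intergene_gap)
  group <- cumsum(c(1L, seq_along(genes)[-1L] %in% (breaks + 1L)))
  lapply(unique(group), function(cid) {
    idx <- which(group == cid)
    gs <- genes[idx]
    for (k in seq_along(gs)) {
      gs[[k]]$cluster_id <- cid
      gs[[k]]$ordinal <- k
    }
    span <- interval(fp_start[idx[1]], fp_end[idx[length(idx)]])
    igv <- list(); igs <- character(0)
    if (length(idx) > 1L) {
      for (k in seq_len(length(idx) - 1L)) {
        iv <- interval(fp_end[idx[k]], fp_start[idx[k + 1L]])
        igv[[k]] <- iv
        igs[k] <- extract(locus, iv)$residues
      }
    }
    new_cluster(cid, span, gs, igv, igs, seq = extract(locus, span))
  })
}

# maximum-weight assignment of rows to columns by bitmask DP (n, m <= ~12)
assign_optimal <- function(W) {
  n <- nrow(W); m <- ncol(W)
  if (m > 24L) ighd_usage_error("assignment too large")
  full <- bitwShiftL(1L, m) - 1L
  best <- rep(-Inf, full + 1L); best[1L] <- 0
  choice <- matrix(NA_integer_, nrow = n, ncol = full + 1L)
  prev_masks <- list(`0` = 0L)
  for (i in seq_len(n)) {
    new_best <- rep(-Inf, full + 1L)
    for (mask in 0:full) {
      if (!is.finite(best[mask + 1L])) next
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(mask, bit) != 0L) next
        nm <- bitwOr(mask, bit)
        v <- best[mask + 1L] + W[i, j]
        if (v > new_best[nm + 1L]) {
          new_best[nm + 1L] <- v
          choice[i, nm + 1L] <- j
        }
      }
    }
    best <- new_best
  }
  k <- which.max(best) - 1L
  pairing <- integer(n)
  for (i in rev(seq_len(n))) {
    j <- choice[i, k + 1L]
    pairing[i] <- j
    k <- bitwAnd(k, bitwNot(bitwShiftL(1L, j - 1L)))
  }
  pairing
}

# indices of matched pairs that break order monotonicity (not in the longest
# increasing subsequence of the matching permutation)
lis_outliers <- function(ord_b) {
  n <- length(ord_b)
  if (n <= 1L) return(integer(0))
  len <- rep(1L, n); prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ord_b[j] < ord_b[i] && len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L; prev[i] <- j
      }
    }
  }
  k <- which.max(len)
  keep <- integer(0)
  while (!is.na(k)) { keep <- c(k, keep); k <- prev[k] }
  setdiff(seq_len(n), keep)
}

#' Map paralogous genes between two clusters
#'
#' All-vs-all global coding identities, then an optimal assignment
#' maximizing summed identity. Pairs below `pair_floor` percent identity are
#' dropped to unmatched. Order events: unmatched genes of `b` are reported
#' as `missing_family`; matched pairs breaking order monotonicity (outside
#' the longest increasing subsequence of the matching) as `transposition`;
#' nonzero coding length differences as `length_delta`.
#'
#' @param a,b `dh_cluster` objects.
#' @param params Global alignment parameters.
#' @param pair_floor Minimum percent identity to accept a pair.
#' @return A `paralog_map`.
#' @export
map_paralogs <- function(a, b, params = align_params(), pair_floor = 70) {
  if (length(a$genes) < 1L || length(b$genes) < 1L)
    ighd_usage_error("both clusters need at least one gene")
  params$mode <- "global"
  na <- length(a$genes); nb <- length(b$genes)
  W <- matrix(0, na, nb)
  for (i in seq_len(na))
    for (j in seq_len(nb))
      W[i, j] <- align(a$genes[[i]]$coding_seq, b$genes[[j]]$coding_seq,
                       params)$identity_pct
  swap <- na > nb
  pairing <- if (swap) assign_optimal(t(W)) else assign_optimal(W)
  pairs <- if (swap) cbind(pairing, seq_len(nb)) else cbind(seq_len(na), pairing)
  idents <- W[pairs]
  ok <- idents >= pair_floor
  matched <- pairs[ok, , drop = FALSE]
  idents <- idents[ok]
  name_a <- vapply(a$genes, `[[`, "", "name")
  name_b <- vapply(b$genes, `[[`, "", "name")
  len_a <- vapply(a$genes, function(g) nchar(g$coding_seq), 0L)
  len_b <- vapply(b$genes, function(g) nchar(g$coding_seq), 0L)
  ord <- order(matched[, 1L])
  matched <- matched[ord, , drop = FALSE]; idents <- idents[ord]
  pairs_df <- data.frame(
    gene_a = name_a[matched[, 1L]], gene_b = name_b[matched[, 2L]],
    identity_pct = idents,
    length_delta = len_a[matched[, 1L]] - len_b[matched[, 2L]],
    stringsAsFactors = FALSE)
  unmatched_a <- setdiff(seq_len(na), matched[, 1L])
  unmatched_b <- setdiff(seq_len(nb), matched[, 2L])
  ev <- list()
  for (j in unmatched_b)
    ev[[length(ev) + 1L]] <- data.frame(
      type = "missing_family", gene_a = NA_character_, gene_b = name_b[j],
      detail = sprintf("no gene of cluster %d matches %s at >= %g%%",
                       a$cluster_id, name_b[j], pair_floor),
      stringsAsFactors = FALSE)
  out_of_order <- lis_outliers(matched[, 2L])
  for (k in out_of_order)
    ev[[length(ev) + 1L]] <- data.frame(
      type = "transposition", gene_a = pairs_df$gene_a[k],
      gene_b = pairs_df$gene_b[k],
      detail = "matched pair breaks cluster order", stringsAsFactors = FALSE)
  for (k in which(pairs_df$length_delta != 0L))
    ev[[length(ev) + 1L]] <- data.frame(
      type = "length_delta", gene_a = pairs_df$gene_a[k],
      gene_b = pairs_df$gene_b[k],
      detail = sprintf("%+d nt", pairs_df$length_delta[k]),
      stringsAsFactors = FALSE)
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(type = character(0), gene_a = character(0),
               gene_b = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  structure(list(cluster_a = a$cluster_id, cluster_b = b$cluster_id,
                 pairs = pairs_df,
                 unmatched_a = name_a[unmatched_a],
                 unmatched_b = name_b[unmatched_b],
                 order_events = events, identity_matrix = W),
            class = "paralog_map")
}

#' @export
print.paralog_map <- function(x, ...) {
  cat(sprintf("<paralog_map> cluster %s vs %s: %d pairs, %d/%d unmatched, %d events\n",
              x$cluster_a, x$cluster_b, nrow(x$pairs), length(x$unmatched_a),
              length(x$unmatched_b), nrow(x$order_events)))
  invisible(x)
}

#' Locate intergenic intervals of one cluster inside another
#'
#' Each intergenic interval of `b` is locally aligned into the concatenated
#' intergenic space of `a` (joined with `N` spacers, which can never match).
#' Coverage is the aligned fraction of the `b` interval, counted only when
#' the alignment is plausibly homologous (`identity_pct >= homology_floor`;
#' local alignments of unrelated DNA plateau near 60% identity under
#' +5/-4 scoring, while true paralogous intergenics here are >90%).
#' Intervals with coverage below `coverage_threshold` are flagged deleted
#' in `a`.
#'
#' @param a,b `dh_cluster` objects.
#' @param pmap A `paralog_map` linking the clusters (used for labels).
#' @param params Local alignment parameters.
#' @param coverage_threshold Deletion flag threshold (fraction).
#' @param homology_floor Minimum percent identity for an alignment to count
#'   toward coverage.
#' @return A data.frame, one row per intergenic interval of `b`.
#' @export
compare_intergenic <- function(a, b, pmap = NULL,
                               params = align_params(mode = "local"),
                               coverage_threshold = 0.30,
                               homology_floor = 80) {
  params$mode <- "local"
  if (length(b$intergenic_seq) == 0L)
    return(data.frame(index = integer(0), between = character(0),
                      length = integer(0), identity_pct = numeric(0),
                      coverage = numeric(0), deleted_in_a = logical(0)))
  target_space <- paste(a$intergenic_seq, collapse = strrep("N", 10L))
  rows <- lapply(seq_along(b$intergenic_seq), function(k) {
    iseq <- b$intergenic_seq[k]
    between <- sprintf("%s..%s", b$genes[[k]]$name, b$genes[[k + 1L]]$name)
    if (nchar(target_space) == 0L) {
      return(data.frame(index = k, between = between, length = nchar(iseq),
                        identity_pct = NA_real_, coverage = 0,
                        deleted_in_a = TRUE, stringsAsFactors = FALSE))
    }
    aln <- align(iseq, target_space, params)
    cov <- if (aln$columns == 0L || aln$identity_pct < homology_floor) 0
           else iv_width(aln$span_a) / nchar(iseq)
    data.frame(index = k, between = between, length = nchar(iseq),
               identity_pct = aln$identity_pct, coverage = cov,
               deleted_in_a = cov < coverage_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
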