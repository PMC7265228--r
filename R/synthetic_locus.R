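# Simulate the evolution of a duplicated D-gene cluster locus: duplication,
# point mutation, segmental deletion with gene fusion, transposition and
# repeat expansion, with a machine-readable truth log whose replay
# reproduces the emitted sequence exactly.

#' Simulation parameters
#'
#' Defaults emulate the bovine D-region: 3 homologous clusters of 6
#' RSS-flanked genes, ~2% divergence per duplication, hexanucleotide repeat
#' arrays, intergenic regions of 300-700 nt, one deletion-fusion, one
#' transposition (displacement >= 2 gene positions) and one repeat
#' expansion in a single designated cluster.
#'
#' @param n_genes Genes per ancestral cluster.
#' @param n_clusters Cluster copies.
#' @param mu Per-site substitution probability per duplication (0-0.2).
#' @param repeat_units Pool of repeat units sampled per gene.
#' @param expansion_geom_p Geometric parameter for extra unit copies.
#' @param expansion_max_extra Cap on extra copies (keeps fused codings
#'   below the 200 nt gene-calling ceiling).
#' @param intergenic_len_range,flank_len_range,copies_range Length ranges.
#' @param cluster_spacer_len Random spacer before each cluster copy (nt);
#'   must exceed the cluster segmentation gap.
#' @param junction_in_repeat_p Probability that each deletion endpoint lies
#'   inside the donor gene's repeat array (exercises breakpoint ambiguity).
#' @param events Character subset of
#'   `c("deletion_fusion","transposition","repeat_expansion")`.
#' @param fusion_gene_index 1-based index i of the 5' fusion donor in the
#'   designated cluster; the 3' donor is gene i+1.
#' @param target_cluster Which cluster copy receives the scripted events.
#' @param mutate_rss If `FALSE` (default) RSS footprints are protected from
#'   substitution.
#' @param seed Optional seed consumed by [simulate_locus()].
#' @return A `sim_params` object.
#' @export
sim_params <- function(n_genes = 6L, n_clusters = 3L, mu = 0.02,
                       repeat_units = c("TGGTTA", "GGTTAT", "TGGTAT",
                                        "GGTATT"),
                       expansion_geom_p = 0.5, expansion_max_extra = 6L,
                       intergenic_len_range = c(300L, 700L),
                       flank_len_range = c(25L, 40L),
                       copies_range = c(2L, 8L),
                       cluster_spacer_len = 2500L,
                       junction_in_repeat_p = 0.5,
                       events = c("deletion_fusion", "transposition",
                                  "repeat_expansion"),
                       fusion_gene_index = 3L,
                       target_cluster = 1L,
                       mutate_rss = FALSE, seed = NULL) {
  if (mu < 0 || mu > 0.2) ighd_usage_error("mu must lie in [0, 0.2]")
  if (n_genes < 2L) ighd_usage_error("need n_genes >= 2")
  if (n_clusters < 1L) ighd_usage_error("need n_clusters >= 1")
  if (any(c(intergenic_len_range, flank_len_range, copies_range) <= 0))
    ighd_usage_error("all ranges must be positive")
  if ("deletion_fusion" %in% events &&
      (fusion_gene_index < 1L || fusion_gene_index + 1L > n_genes))
    ighd_usage_error("fusion_gene_index and its successor must be in 1..n_genes")
  if (target_cluster < 1L || target_cluster > n_clusters)
    ighd_usage_error("target_cluster out of range")
  structure(list(n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters), mu = mu,
                 repeat_units = toupper(repeat_units),
                 expansion_geom_p = expansion_geom_p,
                 expansion_max_extra = as.integer(expansion_max_extra),
                 intergenic_len_range = as.integer(intergenic_len_range),
                 flank_len_range = as.integer(flank_len_range),
                 copies_range = as.integer(copies_range),
                 cluster_spacer_len = as.integer(cluster_spacer_len),
                 junction_in_repeat_p = junction_in_repeat_p,
                 events = events,
                 fusion_gene_index = as.integer(fusion_gene_index),
                 target_cluster = as.integer(target_cluster),
                 mutate_rss = isTRUE(mutate_rss), seed = seed),
            class = "sim_params")
}

SIM_RSS5_NONAMER <- "GGTTTCTGA"
SIM_RSS5_HEPTAMER <- "CACGGTG"
SIM_RSS3_HEPTAMER <- "CACAGTG"
SIM_RSS3_NONAMER <- "ACAAAAACC"

rand_int <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)

#' Simulate an ancestral D-gene cluster
#'
#' One cluster of `n_genes` RSS-flanked genes; each coding region is a
#' sampled tandem repeat array (2-8 copies of a hexamer-class unit) between
#' unique flanks. RSS elements are the planted consensus strings with
#' random 12-nt spacers.
#'
#' @param params A [sim_params()] object (its `seed` is NOT consumed here;
#'   use [simulate_locus()] for the seeded end-to-end run).
#' @return List with `seq` (a `nuc_sequence`) and `truth` (gene table and
#'   empty event list).
#' @export
simulate_ancestor <- function(params = sim_params()) {
  n <- params$n_genes
  parts <- character(0)
  rows <- list()
  cursor <- 0L
  for (g in seq_len(n)) {
    rss5 <- paste0(SIM_RSS5_NONAMER, random_dna(12L), SIM_RSS5_HEPTAMER)
    unit <- sample(params$repeat_units, 1L)
    copies <- rand_int(params$copies_range[1], params$copies_range[2])
    arr <- strrep(unit, copies)
    fl <- random_dna(rand_int(params$flank_len_range[1],
                              params$flank_len_range[2]))
    fr <- random_dna(rand_int(params$flank_len_range[1],
                              params$flank_len_range[2]))
    # guard the array boundaries so the planted copy number is exact
    L <- nchar(unit)
    if (substr(fl, nchar(fl), nchar(fl)) == substr(unit, L, L))
      substr(fl, nchar(fl), nchar(fl)) <-
        setdiff(c("A", "C", "G", "T"), substr(unit, L, L))[1]
    if (substr(fr, 1, 1) == substr(unit, 1, 1))
      substr(fr, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                  substr(unit, 1, 1))[1]
    coding <- paste0(fl, arr, fr)
    rss3 <- paste0(SIM_RSS3_HEPTAMER, random_dna(12L), SIM_RSS3_NONAMER)
    ig <- if (g < n) random_dna(rand_int(params$intergenic_len_range[1],
                                         params$intergenic_len_range[2]))
          else ""
    r5s <- cursor
    cs <- r5s + 28L
    ce <- cs + nchar(coding)
    r3e <- ce + 28L
    rows[[g]] <- data.frame(
      family = g, name = sprintf("pIGHD%d", g),
      r5s = r5s, r5e = cs, cs = cs, ce = ce, r3s = ce, r3e = r3e,
      unit = unit, copies = copies,
      array_start = cs + nchar(fl), array_end = cs + nchar(fl) + nchar(arr),
      stringsAsFactors = FALSE)
    parts <- c(parts, rss5, coding, rss3, ig)
    cursor <- r3e + nchar(ig)
  }
  genes <- do.call(rbind, rows)
  list(seq = nuc_sequence(paste(parts, collapse = ""), id = "ancestor",
                          source = "simulate_ancestor"),
       truth = list(events = list(), genes = genes))
}

shift_pt <- function(pt, at, delta) ifelse(pt >= at, pt + delta, pt)

shift_cols <- function(df, at, delta) {
  for (col in c("r5s", "r5e", "cs", "ce", "r3s", "r3e",
                "array_start", "array_end"))
    df[[col]] <- shift_pt(df[[col]], at, delta)
  df
}

str_delete <- function(s, start, end) {
  paste0(substr(s, 1L, start), substr(s, end + 1L, nchar(s)))
}

str_insert <- function(s, at, ins) {
  paste0(substr(s, 1L, at), ins, substr(s, at + 1L, nchar(s)))
}

#' Evolve an ancestral cluster into a multi-cluster locus
#'
#' Duplicates the ancestor `n_clusters` times (each copy preceded by a
#' random spacer) with i.i.d. substitutions at rate `mu` (RSS footprints
#' protected unless `mutate_rss`), then applies the scripted events to the
#' designated cluster: a deletion from inside gene i's coding to inside
#' gene i+1's coding that fuses them while preserving gene i's 5' RSS and
#' gene i+1's 3' RSS; one gene transposition (displacement >= 2); and a
#' repeat expansion at the fusion junction. Every edit is logged with
#' enough detail for exact replay.
#'
#' @param ancestor Result of [simulate_ancestor()].
#' @param params A [sim_params()].
#' @return List with `seq` (the locus), `truth` (events, per-cluster gene
#'   tables, scripted-event ground truth) and `annotations`.
#' @export
evolve <- function(ancestor, params = sim_params()) {
  anc <- ancestor$seq$residues
  anc_genes <- ancestor$truth$genes
  L <- nchar(anc)
  protected <- logical(L)
  if (!params$mutate_rss) {
    for (k in seq_len(nrow(anc_genes))) {
      protected[(anc_genes$r5s[k] + 1L):anc_genes$r5e[k]] <- TRUE
      protected[(anc_genes$r3s[k] + 1L):anc_genes$r3e[k]] <- TRUE
    }
  }
  events <- list()
  locus <- ""
  tabs <- list()
  for (cl in seq_len(params$n_clusters)) {
    spacer <- random_dna(params$cluster_spacer_len)
    off <- nchar(locus) + nchar(spacer)
    copy <- anc
    pos <- which(runif(L) < params$mu & !protected)
    ref <- alt <- character(length(pos))
    if (length(pos) > 0L) {
      for (q in seq_along(pos)) {
        ref[q] <- substr(copy, pos[q], pos[q])
        alt[q] <- sample(setdiff(c("A", "C", "G", "T"), ref[q]), 1L)
        substr(copy, pos[q], pos[q]) <- alt[q]
      }
    }
    events[[length(events) + 1L]] <-
      list(type = "duplication", cluster = cl, spacer = spacer, at = off)
    events[[length(events) + 1L]] <-
      list(type = "substitution_batch", cluster = cl,
           positions = off + pos - 1L, ref = ref, alt = alt)
    tab <- anc_genes
    tab <- shift_cols(tab, 0L, off)
    tab$cluster <- cl
    tab$name <- sprintf("IGHD%d-%d", tab$family, cl)
    tabs[[cl]] <- tab
    locus <- paste0(locus, spacer, copy)
  }
  genes <- do.call(rbind, tabs)
  tc <- params$target_cluster
  truth_fusion <- NULL; truth_transposition <- NULL; truth_expansion <- NULL
  junction <- NA_integer_

  if ("deletion_fusion" %in% params$events) {
    idx <- which(genes$cluster == tc)
    i <- idx[params$fusion_gene_index]; j <- idx[params$fusion_gene_index + 1L]
    pick_point <- function(row) {
      if (runif(1) < params$junction_in_repeat_p &&
          row$array_end - row$array_start > 2L)
        rand_int(row$array_start + 1L, row$array_end - 1L)
      else {
        w <- row$ce - row$cs
        rand_int(row$cs + w %/% 4L, row$cs + (3L * w) %/% 4L)
      }
    }
    d1 <- pick_point(genes[i, ]); d2 <- pick_point(genes[j, ])
    dlen <- d2 - d1
    locus <- str_delete(locus, d1, d2)
    fused_name <- sprintf("IGHD%d-%d", params$n_genes + 2L, tc)
    fused <- genes[i, ]
    fused$name <- fused_name
    fused$family <- params$n_genes + 2L
    fused$ce <- genes$ce[j] - dlen
    fused$r3s <- genes$r3s[j] - dlen
    fused$r3e <- genes$r3e[j] - dlen
    fused$copies <- NA_integer_
    fused$array_end <- min(fused$array_end, d1) # array may be truncated
    genes <- genes[-c(i, j), , drop = FALSE]
    genes <- shift_cols(genes, d2, -dlen)
    genes <- rbind(genes, fused)
    genes <- genes[order(genes$r5s), , drop = FALSE]
    junction <- d1
    events[[length(events) + 1L]] <-
      list(type = "deletion_fusion", start = d1, end = d2,
           gene5 = sprintf("IGHD%d-%d", params$fusion_gene_index, tc),
           gene3 = sprintf("IGHD%d-%d", params$fusion_gene_index + 1L, tc),
           fused = fused_name)
    truth_fusion <- list(
      fused_name = fused_name,
      donor5_family = params$fusion_gene_index,
      donor3_family = params$fusion_gene_index + 1L,
      junction_coding = d1 - fused$cs,
      deleted_intergenic_ordinal = params$fusion_gene_index,
      cluster = tc)
  }

  if ("transposition" %in% params$events) {
    idx <- which(genes$cluster == tc)
    n_tc <- length(idx)
    fused_nm <- if (!is.null(truth_fusion)) truth_fusion$fused_name else ""
    # movable: not the fused gene, not the last gene (its trailing
    # intergenic travels with it)
    movable <- idx[seq_len(n_tc - 1L)]
    movable <- movable[genes$name[movable] != fused_nm]
    choices <- list()
    for (t in movable) {
      o_t <- match(t, idx)
      for (k in seq_len(n_tc)) {
        tgt <- idx[k]
        if (tgt == t) next
        new_ord <- if (k < o_t) k else k - 1L
        if (k == o_t + 1L) next # reinsertion in place
        if (abs(new_ord - o_t) >= 2L)
          choices[[length(choices) + 1L]] <- c(t, tgt, o_t, new_ord)
      }
    }
    if (length(choices) > 0L) {
      pick <- choices[[sample.int(length(choices), 1L)]]
      t <- pick[1]; tgt <- pick[2]
      moved_name <- genes$name[t]
      nxt <- idx[match(t, idx) + 1L]
      blk_s <- genes$r5s[t]; blk_e <- genes$r5s[nxt]
      cut_len <- blk_e - blk_s
      block <- substr(locus, blk_s + 1L, blk_e)
      p <- genes$r5s[tgt]
      if (p >= blk_e) p <- p - cut_len
      locus <- str_delete(locus, blk_s, blk_e)
      locus <- str_insert(locus, p, block)
      in_block <- genes$r5s >= blk_s & genes$r5s < blk_e
      moved_delta <- p - blk_s
      for (col in c("r5s", "r5e", "cs", "ce", "r3s", "r3e",
                    "array_start", "array_end")) {
        v <- genes[[col]]
        # non-block coords: close the cut, then make room at p
        v_nb <- shift_pt(shift_pt(v, blk_e, -cut_len), p, cut_len)
        genes[[col]] <- ifelse(in_block, v + moved_delta, v_nb)
      }
      genes <- genes[order(genes$r5s), , drop = FALSE]
      if (!is.na(junction)) {
        junction <- shift_pt(junction, blk_e, -cut_len)
        junction <- shift_pt(junction, p, cut_len)
      }
      events[[length(events) + 1L]] <-
        list(type = "transposition", gene = moved_name,
             from_start = blk_s, from_end = blk_e, to = p)
      truth_transposition <- list(gene = moved_name,
                                  family = gene_family(moved_name),
                                  old_ordinal = pick[3], new_ordinal = pick[4],
                                  displacement = pick[4] - pick[3])
    }
  }

  if ("repeat_expansion" %in% params$events && !is.null(truth_fusion)) {
    frow <- which(genes$name == truth_fusion$fused_name)
    unit <- genes$unit[frow]
    n_extra <- min(1L + rgeom(1L, params$expansion_geom_p),
                   params$expansion_max_extra)
    ins <- strrep(unit, n_extra)
    at <- junction
    locus <- str_insert(locus, at, ins)
    genes <- shift_cols(genes, at, nchar(ins))
    events[[length(events) + 1L]] <-
      list(type = "repeat_expansion", gene = truth_fusion$fused_name,
           at = at, inserted = ins, unit = unit, extra_copies = n_extra)
    truth_expansion <- list(gene = truth_fusion$fused_name, unit = unit,
                            extra_copies = n_extra, at = at,
                            inserted_len = nchar(ins))
    truth_fusion$junction_interval_coding <-
      c(truth_fusion$junction_coding,
        truth_fusion$junction_coding + nchar(ins))
  } else if (!is.null(truth_fusion)) {
    truth_fusion$junction_interval_coding <-
      rep(truth_fusion$junction_coding, 2L)
  }

  ann <- build_sim_annotations(genes, "synthetic_locus")
  truth <- list(events = events, genes = genes,
                final_annotations = ann,
                scripted = list(fusion = truth_fusion,
                                transposition = truth_transposition,
                                expansion = truth_expansion),
                n_clusters = params$n_clusters,
                target_cluster = tc)
  list(seq = nuc_sequence(locus, id = "synthetic_locus",
                          source = "ighdarch::evolve"),
       truth = truth)
}

build_sim_annotations <- function(genes, seqid) {
  rows <- list()
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = seqid,
      name = rep(g$name, 4L),
      start = c(g$r5s, g$r5s, g$cs, g$r3s),
      end = c(g$r3e, g$r5e, g$ce, g$r3e),
      strand = "+",
      feature_type = c("gene", "rss5", "coding", "rss3"),
      stringsAsFactors = FALSE)
  }
  for (cl in sort(unique(genes$cluster))) {
    sub <- genes[genes$cluster == cl, ]
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = seqid, name = sprintf("cluster_%d", cl),
      start = min(sub$r5s), end = max(sub$r3e), strand = "+",
      feature_type = "cluster", stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  annotation_frame(df$seqid, df$name, df$start, df$end, df$strand,
                   df$feature_type)
}

#' Seeded end-to-end simulation
#'
#' Sets the seed once, builds the ancestor and evolves it. Identical seeds
#' give byte-identical loci and truth logs.
#'
#' @param params A [sim_params()]; `params$seed` drives all randomness.
#' @return As [evolve()], plus `ancestor`.
#' @export
simulate_locus <- function(params = sim_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  anc <- simulate_ancestor(params)
  out <- evolve(anc, params)
  out$ancestor <- anc
  out
}

#' Replay a truth log against the ancestral sequence
#'
#' Applies the logged events, in order, to the ancestral cluster sequence.
#' The result must equal the emitted locus exactly (the truth-log
#' invariant).
#'
#' @param ancestor_seq The ancestral `nuc_sequence` (or residues).
#' @param truth A truth log from [evolve()] (or re-read by
#'   [read_truth()]).
#' @return A `nuc_sequence`.
#' @export
replay_truth <- function(ancestor_seq, truth) {
  anc <- as_residues(ancestor_seq)
  locus <- ""
  for (ev in truth$events) {
    if (ev$type == "duplication") {
      locus <- paste0(locus, ev$spacer, anc)
    } else if (ev$type == "substitution_batch") {
      pos <- ev$positions
      for (q in seq_along(pos))
        substr(locus, pos[q] + 1L, pos[q] + 1L) <- ev$alt[q]
    } else if (ev$type == "deletion_fusion") {
      locus <- str_delete(locus, ev$start, ev$end)
    } else if (ev$type == "transposition") {
      block <- substr(locus, ev$from_start + 1L, ev$from_end)
      locus <- str_delete(locus, ev$from_start, ev$from_end)
      locus <- str_insert(locus, ev$to, block)
    } else if (ev$type == "repeat_expansion") {
      locus <- str_insert(locus, ev$at, ev$inserted)
    } else {
      ighd_usage_error(sprintf("unknown event type '%s'", ev$type))
    }
  }
  nuc_sequence(locus, id = "replayed_locus", source = "replay_truth")
}

#' Emit a simulated locus to files
#'
#' Writes `locus.fasta`, `annotations.bed` and `truth.json` under
#' `out_dir`.
#'
#' @param sim Result of [simulate_locus()] / [evolve()].
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
emit <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(out_dir, "locus.fasta")
  bed <- file.path(out_dir, "annotations.bed")
  js <- file.path(out_dir, "truth.json")
  res <- sim$seq$residues
  lines <- substring(res, seq(1, nchar(res), 70),
                     pmin(seq(1, nchar(res), 70) + 69, nchar(res)))
  writeLines(c(sprintf(">%s", sim$seq$id), lines), fa)
  write_annotations(sim$truth$final_annotations, bed, "bed")
  truth_out <- sim$truth
  truth_out$genes <- NULL # data.frame bookkeeping; annotations carry coords
  truth_out$ancestor_residues <- if (!is.null(sim$ancestor))
    sim$ancestor$seq$residues else NULL
  jsonlite::write_json(truth_out, js, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(fasta = fa, bed = bed, truth = js))
}

#' Re-read an emitted truth log
#'
#' @param path Path to `truth.json`.
#' @return A truth list usable by [replay_truth()].
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = FALSE)
  truth$events <- lapply(truth$events, function(ev) {
    for (f in c("at", "start", "end", "from_start", "from_end", "to",
                "extra_copies", "cluster"))
      if (!is.null(ev[[f]])) ev[[f]] <- as.integer(ev[[f]])
    if (!is.null(ev$positions))
      ev$positions <- vapply(ev$positions, as.integer, 0L)
    if (!is.null(ev$ref)) ev$ref <- vapply(ev$ref, as.character, "")
    if (!is.null(ev$alt)) ev$alt <- vapply(ev$alt, as.character, "")
    ev
  })
  truth
}
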