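# Recombination signal sequence (RSS) model: heptamer + 12-bp spacer +
# nonamer, on the top strand. At a D gene the 5' RSS reads
# nonamer-spacer-heptamer along the top strand (heptamer adjacent to the
# coding region) and the 3' RSS reads heptamer-spacer-nonamer.

RSS_FOOTPRINT <- 28L # 7 + 12 + 9

#' RSS motif consensus
#'
#' @param heptamer 7-mer consensus.
#' @param nonamer 9-mer consensus.
#' @param spacer_len Spacer length in nt (12 for D-gene RSSs).
#' @param side `"five_prime"` or `"three_prime"`.
#' @return An `rss_motif`.
#' @export
rss_motif <- function(heptamer, nonamer, spacer_len = 12L,
                      side = c("three_prime", "five_prime")) {
  side <- match.arg(side)
  heptamer <- toupper(heptamer); nonamer <- toupper(nonamer)
  if (nchar(heptamer) != 7L || nchar(nonamer) != 9L)
    ighd_usage_error("heptamer must be 7 nt and nonamer 9 nt")
  if (spacer_len != 12L)
    ighd_usage_error("D-gene RSS spacers are 12 nt")
  structure(list(heptamer = heptamer, nonamer = nonamer,
                 spacer_len = as.integer(spacer_len), side = side),
            class = "rss_motif")
}

#' Default 3' RSS consensus (canonical CACAGTG heptamer)
#' @return An `rss_motif`.
#' @export
rss_motif_3p <- function() rss_motif("CACAGTG", "ACAAAAACC", 12L, "three_prime")

#' Default 5' RSS consensus (column-wise majority of the bovine D-gene table)
#' @return An `rss_motif`.
#' @export
rss_motif_5p <- function() rss_motif("CACGGTG", "GGTTTCTGA", 12L, "five_prime")

#' Construct an RSS site from its element strings
#'
#' Mismatch counts are taken against the default consensus for the side.
#'
#' @param heptamer,spacer,nonamer Element strings (7/12/9 nt).
#' @param side `"five_prime"` or `"three_prime"`.
#' @param iv Footprint [interval()] (placeholder `[0,28)` by default).
#' @return An `rss_site`.
#' @export
rss_site <- function(heptamer, spacer, nonamer,
                     side = c("three_prime", "five_prime"),
                     iv = interval(0L, 28L)) {
  side <- match.arg(side)
  heptamer <- toupper(heptamer); spacer <- toupper(spacer)
  nonamer <- toupper(nonamer)
  if (nchar(heptamer) != 7L || nchar(spacer) != 12L || nchar(nonamer) != 9L)
    ighd_usage_error("RSS elements must be 7, 12 and 9 nt")
  motif <- if (side == "three_prime") rss_motif_3p() else rss_motif_5p()
  new_rss_site(iv, heptamer, spacer, nonamer,
               hamming(heptamer, motif$heptamer),
               hamming(nonamer, motif$nonamer), side)
}

new_rss_site <- function(iv, heptamer, spacer, nonamer, hmm, nmm, side) {
  structure(list(interval = iv, heptamer = heptamer, spacer = spacer,
                 nonamer = nonamer, heptamer_mismatches = hmm,
                 nonamer_mismatches = nmm, side = side),
            class = "rss_site")
}

#' @export
print.rss_site <- function(x, ...) {
  cat(sprintf("<rss_site> %s [%d,%d) %s %s %s (mm %d/%d)\n", x$side,
              x$interval$start, x$interval$end,
              tolower(if (x$side == "five_prime") x$nonamer else x$heptamer),
              tolower(x$spacer),
              tolower(if (x$side == "five_prime") x$heptamer else x$nonamer),
              x$heptamer_mismatches, x$nonamer_mismatches))
  invisible(x)
}

#' Scan a sequence for RSS motifs
#'
#' Reports every 28-nt footprint whose heptamer and nonamer windows are
#' within the mismatch maxima; the 12-nt spacer is unconstrained in sequence.
#' Only the top strand is scanned, in the element orders stated above.
#'
#' @param seq A `nuc_sequence`.
#' @param motif An [rss_motif()].
#' @param max_heptamer_mm,max_nonamer_mm Mismatch maxima (defaults 3 and 3:
#'   the tightest setting under which every published bovine D-gene RSS is
#'   within range of the majority consensus -- the IGHD5 5' heptamer
#'   `tgtggtg` sits 3 mismatches from `CACGGTG`).
#' @return List of `rss_site`, in coordinate order. A sequence shorter than
#'   28 nt yields an empty list.
#' @export
scan_rss <- function(seq, motif, max_heptamer_mm = 3L, max_nonamer_mm = 3L) {
  res <- as_residues(seq)
  if (nchar(res) < RSS_FOOTPRINT) return(list())
  subject <- Biostrings::DNAString(res)
  hept_hits <- Biostrings::matchPattern(motif$heptamer, subject,
                                        max.mismatch = max_heptamer_mm)
  non_hits <- Biostrings::matchPattern(motif$nonamer, subject,
                                       max.mismatch = max_nonamer_mm)
  h0 <- BiocGenerics::start(hept_hits) - 1L # 0-based starts
  n0 <- BiocGenerics::start(non_hits) - 1L
  # footprint start as a function of element starts
  if (motif$side == "three_prime") {
    starts <- intersect(h0, n0 - 19L) # heptamer at 0, nonamer at 19
  } else {
    starts <- intersect(n0, h0 - 21L) # nonamer at 0, heptamer at 21
  }
  starts <- sort(starts)
  starts <- starts[starts + RSS_FOOTPRINT <= nchar(res)]
  lapply(starts, function(s) {
    foot <- substr(res, s + 1L, s + RSS_FOOTPRINT)
    if (motif$side == "three_prime") {
      hept <- substr(foot, 1, 7); spacer <- substr(foot, 8, 19)
      non <- substr(foot, 20, 28)
    } else {
      non <- substr(foot, 1, 9); spacer <- substr(foot, 10, 21)
      hept <- substr(foot, 22, 28)
    }
    new_rss_site(interval(s, s + RSS_FOOTPRINT), hept, spacer, non,
                 hamming(hept, motif$heptamer), hamming(non, motif$nonamer),
                 motif$side)
  })
}

#' Compare two RSS sites element-wise
#'
#' Per-element Hamming distances (heptamer, spacer, nonamer) and their sum.
#' Both sites must be on the same side.
#'
#' @param a,b `rss_site` objects.
#' @return An `rss_comparison`.
#' @export
compare_rss <- function(a, b) {
  if (!inherits(a, "rss_site") || !inherits(b, "rss_site"))
    ighd_usage_error("compare_rss expects rss_site objects")
  if (a$side != b$side)
    ighd_usage_error("compare_rss: sites are on different sides")
  hd <- hamming(a$heptamer, b$heptamer)
  sd <- hamming(a$spacer, b$spacer)
  nd <- hamming(a$nonamer, b$nonamer)
  structure(list(site_a = a, site_b = b, heptamer_diffs = hd,
                 spacer_diffs = sd, nonamer_diffs = nd,
                 total_diffs = hd + sd + nd),
            class = "rss_comparison")
}

#' Tabulate the RSSs of a set of D genes
#'
#' One row per gene in deterministic order (cluster, then position):
#' name, cluster, 5' nonamer/spacer/heptamer, 3' heptamer/spacer/nonamer,
#' lowercase. Genes missing an RSS get `"."` markers and a warning.
#'
#' @param genes List of `dh_gene`.
#' @return A data.frame.
#' @export
rss_table <- function(genes) {
  cols <- c("gene", "cluster", "rss5_nonamer", "rss5_spacer", "rss5_heptamer",
            "rss3_heptamer", "rss3_spacer", "rss3_nonamer")
  if (length(genes) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    df$cluster <- integer(0)
    return(df)
  }
  rows <- lapply(genes, function(g) {
    r5 <- g$rss5; r3 <- g$rss3
    if (is.null(r5) || is.null(r3))
      warning(sprintf("gene %s is missing an RSS", g$name))
    data.frame(
      gene = g$name,
      cluster = g$cluster_id %||% NA_integer_,
      rss5_nonamer = if (is.null(r5)) "." else tolower(r5$nonamer),
      rss5_spacer = if (is.null(r5)) "." else tolower(r5$spacer),
      rss5_heptamer = if (is.null(r5)) "." else tolower(r5$heptamer),
      rss3_heptamer = if (is.null(r3)) "." else tolower(r3$heptamer),
      rss3_spacer = if (is.null(r3)) "." else tolower(r3$spacer),
      rss3_nonamer = if (is.null(r3)) "." else tolower(r3$nonamer),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ord <- order(df$cluster, vapply(genes, function(g)
    if (!is.null(g$coding)) g$coding$start else g$ordinal %||% 0L, 0L))
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Published bovine D-gene RSS fixture
#'
#' The 16 RSS rows for *Bos taurus* IGHD genes of clusters 2-4 (5' and 3'
#' nonamer/spacer/heptamer strings), packaged as a plain-text fixture.
#'
#' @return A data.frame with columns gene, cluster and the six RSS elements.
#' @export
ighd_rss_fixture <- function() {
  path <- system.file("extdata", "bovine_dh_rss.tsv", package = "ighdarch")
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  df$gene <- canonical_gene_name(df$gene)
  df
}

#' RSS fixture as paired `rss_site` objects
#'
#' @return Named list (by gene) of lists with elements `rss5` and `rss3`.
#'   Site intervals are placeholders (`[0,28)`) since the fixture carries no
#'   locus coordinates.
#' @export
ighd_rss_sites <- function() {
  df <- ighd_rss_fixture()
  m5 <- rss_motif_5p(); m3 <- rss_motif_3p()
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    h5 <- toupper(r$rss5_heptamer); n5 <- toupper(r$rss5_nonamer)
    h3 <- toupper(r$rss3_heptamer); n3 <- toupper(r$rss3_nonamer)
    list(
      rss5 = new_rss_site(interval(0L, 28L), h5, toupper(r$rss5_spacer), n5,
                          hamming(h5, m5$heptamer), hamming(n5, m5$nonamer),
                          "five_prime"),
      rss3 = new_rss_site(interval(0L, 28L), h3, toupper(r$rss3_spacer), n3,
                          hamming(h3, m3$heptamer), hamming(n3, m3$nonamer),
                          "three_prime"),
      cluster = r$cluster)
  })
  names(out) <- df$gene
  out
}
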