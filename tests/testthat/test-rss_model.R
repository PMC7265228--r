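test_that("the packaged bovine RSS table parses into well-formed site pairs", {
  fx <- ighd_rss_fixture()
  expect_equal(nrow(fx), 17L) # clusters 2-4; families 3 and 7 lack cluster 2
  sites <- ighd_rss_sites()
  for (g in names(sites)) {
    expect_equal(nchar(sites[[g]]$rss5$spacer), 12L)
    expect_equal(nchar(sites[[g]]$rss3$spacer), 12L)
    expect_equal(nchar(sites[[g]]$rss5$heptamer), 7L)
    expect_equal(nchar(sites[[g]]$rss3$nonamer), 9L)
  }
  # every 3' heptamer is the canonical cacagtg
  expect_true(all(tolower(fx$rss3_heptamer) == "cacagtg"))
})

test_that("default consensus motifs equal the column-wise majority of the table", {
  fx <- ighd_rss_fixture()
  maj <- function(x) names(sort(table(toupper(x)), decreasing = TRUE))[1]
  expect_equal(rss_motif_5p()$heptamer, maj(fx$rss5_heptamer))
  expect_equal(rss_motif_5p()$nonamer, maj(fx$rss5_nonamer))
  expect_equal(rss_motif_3p()$heptamer, maj(fx$rss3_heptamer))
  expect_equal(rss_motif_3p()$nonamer, maj(fx$rss3_nonamer))
  # the default mismatch maxima admit every published site (IGHD5's 5'
  # heptamer tgtggtg sits exactly 3 away from the majority consensus)
  h_mm <- vapply(fx$rss5_heptamer, function(h)
    oracle_hamming(toupper(h), rss_motif_5p()$heptamer), 0)
  n_mm <- vapply(fx$rss5_nonamer, function(x)
    oracle_hamming(toupper(x), rss_motif_5p()$nonamer), 0)
  expect_true(all(h_mm <= 3) && max(h_mm) == 3)
  expect_true(all(n_mm <= 3))
})

test_that("RSS relationships match the published architecture", {
  s <- ighd_rss_sites()
  # the ultralong gene's 3' RSS is identical to the family-7 genes
  expect_equal(compare_rss(s[["IGHD8-2"]]$rss3, s[["IGHD7-3"]]$rss3)$total_diffs, 0L)
  expect_equal(compare_rss(s[["IGHD8-2"]]$rss3, s[["IGHD7-4"]]$rss3)$total_diffs, 0L)
  # its 5' RSS shares identity with family 3 and family 6
  expect_equal(compare_rss(s[["IGHD8-2"]]$rss5, s[["IGHD3-3"]]$rss5)$total_diffs, 0L)
  expect_equal(compare_rss(s[["IGHD8-2"]]$rss5, s[["IGHD6-2"]]$rss5)$total_diffs, 0L)
  expect_equal(compare_rss(s[["IGHD8-2"]]$rss5, s[["IGHD6-3"]]$rss5)$total_diffs, 1L)
})

test_that("scan_rss finds planted motifs and nothing else", {
  set.seed(5)
  m3 <- rss_motif_3p()
  planted <- paste0(rnd_dna(30), m3$heptamer, rnd_dna(12), m3$nonamer,
                    rnd_dna(30))
  hits <- scan_rss(nuc_sequence(planted), m3, 0L, 0L)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$interval$start, 30L)
  expect_equal(hits[[1]]$interval$end, 58L)
  expect_equal(hits[[1]]$heptamer, m3$heptamer)
  expect_length(scan_rss(nuc_sequence(strrep("A", 100)), m3, 0L, 0L), 0L)
  expect_length(scan_rss(nuc_sequence("ACGT"), m3, 0L, 0L), 0L) # short input
})

test_that("scan_rss at zero mismatches equals the direct-window oracle", {
  set.seed(101)
  for (k in 1:12) {
    m <- if (k %% 2 == 0) rss_motif_3p() else rss_motif_5p()
    res <- rnd_dna(2000)
    if (k <= 8) { # plant 1-3 motifs so positives occur
      for (p in sample(seq(0, 1900, by = 150), sample(1:3, 1))) {
        ins <- if (m$side == "three_prime")
          paste0(m$heptamer, rnd_dna(12), m$nonamer)
        else paste0(m$nonamer, rnd_dna(12), m$heptamer)
        substr(res, p + 1, p + 28) <- ins
      }
    }
    got <- vapply(scan_rss(nuc_sequence(res), m, 0L, 0L),
                  function(s) s$interval$start, 0L)
    expect_equal(got, oracle_scan_rss0(res, m))
  }
})

test_that("compare_rss is a per-element Hamming metric", {
  a <- rss_site("CACAGTG", "ACTCAGGCCCTG", "ACATAAAGT")
  expect_equal(compare_rss(a, a)$total_diffs, 0L)
  set.seed(33)
  for (k in 1:20) {
    x <- rss_site(rnd_dna(7), rnd_dna(12), rnd_dna(9))
    y <- rss_site(rnd_dna(7), rnd_dna(12), rnd_dna(9))
    z <- rss_site(rnd_dna(7), rnd_dna(12), rnd_dna(9))
    cxy <- compare_rss(x, y)
    expect_equal(cxy$heptamer_diffs, oracle_hamming(x$heptamer, y$heptamer))
    expect_equal(cxy$spacer_diffs, oracle_hamming(x$spacer, y$spacer))
    expect_equal(cxy$nonamer_diffs, oracle_hamming(x$nonamer, y$nonamer))
    expect_equal(cxy$total_diffs,
                 cxy$heptamer_diffs + cxy$spacer_diffs + cxy$nonamer_diffs)
    # symmetry and triangle inequality
    expect_equal(cxy$total_diffs, compare_rss(y, x)$total_diffs)
    expect_lte(cxy$total_diffs,
               compare_rss(x, z)$total_diffs + compare_rss(z, y)$total_diffs)
  }
  b5 <- rss_site("CACGGTG", "TGCCGGCTGTGT", "GGTTTCTGA", "five_prime")
  expect_error(compare_rss(a, b5), "different sides")
})

test_that("rss_table mirrors the published row layout", {
  s <- ighd_rss_sites()
  genes <- lapply(c("IGHD1-2", "IGHD8-2", "IGHD5-2"), function(nm)
    make_gene(nm, rnd_dna(30), rss5 = s[[nm]]$rss5, rss3 = s[[nm]]$rss3,
              cluster_id = s[[nm]]$cluster))
  tab <- rss_table(genes)
  row <- tab[tab$gene == "IGHD1-2", ]
  expect_equal(row$rss5_nonamer, "ggattttga")
  expect_equal(row$rss5_spacer, "gggtgtgcgtgt")
  expect_equal(row$rss5_heptamer, "caccctg")
  expect_equal(row$rss3_heptamer, "cacagtg")
  # empty input gives a header-only table
  empty <- rss_table(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("gene", "cluster", "rss5_nonamer", "rss3_nonamer") %in%
                    names(empty)))
  # a gene missing an RSS is reported with markers, not dropped
  g <- make_gene("IGHD9-1", rnd_dna(30))
  g$rss3 <- NULL
  expect_warning(tab2 <- rss_table(list(g)), "missing an RSS")
  expect_equal(tab2$rss3_heptamer, ".")
})

test_that("every scanned footprint is 28 nt and decomposes as 7+12+9", {
  set.seed(9)
  sim <- simulate_locus(sim_params(seed = 9, n_clusters = 1,
                                   events = character(0)))
  for (m in list(rss_motif_5p(), rss_motif_3p())) {
    for (h in scan_rss(sim$seq, m, 0L, 0L)) {
      expect_equal(h$interval$end - h$interval$start, 28L)
      expect_equal(nchar(h$heptamer) + nchar(h$spacer) + nchar(h$nonamer), 28L)
    }
  }
})
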