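# candidates with unrelated codings plus a target built by concatenating
# the (entire) coding of one donor with the coding of another: the donors
# are exhausted at the junction, so the end identities are exactly 100 and
# the junction is sharp
build_fusion_world <- function(seed = 101, n = 4) {
  set.seed(seed)
  cands <- lapply(seq_len(n), function(k)
    make_gene(sprintf("IGHD%d-3", k), rnd_dna(95),
              rss5 = rss_site(CONS5$heptamer, rnd_dna(12), CONS5$nonamer,
                              "five_prime"),
              rss3 = rss_site(CONS3$heptamer, rnd_dna(12), CONS3$nonamer,
                              "three_prime")))
  d5 <- cands[[2]]; d3 <- cands[[3]]
  target <- make_gene("IGHD8-2",
                      paste0(d5$coding_seq, d3$coding_seq),
                      rss5 = d5$rss5, rss3 = d3$rss3)
  list(target = target, candidates = cands, d5 = d5, d3 = d3,
       junction = nchar(d5$coding_seq))
}

test_that("a constructed fusion is recovered with perfect end identities", {
  w <- build_fusion_world()
  rk <- score_fusion(w$target, w$candidates)
  top <- rk$table[1, ]
  expect_equal(top$donor5, w$d5$name)
  expect_equal(top$donor3, w$d3$name)
  expect_equal(top$prefix_identity, 100)
  expect_equal(top$suffix_identity, 100)
  expect_equal(top$rss5_diffs, 0L)
  expect_equal(top$rss3_diffs, 0L)
  # strict maximality of the true pair
  expect_gt(top$composite, max(rk$table$composite[-1]))
})

test_that("the composite is the documented weighted sum and is monotone", {
  w <- build_fusion_world(seed = 103)
  weights <- c(0.35, 0.35, 0.15, 0.15)
  rk <- score_fusion(w$target, w$candidates, weights)
  tab <- rk$table
  # recompute from the row components (flagged ends contribute zero, which
  # shows up as a 0 in the identity columns only when at_terminus is FALSE;
  # validate through the hypotheses list)
  for (k in seq_len(nrow(tab))) {
    h <- rk$hypotheses[[paste(tab$donor5[k], tab$donor3[k], sep = "|")]]
    pid <- if (h$prefix$at_terminus) h$prefix$identity_pct else 0
    sid <- if (h$suffix$at_terminus) h$suffix$identity_pct else 0
    expect_equal(tab$composite[k],
                 weights[1] * pid / 100 + weights[2] * sid / 100 +
                   weights[3] * (1 - tab$rss5_diffs[k] / 28) +
                   weights[4] * (1 - tab$rss3_diffs[k] / 28))
  }
  # monotone non-decreasing in each component of the formula
  f <- function(p, s, r5, r3) weights[1] * p / 100 + weights[2] * s / 100 +
    weights[3] * (1 - r5 / 28) + weights[4] * (1 - r3 / 28)
  base <- f(80, 70, 5, 9)
  expect_gte(f(90, 70, 5, 9), base)
  expect_gte(f(80, 80, 5, 9), base)
  expect_gte(f(80, 70, 3, 9), base)
  expect_gte(f(80, 70, 5, 2), base)
})

test_that("ranking is invariant to candidate input order", {
  w <- build_fusion_world(seed = 107)
  rk1 <- score_fusion(w$target, w$candidates)
  set.seed(1)
  rk2 <- score_fusion(w$target, sample(w$candidates))
  expect_equal(rk1$table$donor5, rk2$table$donor5)
  expect_equal(rk1$table$donor3, rk2$table$donor3)
  expect_equal(rk1$table$composite, rk2$table$composite)
})

test_that("candidates missing an RSS are excluded with a warning", {
  w <- build_fusion_world(seed = 109)
  broken <- w$candidates
  broken[[1]]$rss5 <- NULL
  expect_warning(rk <- score_fusion(w$target, broken), "missing an RSS")
  expect_false(broken[[1]]$name %in%
                 c(rk$table$donor5, rk$table$donor3))
  expect_error(suppressWarnings(score_fusion(w$target, broken[1:2])),
               "at least two")
})

test_that("breakpoints are clean at exact junctions and widen inside repeats", {
  w <- build_fusion_world(seed = 113)
  bp <- locate_breakpoint(w$target, w$d5, w$d3)
  expect_equal(bp$status, "clean")
  expect_equal(bp$start, w$junction)
  expect_equal(bp$end, w$junction) # width-0 interval at the exact junction
  # shared repeat at the junction makes the breakpoint ambiguous
  set.seed(113)
  unit <- "TGGTTA"
  dA <- make_gene("IGHD2-3", paste0(rnd_dna(40), strrep(unit, 4)))
  dB <- make_gene("IGHD3-3", paste0(strrep(unit, 4), rnd_dna(40)))
  tgt <- make_gene("IGHD8-2", paste0(substr(dA$coding_seq, 1, 52),
                                     substr(dB$coding_seq, 13, 64)))
  bp2 <- locate_breakpoint(tgt, dA, dB)
  expect_equal(bp2$status, "ambiguous-overlap")
  expect_true(bp2$start <= 52 && 52 <= bp2$end + 12) # junction in/near overlap
})

test_that("conserved residue checks compare aligned codons in frame", {
  set.seed(127)
  core <- paste0("ATG", "TGT", "GGT", "TAT", "AGT", "GGC", "TGC", "TAC",
                 "GGA", "TCC") # C at codons 2 and 7
  donor <- make_gene("IGHD6-3", core)
  target <- make_gene("IGHD8-2", core)
  same <- conserved_codon_check(target, donor, "C", 1L)
  expect_true(same$shared)
  expect_true(all(same$positions$agree))
  expect_equal(same$positions$target_codon, c(2L, 7L))
  # mutate the first cysteine codon of the donor (TGT -> AGT, C -> S)
  mut <- core
  substr(mut, 4, 4) <- "A"
  donor2 <- make_gene("IGHD6-3", mut)
  res <- conserved_codon_check(target, donor2, "C", 1L)
  row <- res$positions[res$positions$target_codon == 2L, ]
  expect_false(row$agree)
  expect_equal(row$donor_aa, "S")
  expect_error(conserved_codon_check(target, donor, "C", 5L), "frame")
})

test_that("donor recovery holds across simulated loci", {
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_locus(sim_params(seed = 900 + s))
    rec <- recover_locus(sim)
    rk <- score_fusion(rec$fused, rec$reference$genes)
    refnames <- vapply(rec$reference$genes, `[[`, "", "name")
    tf <- sim$truth$scripted$fusion
    top <- rk$table[1, ]
    if (match(top$donor5, refnames) == tf$donor5_family &&
        match(top$donor3, refnames) == tf$donor3_family) hits <- hits + 1
  }
  expect_gte(hits, 9L)
})
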