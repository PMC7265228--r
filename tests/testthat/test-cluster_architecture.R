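test_that("call_genes recovers planted genes at planted coordinates", {
  sim <- simulate_locus(sim_params(seed = 3, n_clusters = 1,
                                   events = character(0)))
  genes <- call_genes(sim$seq, max_heptamer_mm = 0L, max_nonamer_mm = 0L)
  truth <- sim$truth$genes
  expect_length(genes, nrow(truth))
  for (k in seq_along(genes)) {
    expect_equal(genes[[k]]$coding$start, truth$cs[k])
    expect_equal(genes[[k]]$coding$end, truth$ce[k])
    expect_equal(genes[[k]]$rss5$interval$start, truth$r5s[k])
  }
  # non-overlapping and coordinate-sorted
  fp <- t(vapply(genes, function(g)
    c(g$rss5$interval$start, g$rss3$interval$end), c(0L, 0L)))
  expect_true(all(diff(fp[, 1]) > 0))
  expect_true(all(fp[-nrow(fp), 2] <= fp[-1, 1]))
})

test_that("call_genes takes names from a coordinate table", {
  sim <- simulate_locus(sim_params(seed = 4, n_clusters = 1,
                                   events = character(0)))
  truth <- sim$truth$genes
  nt <- data.frame(name = sprintf("IGHD%d-9", truth$family),
                   start = truth$r5s, end = truth$r3e)
  genes <- call_genes(sim$seq, max_heptamer_mm = 0L, max_nonamer_mm = 0L,
                      names_table = nt)
  expect_equal(vapply(genes, `[[`, "", "name"), nt$name)
  expect_equal(vapply(genes, `[[`, 0L, "family"), truth$family)
})

test_that("segment_clusters applies the gap rule and span convention", {
  sim <- simulate_locus(sim_params(seed = 6, events = character(0)))
  genes <- call_genes(sim$seq, max_heptamer_mm = 0L, max_nonamer_mm = 0L)
  clusters <- segment_clusters(sim$seq, genes)
  expect_length(clusters, 3L)
  for (cl in clusters) {
    gs <- cl$genes
    expect_equal(cl$span$start, gs[[1]]$rss5$interval$start)
    expect_equal(cl$span$end, gs[[length(gs)]]$rss3$interval$end)
    expect_length(cl$intergenic, length(gs) - 1L)
    # total span = gene footprints + intergenic lengths
    foot <- sum(vapply(gs, function(g)
      g$rss3$interval$end - g$rss5$interval$start, 0L))
    ig <- sum(vapply(cl$intergenic, function(x) x$end - x$start, 0L))
    expect_equal(foot + ig, cl$span$end - cl$span$start)
    expect_equal(vapply(gs, `[[`, 0L, "ordinal"), seq_along(gs))
  }
  # one isolated gene forms a single-gene cluster with no intergenic
  one <- clusters[[1]]$genes[[1]]
  solo <- segment_clusters(sim$seq, list(one))
  expect_length(solo, 1L)
  expect_length(solo[[1]]$intergenic, 0L)
})

test_that("optimal assignment equals brute-force permutation search", {
  set.seed(17)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  for (k in 1:10) {
    n <- sample(2:5, 1); m <- sample(n:6, 1)
    W <- matrix(runif(n * m), n, m)
    got <- ighdarch:::assign_optimal(W)
    best <- -Inf
    for (p in perms(seq_len(m))) {
      v <- sum(W[cbind(seq_len(n), p[seq_len(n)])])
      if (v > best) best <- v
    }
    expect_equal(sum(W[cbind(seq_len(n), got)]), best)
    expect_equal(anyDuplicated(got), 0L)
  }
})

test_that("a cluster mapped against itself is the identity matching", {
  sim <- simulate_locus(sim_params(seed = 8, events = character(0)))
  cl <- recover_locus(sim)$clusters[[1]]
  pm <- map_paralogs(cl, cl)
  expect_equal(nrow(pm$pairs), length(cl$genes))
  expect_true(all(pm$pairs$identity_pct == 100))
  expect_true(all(pm$pairs$gene_a == pm$pairs$gene_b))
  expect_equal(nrow(pm$order_events), 0L)
  expect_length(pm$unmatched_a, 0L)
})

test_that("an isolated scripted transposition is reported as exactly that event", {
  hits <- 0
  for (s in 1:8) {
    sim <- simulate_locus(sim_params(seed = 300 + s,
                                     events = "transposition"))
    rec <- recover_locus(sim)
    pm <- map_paralogs(rec$target, rec$reference)
    ev <- pm$order_events[pm$order_events$type == "transposition", ]
    moved_fam <- sim$truth$scripted$transposition$family
    # the moved gene pairs with the reference gene at its family ordinal
    ref_names <- vapply(rec$reference$genes, `[[`, "", "name")
    expect_equal(nrow(ev), 1L)
    if (nrow(ev) == 1L && ev$gene_b == ref_names[moved_fam]) hits <- hits + 1
    expect_equal(nrow(pm$order_events[pm$order_events$type == "missing_family", ]), 0L)
  }
  expect_equal(hits, 8L)
})

test_that("an isolated scripted deletion-fusion flags the right intergenic interval", {
  for (s in 1:5) {
    sim <- simulate_locus(sim_params(seed = 400 + s,
                                     events = "deletion_fusion"))
    rec <- recover_locus(sim)
    ig <- compare_intergenic(rec$target, rec$reference)
    del_ord <- sim$truth$scripted$fusion$deleted_intergenic_ordinal
    expect_true(ig$deleted_in_a[del_ord])
    expect_true(all(ig$coverage[-del_ord] > 0.9)) # the others are conserved
  }
})

test_that("identical clusters show full intergenic coverage", {
  sim <- simulate_locus(sim_params(seed = 12, mu = 0, events = character(0)))
  rec <- recover_locus(sim)
  ig <- compare_intergenic(rec$clusters[[1]], rec$clusters[[2]])
  expect_true(all(ig$coverage >= 0.999))
  expect_true(all(!ig$deleted_in_a))
  expect_true(all(ig$identity_pct > 99.9))
})

test_that("length deltas are reported per matched pair", {
  sim <- simulate_locus(sim_params(seed = 14, events = c("deletion_fusion",
                                                         "repeat_expansion")))
  rec <- recover_locus(sim)
  pm <- map_paralogs(rec$target, rec$reference)
  ld <- pm$order_events[pm$order_events$type == "length_delta", ]
  # unequal coding lengths between true paralogs are rare at mu=0.02 with
  # substitution-only divergence, so deltas only arise from scripted events
  expect_true(all(abs(as.integer(sub(" nt", "", ld$detail))) > 0) ||
                nrow(ld) == 0L)
  expect_equal(pm$pairs$length_delta,
               vapply(seq_len(nrow(pm$pairs)), function(i) {
                 ga <- Filter(function(g) g$name == pm$pairs$gene_a[i],
                              rec$target$genes)[[1]]
                 gb <- Filter(function(g) g$name == pm$pairs$gene_b[i],
                              rec$reference$genes)[[1]]
                 nchar(ga$coding_seq) - nchar(gb$coding_seq)
               }, 0L))
})
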