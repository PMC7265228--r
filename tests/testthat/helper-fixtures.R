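# In-code fixtures: D genes assembled from explicit parts, and the shared
# recovery pipeline used by synthetic-locus tests.

CONS5 <- list(nonamer = "GGTTTCTGA", spacer = "TGCCGGCTGTGT",
              heptamer = "CACGGTG")
CONS3 <- list(heptamer = "CACAGTG", spacer = "ATACTCTCTGGG",
              nonamer = "ACAAAAACC")

make_gene <- function(name, coding,
                      rss5 = rss_site(CONS5$heptamer, CONS5$spacer,
                                      CONS5$nonamer, "five_prime"),
                      rss3 = rss_site(CONS3$heptamer, CONS3$spacer,
                                      CONS3$nonamer, "three_prime"),
                      cluster_id = 1L, ordinal = NA_integer_) {
  dh_gene(name, rss5, rss3,
          coding = interval(28L, 28L + nchar(coding)),
          coding_seq = toupper(coding),
          cluster_id = cluster_id, ordinal = ordinal)
}

# annotate a simulated locus and return the pieces the recovery tests need
recover_locus <- function(sim) {
  genes <- call_genes(sim$seq, max_heptamer_mm = 0L, max_nonamer_mm = 0L)
  clusters <- segment_clusters(sim$seq, genes)
  tc <- sim$truth$target_cluster
  ref_idx <- if (tc == 1L) 2L else 1L
  fused <- NULL
  tf <- sim$truth$scripted$fusion
  if (!is.null(tf)) {
    ann <- sim$truth$final_annotations
    frow <- ann[ann$name == tf$fused_name & ann$feature_type == "coding", ]
    for (g in clusters[[tc]]$genes)
      if (g$coding$start == frow$start[1]) fused <- g
  }
  list(genes = genes, clusters = clusters, target = clusters[[tc]],
       reference = clusters[[ref_idx]], fused = fused)
}
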