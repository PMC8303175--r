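test_that("scale factors follow the per-million and match-max rules", {
  totals <- c(A = 2e6, B = 5e5)
  expect_equal(scale_factors(totals, "match_max"), c(A = 1, B = 4))
  expect_equal(scale_factors(totals, "per_million"), c(A = 0.5, B = 2))
  # per-million conservation: scaled integral is 1e6 for every library
  expect_equal(unname(totals * scale_factors(totals, "per_million")),
               c(1e6, 1e6))
  expect_equal(unname(scale_factors(c(X = 123), "match_max")), 1)
  expect_error(scale_factors(c(A = 0, B = 10)), "positive")
})

test_that("site signal sums the strand-matched window", {
  t <- mk_track(data.frame(strand = "+", pos = 98:102, count = c(0, 2, 5, 1, 0) + 1),
                len = 1000L)
  # counts at 98..102 are 1,3,6,2,1
  expect_equal(site_signal(t, "chr", "+", 100, halfwidth = 2), 13)
  expect_equal(site_signal(t, "chr", "+", 100, halfwidth = 0), 6)
  expect_equal(site_signal(t, "chr", "-", 100, halfwidth = 2), 0)
  expect_equal(site_signal(empty_track(), "chr", "+", 100), 0)
})

test_that("differential sites flag sign-discordant fold changes beyond the floor", {
  genes <- gene_model("g1", "chr", 1000, 1999, "+")
  ann <- mk_annot("t1", "g1", D = 50, position = 1500)
  base <- data.frame(strand = "+", pos = 1000:1999, count = 8)
  mk <- function(site_count, gene_count) {
    df <- base; df$count <- gene_count
    df$count[df$pos %in% 1498:1502] <- site_count
    mk_track(df, len = 10000L)
  }
  # site drops while the gene quadruples: discordant
  d <- differential_sites(mk(40, 8), mk(15, 32), ann, genes)
  expect_true(d$discordant)
  expect_lt(d$log2fc_site, 0)
  expect_gt(d$log2fc_gene, 1)
  # concordant movement is not flagged
  d2 <- differential_sites(mk(10, 8), mk(40, 32), ann, genes)
  expect_false(d2$discordant)
  # both zero: pseudocount gives log2fc 0, concordant
  empty_a <- empty_track(len = 10000L)
  d0 <- differential_sites(empty_a, empty_a, ann, genes)
  expect_equal(d0$log2fc_site, 0)
  expect_false(d0$discordant)
  # sub-floor discordance is not flagged
  d3 <- differential_sites(mk(40, 8), mk(30, 11), ann, genes,
                           effect_floor = 1)
  expect_false(d3$discordant)
})

test_that("differential fold changes are scale invariant and swap antisymmetric", {
  genes <- gene_model("g1", "chr", 1000, 1999, "+")
  ann <- mk_annot("t1", "g1", D = 50, position = 1500)
  df_a <- data.frame(strand = "+", pos = 1000:1999, count = 10)
  df_b <- data.frame(strand = "+", pos = 1000:1999, count = 25)
  ta <- mk_track(df_a, len = 10000L); tb <- mk_track(df_b, len = 10000L)
  d <- differential_sites(ta, tb, ann, genes, pseudocount = 1e-6)
  d_scaled <- differential_sites(scale_track(ta, 7), scale_track(tb, 7),
                                 ann, genes, pseudocount = 1e-6)
  expect_equal(d_scaled$log2fc_site, d$log2fc_site, tolerance = 1e-6)
  expect_equal(d_scaled$log2fc_gene, d$log2fc_gene, tolerance = 1e-6)
  swap <- differential_sites(tb, ta, ann, genes, pseudocount = 1e-6)
  expect_equal(swap$log2fc_site, -d$log2fc_site, tolerance = 1e-9)
  expect_equal(swap$discordant, d$discordant)
})

test_that("ribo peak calling finds spikes and applies the tie rule", {
  flat <- coverage_track(data.frame(replicon = "chr", strand = "+",
                                    pos = 1:2000, depth = 10))
  expect_equal(nrow(call_ribo_peaks(flat)), 0L)
  spike_df <- data.frame(replicon = "chr", strand = "+", pos = 1:2000,
                         depth = 10)
  spike_df$depth[1000] <- 100
  one <- call_ribo_peaks(coverage_track(spike_df))
  expect_equal(one$position, 1000)
  expect_equal(one$height, 100)
  expect_gte(one$z_score, 2)
  # two equal adjacent maxima: leftmost reported
  two_df <- spike_df; two_df$depth[1001] <- 100
  two <- call_ribo_peaks(coverage_track(two_df))
  expect_equal(two$position, 1000)
  # below min_height never a peak
  low_df <- data.frame(replicon = "chr", strand = "+", pos = 1:2000, depth = 1)
  low_df$depth[500] <- 4
  expect_equal(nrow(call_ribo_peaks(coverage_track(low_df))), 0L)
})

test_that("overlap fraction counts summit-adjacent sites", {
  sites <- data.frame(tps_id = sprintf("t%d", 1:244), replicon = "chr",
                      strand = "+", position = (1:244) * 100)
  peaks <- data.frame(replicon = "chr", strand = "+",
                      position = (1:157) * 100 + 7, height = 50, z_score = 5)
  ov <- overlap_fraction(sites, peaks, adjacency = 10)
  expect_equal(ov$n_overlapping, 157L)
  expect_equal(ov$fraction, 157 / 244)
  expect_equal(ov$percent, 64)
  # adjacency 0 with a summit 1 nt away does not overlap
  near <- data.frame(tps_id = "t", replicon = "chr", strand = "+",
                     position = 100)
  pk <- data.frame(replicon = "chr", strand = "+", position = 101,
                   height = 50, z_score = 5)
  expect_equal(overlap_fraction(near, pk, adjacency = 0)$n_overlapping, 0L)
  expect_equal(overlap_fraction(near, pk, adjacency = 1)$n_overlapping, 1L)
  # empty site list: explicit empty result
  ov0 <- overlap_fraction(sites[0, ], peaks)
  expect_true(is.na(ov0$fraction))
  expect_equal(ov0$n_total, 0L)
})

test_that("synthetic ribo peaks at every planted site give overlap 1", {
  design <- sim_design(n_genes = 15, replicon_length = 40000, seed = 17)
  genes <- generate_annotation(design)
  truth <- plant_truth(genes, tps_per_gene = 1, tss_per_gene = 0, seed = 17)
  rs <- simulate_riboseq(genes, truth, peak_fraction = 1, peak_height = 60,
                         base = 5, seed = 17)
  peaks <- call_ribo_peaks(rs$coverage, window = 60)
  sites <- data.frame(tps_id = truth$locus_tag, replicon = truth$replicon,
                      strand = truth$strand, position = truth$position)
  ov <- overlap_fraction(sites, peaks, adjacency = 10)
  expect_equal(ov$fraction, 1)
})
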