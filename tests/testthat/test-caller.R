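test_that("local background is the winsorized window mean with a floor", {
  cfg <- caller_config()
  zero <- empty_track(len = 5000L)
  expect_equal(local_background(zero, "chr", "+", 2500, cfg), 0.01)
  # 1000 window positions all count 2 -> lambda = 2
  flat <- mk_track(data.frame(strand = "+", pos = 2000:3001, count = 2),
                   len = 5000L)
  expect_equal(local_background(flat, "chr", "+", 2500, cfg), 2)
  # a single spike among zeros is winsorized to the 97.5% quantile (= 0)
  spike <- mk_track(data.frame(strand = "+", pos = c(2400, 2500),
                               count = c(1000, 50)), len = 5000L)
  expect_equal(local_background(spike, "chr", "+", 2500, cfg), 0.01)
  # the focal position itself is excluded from its own background
  expect_equal(local_background(spike, "chr", "+", 2400, cfg),
               local_background(spike, "chr", "+", 2600, cfg))
  # window truncation at the replicon edge is not an error
  expect_equal(local_background(flat, "chr", "+", 1, cfg), 0.01)
  expect_equal(local_background(flat, "chr", "+", 4999, cfg), 0.01)
})

test_that("identical tracks yield no candidates", {
  t <- mk_track(data.frame(strand = "+", pos = c(100, 200), count = c(50, 80)),
                len = 2000L)
  tp <- t; tp$meta$treatment <- "TEX_PLUS"
  cand <- scan_positions(t, tp)
  expect_equal(nrow(cand), 0L)
})

test_that("a planted depletion site is called at the planted position", {
  fx <- recovery_fixture(n_genes = 10, len = 30000, mu = 50, seed = 11)
  calls <- call_sites(fx$tm, fx$tp)
  expect_equal(nrow(calls), 10L)
  truth <- fx$truth[order(fx$truth$strand, fx$truth$position), ]
  for (i in seq_len(nrow(calls))) {
    dists <- abs(truth$position[truth$strand == calls$strand[i]] -
                   calls$position[i])
    expect_lte(min(dists), 2)
  }
  expect_true(all(calls$p_value < 1e-9))
  expect_true(all(calls$n_minus >= 10))
})

test_that("replicon present in only one track is skipped with a warning", {
  a <- mk_track(data.frame(replicon = "chr1", strand = "+", pos = 100,
                           count = 50), len = 1000L, replicon = "chr1")
  b <- mk_track(data.frame(replicon = "chr2", strand = "+", pos = 100,
                           count = 1), len = 1000L, replicon = "chr2",
                treatment = "TEX_PLUS")
  expect_warning(cand <- scan_positions(a, b), "only one track")
  expect_equal(nrow(cand), 0L)
})

test_that("clustering chains candidates within the gap and is idempotent", {
  cfg <- caller_config()
  cand <- data.frame(replicon = "chr", strand = "+",
                     pos = c(1000, 1003, 1008, 1020),
                     n_minus = c(12, 30, 12, 15), n_plus = 0,
                     lambda_minus = 0.1, lambda_plus = 0.1,
                     d_obs = c(12, 30, 12, 15),
                     p_value = c(1e-12, 1e-30, 1e-12, 1e-15))
  calls <- cluster_candidates(cand, cfg)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$members, c("1000,1003,1008", "1020"))
  expect_equal(calls$position, c(1003, 1020))  # max favored count wins
  expect_equal(calls$p_value, c(1e-30, 1e-15))
  expect_equal(calls$tps_id, c("TPS_chr_+_1003", "TPS_chr_+_1020"))
  # ties break toward the 5'-most member relative to the strand
  tie <- data.frame(replicon = "chr", strand = c("+", "+", "-", "-"),
                    pos = c(10, 12, 50, 52), n_minus = 20, n_plus = 0,
                    lambda_minus = 0.1, lambda_plus = 0.1, d_obs = 20,
                    p_value = 1e-20)
  tcalls <- cluster_candidates(tie, cfg)
  expect_equal(tcalls$position[tcalls$strand == "+"], 10)
  expect_equal(tcalls$position[tcalls$strand == "-"], 52)
  # idempotence: clustering the representatives returns them unchanged
  rep_cand <- as.data.frame(calls)
  rep_cand$pos <- rep_cand$position
  rep_cand <- rep_cand[, c("replicon", "strand", "pos", "n_minus", "n_plus",
                           "lambda_minus", "lambda_plus", "d_obs", "p_value")]
  again <- cluster_candidates(rep_cand, cfg)
  expect_equal(again$position, calls$position)
  expect_equal(again$tps_id, calls$tps_id)
  # single candidate is its own representative
  single <- cluster_candidates(cand[2, ], cfg)
  expect_equal(single$members, "1003")
})

test_that("mode duality: TSS-only truth yields TSS calls and no TPS calls", {
  design <- sim_design(n_genes = 10, replicon_length = 30000, lambda_bg = 1,
                       tss_enrichment = 30, tss_minus_fraction = 0.2,
                       seed = 13)
  genes <- generate_annotation(design)
  truth <- plant_truth(genes, tps_per_gene = 0, tss_per_gene = 1,
                       strength = 10, seed = 13)
  tm <- simulate_library(truth, design, "TEX_MINUS", seed = 13)
  tp <- simulate_library(truth, design, "TEX_PLUS", seed = 13)
  tps <- call_sites(tm, tp, caller_config(mode = "TPS"))
  tss <- call_sites(tm, tp, caller_config(mode = "TSS"))
  expect_equal(nrow(tps), 0L)
  expect_gte(nrow(tss), 9L)
  truth_pos <- truth$position
  for (i in seq_len(nrow(tss))) {
    expect_lte(min(abs(truth_pos - tss$position[i])), 2)
  }
  expect_match(tss$tps_id[1], "^TSS_")
})

test_that("BED export caps scores and preserves coordinates", {
  fx <- recovery_fixture(n_genes = 3, len = 20000, mu = 60, seed = 21)
  calls <- call_sites(fx$tm, fx$tp)
  bed <- tempfile(fileext = ".bed")
  write_tps_bed(calls, bed)
  lines <- strsplit(readLines(bed), "\t")
  expect_true(all(lengths(lines) == 6L))
  score <- as.numeric(vapply(lines, `[[`, character(1), 5))
  expect_true(all(score <= 300 & score > 9))
  start0 <- as.integer(vapply(lines, `[[`, character(1), 2))
  expect_equal(start0, calls$position - 1L)
})
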