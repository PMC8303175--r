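# shared fixtures, built in code

# minimal track from a compact spec: data.frame(replicon, strand, pos, count)
mk_track <- function(df, len = 100000L, replicon = "chr",
                     treatment = "TEX_MINUS", id = "t") {
  if (is.null(df$replicon)) df$replicon <- replicon
  read_start_track(df, seqlengths = stats::setNames(len, unique(df$replicon)),
                   library_id = id, treatment = treatment)
}

empty_track <- function(treatment = "TEX_MINUS", len = 1000L,
                        replicon = "chr") {
  read_start_track(
    data.frame(replicon = character(0), strand = character(0),
               pos = integer(0), count = numeric(0)),
    seqlengths = stats::setNames(len, replicon), treatment = treatment)
}

# independent Skellam oracle: truncated enumeration of the joint Poisson
# grid in log space; P(N1 - N2 >= d). Truncation keeps all but < 1e-15 of
# the joint mass plus every pair contributing to the tail near d.
oracle_skellam_sf <- function(d, l1, l2) {
  n2_max <- max(stats::qpois(1e-16, l2, lower.tail = FALSE) + 20L, 20L)
  n1_max <- max(stats::qpois(1e-16, l1, lower.tail = FALSE) + 20L,
                d + n2_max + 20L, 20L)
  n1 <- 0:n1_max
  n2 <- 0:n2_max
  lp <- outer(stats::dpois(n1, l1, log = TRUE),
              stats::dpois(n2, l2, log = TRUE), `+`)
  sel <- outer(n1, n2, `-`) >= d
  v <- lp[sel]
  if (length(v) == 0L) return(0)
  m <- max(v)
  min(exp(m + log(sum(exp(v - m)))), 1)
}

# hand-built 3-read SAM fixture; returns the SAM path
write_sam_fixture <- function(path = tempfile(fileext = ".sam")) {
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr\tLN:5000",
    # forward primary read, spans 1001-1030
    "r1\t0\tchr\t1001\t60\t30M\t*\t0\t0\t*\t*",
    # reverse primary read, spans 1001-1030 -> 5' end at 1030
    "r2\t16\tchr\t1001\t60\t30M\t*\t0\t0\t*\t*",
    # forward read with soft clip: counted at first aligned base 2001
    "r3\t0\tchr\t2001\t60\t5S25M\t*\t0\t0\t*\t*",
    # secondary alignment (flag 256): skipped by default
    "r3\t256\tchr\t3001\t60\t25M\t*\t0\t0\t*\t*",
    # second-in-pair (flag 131 = paired,proper,R2): dropped when r1_only
    "r4\t131\tchr\t4001\t60\t30M\t*\t0\t0\t*\t*",
    # low mapq forward read
    "r5\t0\tchr\t4501\t5\t30M\t*\t0\t0\t*\t*")
  writeLines(lines, path)
  path
}

# small deterministic simulated study used by several caller tests
recovery_fixture <- function(n_genes = 20, len = 50000, mu = 30, seed = 7) {
  design <- sim_design(n_genes = n_genes, replicon_length = len,
                       lambda_bg = 1, seed = seed)
  genes <- generate_annotation(design)
  truth <- plant_truth(genes, tps_per_gene = 1, tss_per_gene = 0,
                       strength = mu, seed = seed)
  list(design = design, genes = genes, truth = truth,
       tm = simulate_library(truth, design, "TEX_MINUS", seed = seed),
       tp = simulate_library(truth, design, "TEX_PLUS", seed = seed))
}

# annotation row builder for comparative-layer tests
mk_annot <- function(tps_id, locus_tag, orientation = "sense", D = 50,
                     replicon = "chr", strand = "+", position = 100,
                     p_value = 1e-12) {
  df <- data.frame(tps_id = tps_id, locus_tag = locus_tag,
                   orientation = orientation, replicon = replicon,
                   strand = strand, position = position, D = D,
                   p_value = p_value, stringsAsFactors = FALSE)
  df$category <- position_category(df$D)
  class(df) <- c("tps_annotation", "data.frame")
  df
}
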