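test_that("GFF3 annotations load with strand-aware CDS anchors", {
  design <- sim_design(n_genes = 10, replicon_length = 30000, seed = 2)
  gff <- tempfile(fileext = ".gff3")
  genes <- generate_annotation(design, gff_path = gff)
  loaded <- load_annotation(gff)
  expect_equal(loaded, genes)
  fwd <- loaded[loaded$strand == "+", ][1, ]
  expect_equal(fwd$x_cds_start, fwd$start)
  expect_equal(fwd$x_cds_end, fwd$end)
  rev_ <- loaded[loaded$strand == "-", ][1, ]
  expect_equal(rev_$x_cds_start, rev_$end)
  expect_equal(rev_$x_cds_end, rev_$start)
  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_equal(nrow(load_annotation(empty)), 0L)
})

test_that("normalized position D spans 0 at start codon to 100 at last base", {
  g <- gene_model("g1", "chr", 101, 300, "+")
  expect_equal(normalized_position(g, 101), 0)
  expect_equal(normalized_position(g, 300), 100)
  expect_equal(normalized_position(g, 151), 100 * 50 / 199)
  r <- gene_model("g2", "chr", 101, 300, "-")
  expect_equal(normalized_position(r, 300), 0)
  expect_equal(normalized_position(r, 101), 100)
  # mirror: position 250 on the reverse gene equals 151 on the forward one
  expect_equal(normalized_position(r, 250), normalized_position(g, 151))
  # out-of-bounds coordinates map to D < 0 and D > 100
  expect_lt(normalized_position(g, 90), 0)
  expect_gt(normalized_position(g, 310), 100)
  expect_lt(normalized_position(r, 310), 0)
})

test_that("D categories partition the axis with proximal-inclusive bounds", {
  D <- c(-0.001, 0, 25, 25.001, 74.999, 75, 100, 100.001)
  got <- as.character(position_category(D))
  expect_equal(got, c("UPSTREAM", "START_PROXIMAL", "START_PROXIMAL",
                      "INTERNAL", "INTERNAL", "STOP_PROXIMAL",
                      "STOP_PROXIMAL", "DOWNSTREAM"))
  # every finite D maps to exactly one category
  grid <- seq(-50, 150, by = 0.37)
  expect_false(anyNA(position_category(grid)))
})

test_that("strand mirror leaves D values and categories unchanged", {
  design <- sim_design(n_genes = 15, replicon_length = 40000, seed = 6)
  genes <- generate_annotation(design)
  truth <- plant_truth(genes, tps_per_gene = 1, tss_per_gene = 0, seed = 6)
  gi <- match(truth$locus_tag, genes$locus_tag)
  D <- normalized_position(genes[gi, ], truth$position)
  # reverse-complement the genome: p -> L - p + 1, strand flip
  L <- design$replicon_length
  flip <- c("+" = "-", "-" = "+")
  m_genes <- gene_model(genes$locus_tag, genes$replicon,
                        L - genes$end + 1L, L - genes$start + 1L,
                        unname(flip[genes$strand]))
  D_m <- normalized_position(m_genes[gi, ], L - truth$position + 1L)
  expect_equal(D_m, D)
  expect_equal(position_category(D_m), position_category(D))
})

test_that("sense, antisense and unassigned calls are assigned per policy", {
  genes <- gene_model(c("gf", "gr"), "chr", c(1000, 5000), c(1999, 5999),
                      c("+", "-"))
  calls <- data.frame(
    tps_id = c("in_sense", "anti", "upstream_near", "upstream_far",
               "anti_outside"),
    replicon = "chr", strand = c("+", "-", "+", "+", "-"),
    position = c(1500, 1500, 900, 800, 900), p_value = 1e-12)
  ann <- assign_tps(calls, genes, ext_up = 150, ext_down = 150)
  by_id <- split(ann, ann$tps_id)
  expect_equal(by_id$in_sense$orientation, "sense")
  expect_equal(by_id$in_sense$locus_tag, "gf")
  expect_equal(by_id$anti$orientation, "antisense")   # - call inside + gene
  expect_equal(by_id$upstream_near$orientation, "sense")  # 100 nt upstream
  expect_true(is.na(by_id$upstream_far$locus_tag))    # 200 nt > ext
  expect_true(is.na(by_id$anti_outside$locus_tag))    # no antisense extension
  # monotonicity: enlarging the extension never removes an assignment
  ann_wide <- assign_tps(calls, genes, ext_up = 300, ext_down = 300)
  assigned <- function(a) unique(a$tps_id[!is.na(a$locus_tag)])
  expect_true(all(assigned(ann) %in% assigned(ann_wide)))
  expect_true("upstream_far" %in% assigned(ann_wide))
})

test_that("a call may annotate several genes and D follows each host", {
  genes <- gene_model(c("g1", "g2"), "chr", c(1000, 1400), c(1999, 2399),
                      c("+", "-"))
  call <- data.frame(tps_id = "t", replicon = "chr", strand = "+",
                     position = 1500, p_value = 1e-12)
  ann <- assign_tps(call, genes)
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$orientation, c("sense", "antisense"))
  expect_equal(ann$D[ann$locus_tag == "g1"], 100 * 500 / 999)
})

test_that("summaries report multiplicity, D histogram and densest window", {
  ann <- rbind(
    mk_annot(sprintf("t%d", 1:8), "gene1", D = seq(10, 80, by = 10),
             position = seq(1000, 1140, by = 20)),
    mk_annot("t9", "gene2", D = 50, position = 5000))
  s <- summarize_annotations(ann, window = 200)
  expect_equal(s$multiplicity$n_genes[s$multiplicity$n_tps == 8], 1L)
  expect_equal(s$multiplicity$n_genes[s$multiplicity$n_tps == 1], 1L)
  expect_equal(sum(s$d_histogram$count), 9L)
  expect_true(all(diff(s$d_histogram$bin_start) == 3))
  # 8 sites within one 200-nt window -> density 0.04 per nt
  expect_equal(s$densest$count, 8L)
  expect_equal(s$densest$density, 0.04)
  # 11 sites in 200 nt -> 0.055 per nt
  ann11 <- mk_annot(sprintf("u%d", 1:11), "gene3", D = 50,
                    position = seq(100, 290, by = 19))
  s11 <- summarize_annotations(ann11, window = 200)
  expect_equal(s11$densest$density, 0.055)
  # empty input: empty tables, no crash
  s0 <- summarize_annotations(assign_tps(
    data.frame(tps_id = character(0), replicon = character(0),
               strand = character(0), position = integer(0),
               p_value = numeric(0)),
    gene_model("g", "chr", 1, 100, "+")))
  expect_equal(nrow(s0$multiplicity), 0L)
  expect_equal(nrow(s0$d_histogram), 0L)
})
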