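#' Design of a synthetic dRNA-seq experiment
#'
#' Parameters of the generative model used for validation: non-overlapping
#' CDS on both strands of one replicon, Poisson background read-start
#' noise in every library, and planted sites. A transcript processing
#' site (TPS, 5' monophosphate) of strength mu contributes mu expected
#' extra read starts to the TEX- library but only `mu * tex_plus_leak` to
#' the TEX+ library (incomplete exonuclease digestion); a transcription
#' start site (TSS, 5' triphosphate) contributes `mu * tss_enrichment` to
#' TEX+ and `mu * tss_minus_fraction` to TEX-.
#'
#' @param n_genes number of CDS to place.
#' @param replicon_length replicon length in nt.
#' @param gene_length length 2 vector: min and max CDS length (nt).
#' @param strand_balance fraction of genes on the forward strand.
#' @param lambda_bg background Poisson mean read starts per position per
#'   library (> 0).
#' @param tex_plus_leak fraction of a TPS's strength surviving TEX
#'   treatment (default 0.02; in `[0, 1)`).
#' @param tss_enrichment TEX+ enrichment factor for TSS (default 3).
#' @param tss_minus_fraction fraction of a TSS's strength seen in TEX-
#'   (default 1).
#' @param replicon replicon name.
#' @param seed integer seed making every generator deterministic.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(n_genes = 50L,
                       replicon_length = 100000L,
                       gene_length = c(300L, 1500L),
                       strand_balance = 0.5,
                       lambda_bg = 1,
                       tex_plus_leak = 0.02,
                       tss_enrichment = 3,
                       tss_minus_fraction = 1,
                       replicon = "chrSim",
                       seed = 1L) {
  .assert(.is_count(n_genes), "n_genes must be a non-negative integer")
  .assert(.is_count(replicon_length) && replicon_length >= 1,
          "replicon_length must be a positive integer")
  .assert(length(gene_length) == 2 && all(gene_length >= 6) &&
            gene_length[1] <= gene_length[2], "invalid gene_length range")
  .assert(strand_balance >= 0 && strand_balance <= 1,
          "strand_balance must be in [0, 1]")
  .assert(lambda_bg > 0, "lambda_bg must be > 0")
  .assert(tex_plus_leak >= 0 && tex_plus_leak < 1,
          "tex_plus_leak must be in [0, 1)")
  .assert(tss_enrichment > 0 && tss_minus_fraction >= 0,
          "invalid TSS parameters")
  structure(list(n_genes = as.integer(n_genes),
                 replicon_length = as.integer(replicon_length),
                 gene_length = as.integer(gene_length),
                 strand_balance = strand_balance,
                 lambda_bg = lambda_bg,
                 tex_plus_leak = tex_plus_leak,
                 tss_enrichment = tss_enrichment,
                 tss_minus_fraction = tss_minus_fraction,
                 replicon = replicon,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf(
    "sim_design: %d genes on %s (%d nt), lambda_bg = %g, TEX leak = %g, seed %d\n",
    x$n_genes, x$replicon, x$replicon_length, x$lambda_bg, x$tex_plus_leak,
    x$seed))
  invisible(x)
}

# place n non-overlapping intervals of the given lengths on [1, L],
# separated by >= 1 nt; random slack distribution, left to right
.place_intervals <- function(n, lens, L) {
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  need <- sum(lens) + (n - 1L)
  .assert(need <= L,
          "replicon too short: %d nt needed for %d genes, %d available",
          need, n, L)
  slack <- L - need
  gaps <- as.integer(stats::rmultinom(1, slack, rep(1, n + 1L)))
  starts <- integer(n)
  cur <- 1L + gaps[1]
  for (i in seq_len(n)) {
    starts[i] <- cur
    cur <- cur + lens[i] + 1L + gaps[i + 1L]
  }
  data.frame(start = starts, end = starts + lens - 1L)
}

#' Generate a synthetic CDS annotation
#'
#' Places `n_genes` CDS with lengths drawn uniformly from the design's
#' range; same-strand genes never overlap (at least 1 nt apart).
#' Deterministic given the design seed. Optionally written as GFF3 with
#' `locus_tag` attributes.
#'
#' @param design a [sim_design()].
#' @param gff_path optional output GFF3 path.
#' @param locus_prefix prefix of the generated locus tags.
#' @return a [gene_model()] data.frame.
#' @export
generate_annotation <- function(design, gff_path = NULL,
                                locus_prefix = "SIMG") {
  stopifnot(inherits(design, "sim_design"))
  genes <- .with_seed(design$seed, {
    n_plus <- round(design$n_genes * design$strand_balance)
    n_minus <- design$n_genes - n_plus
    res <- list()
    for (s in c("+", "-")) {
      n_s <- if (s == "+") n_plus else n_minus
      if (n_s == 0) next
      lens <- as.integer(round(stats::runif(n_s, design$gene_length[1],
                                            design$gene_length[2])))
      iv <- .place_intervals(n_s, lens, design$replicon_length)
      res[[s]] <- data.frame(start = iv$start, end = iv$end, strand = s,
                             stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, res)
    if (is.null(df)) df <- data.frame(start = integer(0), end = integer(0),
                                      strand = character(0))
    df <- df[order(df$start, df$strand), , drop = FALSE]
    df
  })
  gm <- gene_model(
    locus_tag = sprintf("%s_%04d", locus_prefix, seq_len(nrow(genes))),
    replicon = design$replicon, start = genes$start, end = genes$end,
    strand = genes$strand)
  if (!is.null(gff_path)) write_annotation_gff3(gm, gff_path, design)
  gm
}

#' Write a gene-model table as GFF3
#' @param genes a [gene_model()] data.frame.
#' @param path output GFF3 file.
#' @param design optional [sim_design()] providing the replicon length.
#' @return invisibly, `path`.
#' @export
write_annotation_gff3 <- function(genes, path, design = NULL) {
  if (nrow(genes) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  sl <- NULL
  if (!is.null(design)) {
    sl <- stats::setNames(design$replicon_length, design$replicon)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$replicon,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "CDS", phase = 0L, ID = genes$locus_tag,
    locus_tag = genes$locus_tag, seqlengths = sl)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# draw n values from a distribution spec: a single constant, a named
# probability vector (names = values), or a function(n)
.draw_spec <- function(spec, n, what) {
  if (is.function(spec)) return(spec(n))
  if (is.numeric(spec) && length(spec) == 1L) return(rep(spec, n))
  if (is.numeric(spec) && !is.null(names(spec))) {
    .assert(all(spec >= 0) && sum(spec) > 0, "invalid %s distribution", what)
    return(sample(as.numeric(names(spec)), n, replace = TRUE,
                  prob = spec / sum(spec)))
  }
  stop(sprintf("%s must be a constant, a named probability vector or a function",
               what), call. = FALSE)
}

#' Plant ground-truth sites into a synthetic annotation
#'
#' Draws a per-gene number of processing sites (TPS) and start sites
#' (TSS), places TPS uniformly inside the gene body and TSS at the gene's
#' 5' end (leaderless-style, jittered a few nt), and enforces a minimum
#' spacing between same-kind same-strand sites by rejection so that the
#' truth is unambiguous at evaluation time. A site that cannot be placed
#' is skipped with a warning, never silently dropped from the accounting.
#'
#' The default multiplicity spec reflects processing-site maps in
#' halophilic archaea, where single-TPS genes dominate and genes with
#' more than three sites are rare.
#'
#' @param genes a [gene_model()] data.frame.
#' @param tps_per_gene,tss_per_gene distribution specs for per-gene site
#'   counts: a constant, a named probability vector (names = counts), or
#'   a `function(n)`.
#' @param strength distribution spec for site strength mu (expected extra
#'   read starts in the favored library).
#' @param min_spacing minimum distance (nt) between same-kind same-strand
#'   sites; default 6 = clustering gap + 1.
#' @param seed integer seed.
#' @return data.frame of class `site_truth` with columns `replicon`,
#'   `position`, `strand`, `kind` (`"TPS"`/`"TSS"`), `strength`,
#'   `locus_tag`; the seed is kept as an attribute.
#' @export
plant_truth <- function(genes,
                        tps_per_gene = c("0" = 0.40, "1" = 0.35,
                                         "2" = 0.15, "3" = 0.10),
                        tss_per_gene = 1,
                        strength = function(n) stats::rlnorm(n, log(30), 0.5),
                        min_spacing = 6L,
                        seed = 1L) {
  .assert(.is_count(min_spacing) && min_spacing >= 1,
          "min_spacing must be a positive integer")
  truth <- .with_seed(seed, {
    n_tps <- as.integer(.draw_spec(tps_per_gene, nrow(genes), "tps_per_gene"))
    n_tss <- as.integer(.draw_spec(tss_per_gene, nrow(genes), "tss_per_gene"))
    .assert(all(n_tps >= 0) && all(n_tss >= 0), "site counts must be >= 0")
    placed <- list()  # per (replicon, strand, kind): accepted positions
    rows <- list()
    skipped <- 0L
    add_site <- function(gene, kind, draw_pos) {
      key <- paste(gene$replicon, gene$strand, kind, sep = "\r")
      prev <- placed[[key]]
      for (try in seq_len(200L)) {
        p <- draw_pos()
        if (is.null(prev) || all(abs(prev - p) >= min_spacing)) {
          placed[[key]] <<- c(prev, p)
          return(p)
        }
      }
      NA_integer_
    }
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, , drop = FALSE]
      for (k in seq_len(n_tps[i])) {
        p <- add_site(g, "TPS", function() {
          as.integer(round(stats::runif(1, g$start, g$end)))
        })
        if (is.na(p)) { skipped <- skipped + 1L; next }
        rows[[length(rows) + 1L]] <- data.frame(
          replicon = g$replicon, position = p, strand = g$strand,
          kind = "TPS", locus_tag = g$locus_tag, stringsAsFactors = FALSE)
      }
      for (k in seq_len(n_tss[i])) {
        # leaderless-style TSS: at or a few nt inside the 5' gene end
        p <- add_site(g, "TSS", function() {
          if (g$strand == "+") {
            as.integer(round(stats::runif(1, g$start, min(g$end, g$start + 10L))))
          } else {
            as.integer(round(stats::runif(1, max(g$start, g$end - 10L), g$end)))
          }
        })
        if (is.na(p)) { skipped <- skipped + 1L; next }
        rows[[length(rows) + 1L]] <- data.frame(
          replicon = g$replicon, position = p, strand = g$strand,
          kind = "TSS", locus_tag = g$locus_tag, stringsAsFactors = FALSE)
      }
    }
    if (skipped > 0L) {
      warning(sprintf("%d site(s) skipped: min spacing unsatisfiable", skipped),
              call. = FALSE)
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(replicon = character(0), position = integer(0),
                 strand = character(0), kind = character(0),
                 locus_tag = character(0), stringsAsFactors = FALSE)
    df$strength <- .draw_spec(strength, nrow(df), "strength")
    .assert(all(df$strength >= 0), "strengths must be non-negative")
    df
  })
  truth <- truth[order(truth$replicon, truth$strand, truth$position),
                 c("replicon", "position", "strand", "kind", "strength",
                   "locus_tag")]
  rownames(truth) <- NULL
  class(truth) <- c("site_truth", "data.frame")
  attr(truth, "seed") <- as.integer(seed)
  truth
}

#' Write a ground-truth site table as TSV
#' @param truth a `site_truth` data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_site_truth <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate one dRNA-seq library from planted truth
#'
#' Per-position counts are `Poisson(lambda_bg)` background plus an
#' independent Poisson site contribution at every planted site: a TPS of
#' strength mu adds mean mu to TEX- and `mu * tex_plus_leak` to TEX+; a
#' TSS adds `mu * tss_enrichment` to TEX+ and `mu * tss_minus_fraction`
#' to TEX-. Deterministic given (seed, replicate, treatment).
#'
#' @param truth a `site_truth` from [plant_truth()] (may be empty).
#' @param design the [sim_design()] the truth was generated under.
#' @param treatment `"TEX_MINUS"` or `"TEX_PLUS"`.
#' @param replicate replicate number (independent noise per replicate).
#' @param seed integer seed; defaults to the design seed.
#' @param condition condition label stored in the track metadata.
#' @return a [read_start_track()].
#' @export
simulate_library <- function(truth, design,
                             treatment = c("TEX_MINUS", "TEX_PLUS"),
                             replicate = 1L, seed = design$seed,
                             condition = NA_character_) {
  stopifnot(inherits(design, "sim_design"))
  treatment <- match.arg(treatment)
  .assert(all(truth$replicon == design$replicon),
          "truth and design refer to different replicons")
  .assert(all(truth$position >= 1 & truth$position <= design$replicon_length),
          "planted site outside replicon bounds")
  L <- design$replicon_length
  stream <- .stream_seed(seed, replicate, as.integer(treatment == "TEX_PLUS"))
  counts <- .with_seed(stream, {
    out <- list()
    for (s in c("+", "-")) {
      v <- stats::rpois(L, design$lambda_bg)
      t_s <- truth[truth$strand == s, , drop = FALSE]
      if (nrow(t_s)) {
        mu <- ifelse(t_s$kind == "TPS",
                     ifelse(treatment == "TEX_MINUS", t_s$strength,
                            t_s$strength * design$tex_plus_leak),
                     ifelse(treatment == "TEX_PLUS",
                            t_s$strength * design$tss_enrichment,
                            t_s$strength * design$tss_minus_fraction))
        extra <- stats::rpois(nrow(t_s), mu)
        v[t_s$position] <- v[t_s$position] + extra
      }
      nz <- which(v > 0)
      if (length(nz)) {
        out[[s]] <- data.frame(replicon = design$replicon, strand = s,
                               pos = nz, count = v[nz],
                               stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(replicon = character(0), strand = character(0),
                 pos = integer(0), count = numeric(0))
  })
  read_start_track(
    counts,
    seqlengths = stats::setNames(L, design$replicon),
    library_id = sprintf("%s_%s_rep%d", design$replicon,
                         tolower(treatment), as.integer(replicate)),
    treatment = treatment, condition = condition, replicate = replicate)
}

#' Simulate a two-species ortholog study with planted conservation
#'
#' Generates annotations for two species, pairs the first `n_pairs` genes
#' of each into an ortholog table, and plants exactly one TPS per paired
#' gene. A controlled fraction of pairs is positionally conserved: the
#' species-B site sits at normalized position `D_b = D_a + U(-jitter,
#' jitter)`. For the remaining pairs the species-B position is re-drawn
#' until it lies at least `threshold + 1` D-units away from the species-A
#' site, so the planted truth is unambiguous under the conservation
#' criterion (`jitter >= threshold` is refused for the same reason).
#'
#' @param design_a,design_b [sim_design()]s of the two species (replicon
#'   names should differ).
#' @param n_pairs number of ortholog pairs (at most the smaller gene
#'   count).
#' @param conserved_fraction fraction of pairs planted as conserved.
#' @param jitter maximum |D_a - D_b| of a conserved pair (D-units; must
#'   be < `threshold`).
#' @param threshold conservation cutoff the truth is built against
#'   (default 3).
#' @param strength TPS strength mu for every planted site.
#' @param seed integer seed.
#' @return list with `genes_a`, `genes_b` ([gene_model()]s), `pairs`
#'   ([ortholog_pairs()]), `truth_a`, `truth_b` (`site_truth`s) and
#'   `conserved_truth` (per pair: planted positions, realized `D_a`,
#'   `D_b` and the `conserved` flag).
#' @export
simulate_ortholog_study <- function(design_a, design_b, n_pairs,
                                    conserved_fraction = 0.5, jitter = 1,
                                    threshold = 3, strength = 50, seed = 1L) {
  stopifnot(inherits(design_a, "sim_design"), inherits(design_b, "sim_design"))
  .assert(conserved_fraction >= 0 && conserved_fraction <= 1,
          "conserved_fraction must be in [0, 1]")
  .assert(jitter >= 0, "jitter must be non-negative")
  .assert(jitter < threshold,
          "jitter (%g) must be below the conservation threshold (%g): the planted truth would be ambiguous",
          jitter, threshold)
  genes_a <- generate_annotation(design_a, locus_prefix = "SPA")
  genes_b <- generate_annotation(design_b, locus_prefix = "SPB")
  .assert(n_pairs >= 1 && n_pairs <= min(nrow(genes_a), nrow(genes_b)),
          "n_pairs exceeds the available gene count")
  pairs <- ortholog_pairs(genes_a$locus_tag[seq_len(n_pairs)],
                          genes_b$locus_tag[seq_len(n_pairs)])
  res <- .with_seed(seed, {
    n_cons <- round(n_pairs * conserved_fraction)
    cons <- logical(n_pairs)
    cons[sample.int(n_pairs, n_cons)] <- TRUE
    ga <- genes_a[match(pairs$locus_a, genes_a$locus_tag), , drop = FALSE]
    gb <- genes_b[match(pairs$locus_b, genes_b$locus_tag), , drop = FALSE]
    d_to_x <- function(g, D) {
      sig <- ifelse(g$strand == "+", 1L, -1L)
      as.integer(g$x_cds_start +
                   sig * round(D / 100 * abs(g$x_cds_start - g$x_cds_end)))
    }
    D_a <- stats::runif(n_pairs, 5, 95)
    pos_a <- d_to_x(ga, D_a)
    D_a_real <- normalized_position(ga, pos_a)
    D_b <- numeric(n_pairs)
    for (i in seq_len(n_pairs)) {
      if (cons[i]) {
        D_b[i] <- D_a_real[i] + stats::runif(1, -jitter, jitter)
      } else {
        repeat {
          cand <- stats::runif(1, 5, 95)
          if (abs(cand - D_a_real[i]) >= threshold + 1) { D_b[i] <- cand; break }
        }
      }
    }
    pos_b <- d_to_x(gb, D_b)
    D_b_real <- normalized_position(gb, pos_b)
    list(cons = cons, pos_a = pos_a, pos_b = pos_b,
         D_a = D_a_real, D_b = D_b_real, ga = ga, gb = gb)
  })
  mk_truth <- function(g, pos) {
    df <- data.frame(replicon = g$replicon, position = pos, strand = g$strand,
                     kind = "TPS", strength = strength,
                     locus_tag = g$locus_tag, stringsAsFactors = FALSE)
    df <- df[order(df$replicon, df$strand, df$position), ]
    rownames(df) <- NULL
    class(df) <- c("site_truth", "data.frame")
    attr(df, "seed") <- as.integer(seed)
    df
  }
  conserved_truth <- data.frame(
    locus_a = pairs$locus_a, locus_b = pairs$locus_b,
    pos_a = res$pos_a, pos_b = res$pos_b,
    D_a = res$D_a, D_b = res$D_b, conserved = res$cons,
    stringsAsFactors = FALSE)
  list(genes_a = genes_a, genes_b = genes_b, pairs = pairs,
       truth_a = mk_truth(res$ga, res$pos_a),
       truth_b = mk_truth(res$gb, res$pos_b),
       conserved_truth = conserved_truth)
}

#' Simulate Ribo-seq coverage with peaks planted at processing sites
#'
#' Coverage is `base` at every CDS position (0 outside), plus a
#' triangular peak of summit height `peak_height` centered on a randomly
#' chosen fraction of the planted TPS. The summit depth is exactly
#' `base + peak_height` when the site lies inside its CDS.
#'
#' @param genes a [gene_model()] data.frame.
#' @param truth a `site_truth`; only `kind == "TPS"` rows receive peaks.
#' @param peak_fraction fraction of TPS that get a peak.
#' @param peak_height summit height added at the site.
#' @param base in-CDS baseline depth.
#' @param halfwidth half-width of the triangular peak (nt).
#' @param seed integer seed.
#' @return list with `coverage` (a [coverage_track()]) and `peak_truth`
#'   (the TPS rows of `truth` plus a logical `has_peak`).
#' @export
simulate_riboseq <- function(genes, truth, peak_fraction = 0.5,
                             peak_height = 50, base = 5, halfwidth = 15L,
                             seed = 1L) {
  .assert(peak_fraction >= 0 && peak_fraction <= 1,
          "peak_fraction must be in [0, 1]")
  .assert(peak_height > 0 && base >= 0 && halfwidth >= 1,
          "invalid peak parameters")
  tps <- truth[truth$kind == "TPS", , drop = FALSE]
  n_peak <- round(nrow(tps) * peak_fraction)
  has_peak <- .with_seed(seed, {
    f <- logical(nrow(tps))
    if (n_peak > 0) f[sample.int(nrow(tps), n_peak)] <- TRUE
    f
  })
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      replicon = g$replicon, strand = g$strand, pos = g$start:g$end,
      depth = base, stringsAsFactors = FALSE)
  }
  if (any(has_peak)) {
    pk <- tps[has_peak, , drop = FALSE]
    off <- -(halfwidth):(halfwidth)
    tri <- peak_height * (1 - abs(off) / (halfwidth + 1))
    for (i in seq_len(nrow(pk))) {
      pos <- pk$position[i] + off
      keep <- pos >= 1
      rows[[length(rows) + 1L]] <- data.frame(
        replicon = pk$replicon[i], strand = pk$strand[i], pos = pos[keep],
        depth = tri[keep], stringsAsFactors = FALSE)
    }
  }
  depths <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicon = character(0), strand = character(0),
               pos = integer(0), depth = numeric(0))
  peak_truth <- as.data.frame(tps)
  peak_truth$has_peak <- has_peak
  list(coverage = coverage_track(depths), peak_truth = peak_truth)
}
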