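#' Library-size scale factors
#'
#' Two normalization conventions for comparing libraries: `"per_million"`
#' sets every library's signal integral to one million
#' (factor = 1e6 / total), and `"match_max"` rescales the less deeply
#' sequenced libraries to match the most sequenced one
#' (factor = max(totals) / total; the deepest library gets factor 1).
#'
#' @param totals named numeric vector of library totals (sums of all
#'   per-position counts), or a list of [read_start_track()]s.
#' @param mode `"match_max"` or `"per_million"`.
#' @return named numeric vector of factors.
#' @export
scale_factors <- function(totals, mode = c("match_max", "per_million")) {
  mode <- match.arg(mode)
  if (is.list(totals) && all(vapply(totals, inherits, logical(1),
                                    "read_start_track"))) {
    nm <- vapply(totals, function(t) t$meta$library_id, character(1))
    totals <- stats::setNames(vapply(totals, total_read_starts, numeric(1)), nm)
  }
  .assert(is.numeric(totals) && length(totals) >= 1, "totals must be numeric")
  .assert(all(totals > 0), "library totals must be positive")
  switch(mode,
         per_million = 1e6 / totals,
         match_max = max(totals) / totals)
}

#' Read-start signal around a site
#'
#' Sum of strand-matched counts over the window
#' `[position - halfwidth, position + halfwidth]`.
#'
#' @param track a [read_start_track()] (typically library-size normalized).
#' @param replicon,strand,position site location.
#' @param halfwidth window half-width in nt (default 2; 0 gives the count
#'   at the position itself).
#' @return non-negative numeric.
#' @export
site_signal <- function(track, replicon, strand, position, halfwidth = 2L) {
  stopifnot(inherits(track, "read_start_track"))
  .assert(halfwidth >= 0, "halfwidth must be non-negative")
  sum(.counts_at(track, replicon, .match_strand(strand),
                 (position - halfwidth):(position + halfwidth)))
}

# mean normalized count over the CDS interval, gene strand
.gene_signal <- function(track, gene) {
  sum(.counts_at(track, gene$replicon, gene$strand, gene$start:gene$end)) /
    (gene$end - gene$start + 1)
}

#' Differential processing between two conditions
#'
#' For every sense-annotated site, compares the site-proximal read-start
#' signal between two conditions against the behaviour of the whole
#' cognate gene, and flags discordant sites: those whose site signal and
#' gene signal move in opposite directions, both beyond an effect floor.
#' Such sites mark transcripts whose processing-product abundance departs
#' from the expression pattern of the full-length gene.
#'
#' Both tracks must be normalized with the same library-size mode (see
#' [scale_factors()]); fold-changes are pseudocount-stabilized:
#' `log2fc = log2((b + pseudocount) / (a + pseudocount))`.
#'
#' @param track_a,track_b normalized TEX- tracks of conditions a and b.
#' @param annotations `tps_annotation` table ([assign_tps()]).
#' @param genes [gene_model()] table for the gene-level signal.
#' @param halfwidth site window half-width (nt), see [site_signal()].
#' @param pseudocount added to both numerator and denominator.
#' @param effect_floor minimum |log2fc| (both layers) for discordance.
#' @return data.frame `tps_id`, `locus_tag`, `signal_a`, `signal_b`,
#'   `gene_a`, `gene_b`, `log2fc_site`, `log2fc_gene`, `discordant`.
#' @export
differential_sites <- function(track_a, track_b, annotations, genes,
                               halfwidth = 2L, pseudocount = 1,
                               effect_floor = 1) {
  .assert(pseudocount > 0, "pseudocount must be positive")
  sense <- annotations[!is.na(annotations$orientation) &
                         annotations$orientation == "sense", , drop = FALSE]
  if (nrow(sense) == 0L) {
    return(data.frame(tps_id = character(0), locus_tag = character(0),
                      signal_a = numeric(0), signal_b = numeric(0),
                      gene_a = numeric(0), gene_b = numeric(0),
                      log2fc_site = numeric(0), log2fc_gene = numeric(0),
                      discordant = logical(0)))
  }
  gene_idx <- match(sense$locus_tag, genes$locus_tag)
  .assert(!anyNA(gene_idx), "annotation references loci absent from genes")
  sig_a <- sig_b <- gA <- gB <- numeric(nrow(sense))
  for (i in seq_len(nrow(sense))) {
    sig_a[i] <- site_signal(track_a, sense$replicon[i], sense$strand[i],
                            sense$position[i], halfwidth)
    sig_b[i] <- site_signal(track_b, sense$replicon[i], sense$strand[i],
                            sense$position[i], halfwidth)
    g <- genes[gene_idx[i], , drop = FALSE]
    gA[i] <- .gene_signal(track_a, g)
    gB[i] <- .gene_signal(track_b, g)
  }
  fc_site <- log2((sig_b + pseudocount) / (sig_a + pseudocount))
  fc_gene <- log2((gB + pseudocount) / (gA + pseudocount))
  disc <- sign(fc_site) != sign(fc_gene) & sign(fc_site) != 0 &
    sign(fc_gene) != 0 & abs(fc_site) >= effect_floor &
    abs(fc_gene) >= effect_floor
  data.frame(tps_id = sense$tps_id, locus_tag = sense$locus_tag,
             signal_a = sig_a, signal_b = sig_b, gene_a = gA, gene_b = gB,
             log2fc_site = fc_site, log2fc_gene = fc_gene,
             discordant = disc, stringsAsFactors = FALSE)
}

#' Call local coverage peaks (Ribo-seq style)
#'
#' A position is a peak summit when its depth is at least `min_height`,
#' exceeds every other depth within `window/2` nt (ties resolved toward
#' the leftmost position), and stands `min_z` standard deviations above
#' the surrounding window (focal position excluded; SD floored at 1).
#' This is a deliberately simple local-maximum rule for detecting
#' ribosome dwell peaks in profiling coverage.
#'
#' @param coverage a [coverage_track()].
#' @param window window width in nt for the local statistics (default 200).
#' @param min_z minimum z-score of the summit (default 2).
#' @param min_height minimum summit depth (default 5).
#' @return data.frame `replicon`, `strand`, `position`, `height`,
#'   `z_score`.
#' @export
call_ribo_peaks <- function(coverage, window = 200L, min_z = 2,
                            min_height = 5) {
  stopifnot(inherits(coverage, "coverage_track"))
  half <- as.integer(window) %/% 2L
  out <- list()
  d <- coverage$depths
  for (rep_ in unique(d$replicon)) {
    strands <- unique(d$strand[d$replicon == rep_])
    len <- coverage$seqlengths[rep_]
    if (is.null(len) || is.na(len)) {
      len <- max(d$pos[d$replicon == rep_]) + half
    }
    for (s in strands) {
      v <- .dense_depths(coverage, rep_, s, len)
      cand <- which(v >= min_height)
      keep_pos <- integer(0); keep_h <- keep_z <- numeric(0)
      for (p in cand) {
        lo <- max(1L, p - half); hi <- min(len, p + half)
        win <- v[lo:hi]
        focal <- p - lo + 1L
        left <- win[seq_len(focal - 1L)]
        right <- if (focal < length(win)) win[(focal + 1L):length(win)] else numeric(0)
        # strict local maximum; equal-height ties go to the leftmost summit
        if (length(left) && any(left >= v[p])) next
        if (length(right) && any(right > v[p])) next
        rest <- c(left, right)
        z <- (v[p] - mean(rest)) / max(stats::sd(rest), 1)
        if (!is.finite(z) || z < min_z) next
        keep_pos <- c(keep_pos, p); keep_h <- c(keep_h, v[p])
        keep_z <- c(keep_z, z)
      }
      if (length(keep_pos)) {
        out[[length(out) + 1L]] <- data.frame(
          replicon = rep_, strand = s, position = keep_pos,
          height = keep_h, z_score = keep_z, stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(replicon = character(0), strand = character(0),
               position = integer(0), height = numeric(0),
               z_score = numeric(0))
  rownames(res) <- NULL
  res
}

#' Fraction of sites inside or adjacent to coverage peaks
#'
#' A site overlaps when some peak summit on the same replicon (and same
#' strand, unless the peak is unstranded) lies within `adjacency` nt of
#' it. The fraction of overlapping sites is reported both raw and as a
#' percentage rounded to the nearest integer, together with the per-site
#' nearest-summit distance.
#'
#' @param sites data.frame with `tps_id`, `replicon`, `strand`,
#'   `position` (e.g. a `tps_calls` object or conserved-site table).
#' @param peaks peak table from [call_ribo_peaks()].
#' @param adjacency maximum summit distance in nt (default 10).
#' @return list `fraction`, `percent`, `n_overlapping`, `n_total`, and
#'   `table` (per-site `overlaps` flag and `nearest_distance`). With no
#'   sites, `fraction` is `NA` and the table empty.
#' @export
overlap_fraction <- function(sites, peaks, adjacency = 10L) {
  .assert(adjacency >= 0, "adjacency must be non-negative")
  if (nrow(sites) == 0L) {
    return(list(fraction = NA_real_, percent = NA_real_, n_overlapping = 0L,
                n_total = 0L,
                table = data.frame(tps_id = character(0),
                                   overlaps = logical(0),
                                   nearest_distance = numeric(0))))
  }
  nearest <- vapply(seq_len(nrow(sites)), function(i) {
    sel <- peaks$replicon == sites$replicon[i] &
      (peaks$strand == "*" | peaks$strand == sites$strand[i])
    if (!any(sel)) return(Inf)
    min(abs(peaks$position[sel] - sites$position[i]))
  }, numeric(1))
  ov <- nearest <= adjacency
  list(fraction = mean(ov), percent = round(100 * mean(ov)),
       n_overlapping = sum(ov), n_total = nrow(sites),
       table = data.frame(tps_id = sites$tps_id, overlaps = ov,
                          nearest_distance = nearest,
                          stringsAsFactors = FALSE))
}
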