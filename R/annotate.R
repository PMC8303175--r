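#' Build a gene-model table
#'
#' Internal representation of CDS features: 1-based inclusive genomic
#' coordinates plus the strand-aware coordinates of the first base of the
#' start codon (`x_cds_start`) and the last CDS base (`x_cds_end`), which
#' anchor the normalized position scale.
#'
#' @param locus_tag,replicon,start,end,strand vectors of equal length;
#'   `start <= end`, strand `"+"` or `"-"`, length >= 6 nt.
#' @return data.frame of class `gene_model` with columns `locus_tag`,
#'   `replicon`, `start`, `end`, `strand`, `x_cds_start`, `x_cds_end`.
#' @export
gene_model <- function(locus_tag, replicon, start, end, strand) {
  n <- length(locus_tag)
  replicon <- rep_len(as.character(replicon), n)
  strand <- rep_len(.match_strand(strand), n)
  .assert(all(start <= end), "gene start must be <= end")
  .assert(all(end - start + 1 >= 6), "genes must be at least 6 nt long")
  .assert(!anyDuplicated(locus_tag), "duplicate locus tags")
  df <- data.frame(locus_tag = as.character(locus_tag),
                   replicon = as.character(replicon),
                   start = as.integer(start), end = as.integer(end),
                   strand = strand,
                   x_cds_start = ifelse(strand == "+", as.integer(start),
                                        as.integer(end)),
                   x_cds_end = ifelse(strand == "+", as.integer(end),
                                      as.integer(start)),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Load gene models from a GFF3 annotation
#'
#' Reads features of the requested type through `rtracklayer` and derives
#' the strand-aware CDS anchors. The `locus_tag` attribute names the gene,
#' falling back to `ID`. Features without a strand are skipped with a
#' warning; duplicate locus tags are an error.
#'
#' @param path GFF3 file.
#' @param feature_type feature type to keep (default `"CDS"`).
#' @return a [gene_model()] data.frame.
#' @export
load_annotation <- function(path, feature_type = "CDS") {
  .assert(file.exists(path), "annotation file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop(sprintf("failed to parse %s: %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L) {
    return(gene_model(character(0), character(0), integer(0), integer(0),
                      character(0)))
  }
  tags <- if (!is.null(gr$locus_tag)) as.character(gr$locus_tag) else
    rep(NA_character_, length(gr))
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  tags <- ifelse(is.na(tags), ids, tags)
  .assert(!anyNA(tags), "feature without locus_tag or ID attribute in %s", path)
  str <- as.character(BiocGenerics::strand(gr))
  unstranded <- !(str %in% c("+", "-"))
  if (any(unstranded)) {
    warning(sprintf("%d feature(s) without strand skipped", sum(unstranded)),
            call. = FALSE)
  }
  keep <- !unstranded
  .assert(!anyDuplicated(tags[keep]), "duplicate locus tags in %s", path)
  gene_model(tags[keep], as.character(GenomeInfoDb::seqnames(gr))[keep],
             BiocGenerics::start(gr)[keep], BiocGenerics::end(gr)[keep],
             str[keep])
}

#' Normalized position of a site within a CDS
#'
#' Rescales a genomic coordinate onto the CDS: D = 0 at the first base of
#' the start codon and D = 100 at the last CDS base, computed as
#' `100 * s * (x - x_cds_start) / |x_cds_start - x_cds_end|` with s = +1
#' on forward and -1 on reverse genes. Values below 0 or above 100 denote
#' sites upstream of the start codon or downstream of the stop codon,
#' respectively.
#'
#' @param genes a [gene_model()] data.frame (one row per site, recycled if
#'   a single row).
#' @param x_tps genomic coordinate(s) of the site(s).
#' @return numeric vector of normalized positions.
#' @examples
#' g <- gene_model("g1", "chr", 101, 300, "+")
#' normalized_position(g, c(101, 300, 151))
#' @export
normalized_position <- function(genes, x_tps) {
  n <- max(nrow(genes), length(x_tps))
  idx <- rep_len(seq_len(nrow(genes)), n)
  x <- rep_len(x_tps, n)
  sig <- ifelse(genes$strand[idx] == "+", 1, -1)
  denom <- abs(genes$x_cds_start[idx] - genes$x_cds_end[idx])
  100 * sig * (x - genes$x_cds_start[idx]) / denom
}

#' Positional category of a normalized position
#'
#' Partition of the D axis: `UPSTREAM` (D < 0), `START_PROXIMAL`
#' (0 <= D <= 25), `INTERNAL` (25 < D < 75, strict as in the internal-site
#' definition), `STOP_PROXIMAL` (75 <= D <= 100), `DOWNSTREAM` (D > 100).
#'
#' @param D numeric normalized positions.
#' @return factor with the five category levels; NA stays NA.
#' @export
position_category <- function(D) {
  lev <- c("UPSTREAM", "START_PROXIMAL", "INTERNAL", "STOP_PROXIMAL",
           "DOWNSTREAM")
  out <- rep(NA_character_, length(D))
  out[!is.na(D) & D < 0] <- "UPSTREAM"
  out[!is.na(D) & D >= 0 & D <= 25] <- "START_PROXIMAL"
  out[!is.na(D) & D > 25 & D < 75] <- "INTERNAL"
  out[!is.na(D) & D >= 75 & D <= 100] <- "STOP_PROXIMAL"
  out[!is.na(D) & D > 100] <- "DOWNSTREAM"
  factor(out, levels = lev)
}

#' Assign site calls to gene models
#'
#' A call is assigned *sense* to every same-strand gene whose interval,
#' extended by `ext_up` nt upstream and `ext_down` nt downstream (strand
#' aware), contains the call position, and *antisense* (aTPS) to every
#' opposite-strand gene whose unextended interval contains it. A call may
#' annotate several genes; calls matching no gene are retained with an
#' `NA` locus.
#'
#' @param calls a `tps_calls` object (or data.frame with `tps_id`,
#'   `replicon`, `strand`, `position`, `p_value`).
#' @param genes a [gene_model()] data.frame.
#' @param ext_up,ext_down extension of the gene interval (nt) for sense
#'   assignment, on the 5' and 3' side of the gene respectively.
#' @return data.frame of class `tps_annotation`: `tps_id`, `locus_tag`,
#'   `orientation` (`"sense"`/`"antisense"`), `replicon`, `strand` (of the
#'   call), `position`, `D`, `category`, `p_value`.
#' @export
assign_tps <- function(calls, genes, ext_up = 150L, ext_down = 150L) {
  .assert(ext_up >= 0 && ext_down >= 0, "extensions must be non-negative")
  empty <- data.frame(tps_id = character(0), locus_tag = character(0),
                      orientation = character(0), replicon = character(0),
                      strand = character(0), position = integer(0),
                      D = numeric(0), category = position_category(numeric(0)),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("tps_annotation", "data.frame")
  if (nrow(calls) == 0L) return(empty)
  pval <- if ("p_value" %in% names(calls)) calls$p_value else NA_real_
  rows <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    x <- calls$position[i]
    same_rep <- genes$replicon == calls$replicon[i]
    ext_start <- ifelse(genes$strand == "+", genes$start - ext_up,
                        genes$start - ext_down)
    ext_end <- ifelse(genes$strand == "+", genes$end + ext_down,
                      genes$end + ext_up)
    sense <- which(same_rep & genes$strand == calls$strand[i] &
                     x >= ext_start & x <= ext_end)
    anti <- which(same_rep & genes$strand != calls$strand[i] &
                    x >= genes$start & x <= genes$end)
    hits <- c(sense, anti)
    if (length(hits) == 0L) {
      rows[[i]] <- data.frame(tps_id = calls$tps_id[i], locus_tag = NA_character_,
                              orientation = NA_character_,
                              replicon = calls$replicon[i],
                              strand = calls$strand[i], position = x,
                              D = NA_real_, p_value = pval[min(i, length(pval))],
                              stringsAsFactors = FALSE)
    } else {
      g <- genes[hits, , drop = FALSE]
      rows[[i]] <- data.frame(
        tps_id = calls$tps_id[i], locus_tag = g$locus_tag,
        orientation = rep(c("sense", "antisense"),
                          c(length(sense), length(anti))),
        replicon = calls$replicon[i], strand = calls$strand[i], position = x,
        D = normalized_position(g, x),
        p_value = pval[min(i, length(pval))], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$category <- position_category(res$D)
  res <- res[, c("tps_id", "locus_tag", "orientation", "replicon", "strand",
                 "position", "D", "category", "p_value")]
  rownames(res) <- NULL
  class(res) <- c("tps_annotation", "data.frame")
  res
}

#' Summary tables for annotated sites
#'
#' Produces the descriptive layers used to characterize a processing-site
#' map: the per-gene site multiplicity distribution (sense assignments,
#' distinct sites per locus), a histogram of normalized positions D with
#' fixed-width bins, and the densest window of sites per replicon
#' (maximum site count in any `window`-nt stretch, with density =
#' count / window per nt).
#'
#' @param annotations a `tps_annotation` data.frame from [assign_tps()].
#' @param bin_width histogram bin width on the D axis (default 3 units).
#' @param window window length in nt for the density scan (default 200).
#' @return list with data.frames `multiplicity` (`n_tps`, `n_genes`,
#'   `fraction`), `d_histogram` (`bin_start`, `bin_mid`, `count`) and
#'   `densest` (`replicon`, `window_start`, `count`, `density`).
#' @export
summarize_annotations <- function(annotations, bin_width = 3, window = 200L) {
  sense <- annotations[!is.na(annotations$orientation) &
                         annotations$orientation == "sense", , drop = FALSE]
  if (nrow(sense)) {
    per_gene <- tapply(sense$tps_id, sense$locus_tag,
                       function(x) length(unique(x)))
    tab <- table(factor(per_gene, levels = seq_len(max(per_gene))))
    multiplicity <- data.frame(n_tps = as.integer(names(tab)),
                               n_genes = as.integer(tab),
                               fraction = as.numeric(tab) / sum(tab))
  } else {
    multiplicity <- data.frame(n_tps = integer(0), n_genes = integer(0),
                               fraction = numeric(0))
  }
  D <- sense$D[is.finite(sense$D)]
  if (length(D)) {
    lo <- floor(min(D) / bin_width) * bin_width
    hi <- ceiling((max(D) + 1e-9) / bin_width) * bin_width
    breaks <- seq(lo, hi, by = bin_width)
    idx <- findInterval(D, breaks)  # bins are [b_i, b_{i+1})
    counts <- tabulate(idx, nbins = length(breaks) - 1L)
    d_histogram <- data.frame(bin_start = breaks[-length(breaks)],
                              bin_mid = breaks[-length(breaks)] + bin_width / 2,
                              count = counts)
  } else {
    d_histogram <- data.frame(bin_start = numeric(0), bin_mid = numeric(0),
                              count = integer(0))
  }
  pos_df <- unique(annotations[, c("replicon", "position")])
  densest <- do.call(rbind, lapply(split(pos_df$position, pos_df$replicon),
                                   function(p) {
    p <- sort(unique(p))
    counts <- vapply(p, function(x) sum(p >= x & p <= x + window - 1L),
                     integer(1))
    best <- which.max(counts)
    data.frame(window_start = p[best], count = counts[best],
               density = counts[best] / window)
  }))
  if (!is.null(densest)) {
    densest <- data.frame(replicon = rownames(densest), densest,
                          row.names = NULL, stringsAsFactors = FALSE)
  } else {
    densest <- data.frame(replicon = character(0), window_start = integer(0),
                          count = integer(0), density = numeric(0))
  }
  list(multiplicity = multiplicity, d_histogram = d_histogram,
       densest = densest)
}
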