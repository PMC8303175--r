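#' Read an ortholog pair table
#'
#' Two-column TSV with a header; column 1 holds species-A locus tags,
#' column 2 species-B locus tags. The mapping must be one-to-one.
#'
#' @param path TSV file.
#' @return data.frame with columns `locus_a`, `locus_b`.
#' @export
read_ortholog_pairs <- function(path) {
  .assert(file.exists(path), "ortholog table not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  .assert(ncol(df) >= 2, "ortholog table needs two columns")
  ortholog_pairs(df[[1]], df[[2]])
}

#' Construct an ortholog pair table
#' @param locus_a,locus_b equal-length character vectors of locus tags.
#' @return data.frame with columns `locus_a`, `locus_b` (one-to-one).
#' @export
ortholog_pairs <- function(locus_a, locus_b) {
  .assert(length(locus_a) == length(locus_b), "columns differ in length")
  .assert(!anyDuplicated(locus_a) && !anyDuplicated(locus_b),
          "ortholog table must be one-to-one (duplicate locus)")
  data.frame(locus_a = as.character(locus_a), locus_b = as.character(locus_b),
             stringsAsFactors = FALSE)
}

.sense_annot <- function(annot) {
  annot[!is.na(annot$orientation) & annot$orientation == "sense" &
          is.finite(annot$D), , drop = FALSE]
}

#' Positionally conserved sites in orthologous gene pairs
#'
#' For every ortholog pair, all combinations of a sense site in the
#' species-A gene and a sense site in the species-B gene whose normalized
#' positions differ by strictly less than `threshold` D-units
#' (`|D_a - D_b| < threshold`) are reported. A site may take part in
#' several conserved combinations.
#'
#' @param annot_a,annot_b `tps_annotation` tables of the two species.
#' @param pairs ortholog table from [ortholog_pairs()].
#' @param threshold conservation cutoff in D-units (strict `<`, default 3).
#' @return data.frame `locus_a`, `locus_b`, `tps_a`, `tps_b`, `D_a`,
#'   `D_b`, `delta`, sorted by pair then delta; attribute
#'   `n_distinct_sites` counts distinct participating site ids.
#' @export
conserved_sites <- function(annot_a, annot_b, pairs, threshold = 3) {
  .assert(is.numeric(threshold) && threshold > 0, "threshold must be positive")
  sa <- .sense_annot(annot_a)
  sb <- .sense_annot(annot_b)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    da <- sa[sa$locus_tag == pairs$locus_a[i], , drop = FALSE]
    db <- sb[sb$locus_tag == pairs$locus_b[i], , drop = FALSE]
    if (nrow(da) == 0L || nrow(db) == 0L) next
    cmb <- expand.grid(ia = seq_len(nrow(da)), ib = seq_len(nrow(db)))
    delta <- abs(da$D[cmb$ia] - db$D[cmb$ib])
    keep <- delta < threshold
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      locus_a = pairs$locus_a[i], locus_b = pairs$locus_b[i],
      tps_a = da$tps_id[cmb$ia[keep]], tps_b = db$tps_id[cmb$ib[keep]],
      D_a = da$D[cmb$ia[keep]], D_b = db$D[cmb$ib[keep]],
      delta = delta[keep], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_a = character(0), locus_b = character(0),
               tps_a = character(0), tps_b = character(0),
               D_a = numeric(0), D_b = numeric(0), delta = numeric(0))
  res <- res[order(res$locus_a, res$locus_b, res$delta), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_distinct_sites") <- length(unique(c(res$tps_a, res$tps_b)))
  res
}

#' Species-specific internal sites in ortholog pairs
#'
#' Internal means a sense site with 25 < D < 75 (strict). For each
#' ortholog pair, the species-A gene is A-specific when it carries at
#' least one internal site while its species-B partner carries none, and
#' reciprocally.
#'
#' @inheritParams conserved_sites
#' @return list with character vectors `a_specific` and `b_specific`
#'   (locus tags of the gene carrying the internal site).
#' @export
specific_internal <- function(annot_a, annot_b, pairs) {
  internal_loci <- function(annot) {
    s <- .sense_annot(annot)
    unique(s$locus_tag[s$D > 25 & s$D < 75])
  }
  ia <- internal_loci(annot_a)
  ib <- internal_loci(annot_b)
  a_has <- pairs$locus_a %in% ia
  b_has <- pairs$locus_b %in% ib
  list(a_specific = pairs$locus_a[a_has & !b_has],
       b_specific = pairs$locus_b[b_has & !a_has])
}

#' Sense/antisense positional coincidences
#'
#' Pairs of a sense site and an antisense site (aTPS) on the same
#' replicon and opposite strands whose genomic positions are at most
#' `window` nt apart — the positional signature expected from cleavage of
#' a sense/antisense RNA duplex. Each unordered pair of site ids is
#' reported once.
#'
#' @param annotations a `tps_annotation` table containing both
#'   orientations.
#' @param window maximum distance in nt (default 5).
#' @return data.frame `tps_sense`, `tps_antisense`, `replicon`,
#'   `pos_sense`, `pos_antisense`, `distance`.
#' @export
coincident_atps <- function(annotations, window = 5L) {
  .assert(window >= 0, "window must be non-negative")
  a <- annotations[!is.na(annotations$orientation), , drop = FALSE]
  sense <- unique(a[a$orientation == "sense",
                    c("tps_id", "replicon", "strand", "position")])
  anti <- unique(a[a$orientation == "antisense",
                   c("tps_id", "replicon", "strand", "position")])
  out <- list()
  for (i in seq_len(nrow(sense))) {
    hit <- which(anti$replicon == sense$replicon[i] &
                   anti$strand != sense$strand[i] &
                   abs(anti$position - sense$position[i]) <= window &
                   anti$tps_id != sense$tps_id[i])
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        tps_sense = sense$tps_id[i], tps_antisense = anti$tps_id[hit],
        replicon = sense$replicon[i], pos_sense = sense$position[i],
        pos_antisense = anti$position[hit],
        distance = abs(anti$position[hit] - sense$position[i]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(tps_sense = character(0), tps_antisense = character(0),
               replicon = character(0), pos_sense = integer(0),
               pos_antisense = integer(0), distance = integer(0))
  res <- unique(res)
  key <- apply(cbind(res$tps_sense, res$tps_antisense), 1,
               function(x) paste(sort(x), collapse = "\r"))
  res <- res[!duplicated(key), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Ortholog pairs with antisense sites in both partners
#'
#' Presence-only criterion: an ortholog pair is reported when both genes
#' carry at least one antisense site, with no positional requirement
#' (antisense transcription is poorly conserved, so co-presence is
#' already informative).
#'
#' @inheritParams conserved_sites
#' @return subset of `pairs` (with counts `n_atps_a`, `n_atps_b`).
#' @export
conserved_atps <- function(annot_a, annot_b, pairs) {
  anti_loci <- function(annot) {
    a <- annot[!is.na(annot$orientation) & annot$orientation == "antisense", ,
               drop = FALSE]
    table(a$locus_tag)
  }
  ta <- anti_loci(annot_a)
  tb <- anti_loci(annot_b)
  keep <- pairs$locus_a %in% names(ta) & pairs$locus_b %in% names(tb)
  res <- pairs[keep, , drop = FALSE]
  res$n_atps_a <- as.integer(ta[res$locus_a])
  res$n_atps_b <- as.integer(tb[res$locus_b])
  rownames(res) <- NULL
  res
}
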