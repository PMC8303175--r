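#' Count read 5' ends from an alignment file
#'
#' Builds a [read_start_track()] from a SAM or BAM file. The counted
#' coordinate is the biological 5' end of each alignment: the leftmost
#' aligned reference base for forward-strand alignments and the rightmost
#' aligned reference base for reverse-strand alignments. Soft-clipped bases
#' do not shift the counted position. Unmapped reads are always skipped;
#' secondary and supplementary alignments are skipped unless
#' `keep_secondary = TRUE`.
#'
#' In paired-end dRNA-seq protocols only the R1 read carries the 5' end of
#' the cDNA, so `r1_only = TRUE` drops second-in-pair records.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param r1_only drop second-in-pair alignments.
#' @param min_mapq minimum mapping quality; 0 (default) disables the filter.
#' @param keep_secondary keep secondary/supplementary alignments (off by
#'   default to avoid double counting multi-mappers).
#' @param library_id,treatment,condition,replicate library metadata, see
#'   [read_start_track()].
#' @return a `read_start_track` with `seqlengths` taken from the header.
#' @export
count_read_starts <- function(path,
                              r1_only = FALSE,
                              min_mapq = 0L,
                              keep_secondary = FALSE,
                              library_id = basename(path),
                              treatment = c("TEX_MINUS", "TEX_PLUS"),
                              condition = NA_character_,
                              replicate = 1L) {
  treatment <- match.arg(treatment)
  .assert(file.exists(path), "alignment file not found: %s", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (keep_secondary) NA else FALSE,
    isSupplementaryAlignment = if (keep_secondary) NA else FALSE,
    isSecondMateRead = if (r1_only) FALSE else NA)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    mapqFilter = if (min_mapq > 0) as.integer(min_mapq) else NA_integer_)
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  sl <- GenomeInfoDb::seqlengths(ga)
  sl <- sl[!is.na(sl)]
  if (length(ga) == 0L) {
    return(read_start_track(
      data.frame(replicon = character(0), strand = character(0),
                 pos = integer(0), count = numeric(0)),
      seqlengths = if (length(sl)) sl else NULL,
      library_id = library_id, treatment = treatment,
      condition = condition, replicate = replicate))
  }
  str <- as.character(BiocGenerics::strand(ga))
  keep <- str %in% c("+", "-")
  ga <- ga[keep]; str <- str[keep]
  pos <- ifelse(str == "+", BiocGenerics::start(ga), BiocGenerics::end(ga))
  df <- data.frame(replicon = as.character(GenomeInfoDb::seqnames(ga)),
                   strand = str, pos = pos, count = 1,
                   stringsAsFactors = FALSE)
  read_start_track(df, seqlengths = if (length(sl)) sl else NULL,
                   library_id = library_id, treatment = treatment,
                   condition = condition, replicate = replicate)
}

# ---- bedGraph ----------------------------------------------------------
# bedGraph is written/read directly: the format is 4 whitespace columns
# (chrom, 0-based start, end, value) plus optional track/comment lines,
# and the ingest contract demands per-line validation (negative values,
# overlapping intervals) that names the offending line.

.read_bedgraph_df <- function(path) {
  .assert(file.exists(path), "bedGraph file not found: %s", path)
  lines <- readLines(path)
  is_data <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(is_data)) {
    return(data.frame(replicon = character(0), pos = integer(0),
                      value = numeric(0)))
  }
  ln <- which(is_data)
  fields <- strsplit(trimws(lines[ln]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    stop(sprintf("%s line %d: expected 4 bedGraph columns, got %d",
                 path, ln[which(nf != 4L)[1]], nf[nf != 4L][1]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start0 <- suppressWarnings(as.numeric(m[, 2]))
  end0 <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start0) | is.na(end0) | is.na(value) | end0 <= start0)
  if (length(bad)) {
    stop(sprintf("%s line %d: malformed bedGraph interval", path, ln[bad[1]]),
         call. = FALSE)
  }
  neg <- which(value < 0)
  if (length(neg)) {
    stop(sprintf("%s line %d: negative bedGraph value %g", path, ln[neg[1]],
                 value[neg[1]]), call. = FALSE)
  }
  df <- data.frame(replicon = m[, 1], start0 = start0, end0 = end0,
                   value = value, line = ln, stringsAsFactors = FALSE)
  # overlap check per replicon on the 0-based half-open intervals
  for (rep_ in unique(df$replicon)) {
    d <- df[df$replicon == rep_, , drop = FALSE]
    d <- d[order(d$start0, d$end0), , drop = FALSE]
    if (nrow(d) > 1L) {
      ov <- which(d$start0[-1] < d$end0[-nrow(d)])
      if (length(ov)) {
        stop(sprintf("%s line %d: interval overlaps a previous interval on %s",
                     path, d$line[ov[1] + 1L], rep_), call. = FALSE)
      }
    }
  }
  # expand to per-position (1-based) records, dropping zero runs
  df <- df[df$value != 0, , drop = FALSE]
  w <- as.integer(df$end0 - df$start0)
  data.frame(
    replicon = rep(df$replicon, w),
    pos = sequence(w) + rep(as.integer(df$start0), w),
    value = rep(df$value, w),
    stringsAsFactors = FALSE)
}

#' Read a strand pair of bedGraph files as a read-start track
#'
#' Converts the 0-based half-open bedGraph intervals to 1-based positions.
#' Negative values and overlapping intervals are rejected with the file and
#' line of the first offence.
#'
#' @param plus_path,minus_path bedGraph files for the forward and reverse
#'   strand of the same library.
#' @param seqlengths optional named replicon lengths.
#' @inheritParams count_read_starts
#' @return a `read_start_track`.
#' @export
read_bedgraph_pair <- function(plus_path, minus_path,
                               seqlengths = NULL,
                               library_id = basename(plus_path),
                               treatment = c("TEX_MINUS", "TEX_PLUS"),
                               condition = NA_character_,
                               replicate = 1L) {
  treatment <- match.arg(treatment)
  p <- .read_bedgraph_df(plus_path)
  m <- .read_bedgraph_df(minus_path)
  counts <- rbind(
    if (nrow(p)) data.frame(replicon = p$replicon, strand = "+", pos = p$pos,
                            count = p$value, stringsAsFactors = FALSE),
    if (nrow(m)) data.frame(replicon = m$replicon, strand = "-", pos = m$pos,
                            count = m$value, stringsAsFactors = FALSE))
  if (is.null(counts)) {
    counts <- data.frame(replicon = character(0), strand = character(0),
                         pos = integer(0), count = numeric(0))
  }
  suppressWarnings(
    read_start_track(counts, seqlengths = seqlengths, library_id = library_id,
                     treatment = treatment, condition = condition,
                     replicate = replicate))
}

# run-length merge of per-position values into bedGraph intervals
.bedgraph_lines <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  o <- order(df$replicon, df$pos)
  df <- df[o, , drop = FALSE]
  new_run <- c(TRUE, df$replicon[-1] != df$replicon[-nrow(df)] |
                 df$pos[-1] != df$pos[-nrow(df)] + 1L |
                 df$value[-1] != df$value[-nrow(df)])
  run <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1] - 1L, nrow(df))
  sprintf("%s\t%d\t%d\t%s",
          df$replicon[first], df$pos[first] - 1L, df$pos[last],
          .fmt_num(df$value[first]))
}

#' Write a read-start track as a strand pair of bedGraph files
#'
#' Adjacent positions with equal values are merged into single intervals;
#' [read_bedgraph_pair()] on the output reproduces the track exactly. An
#' empty strand yields a header-only file.
#'
#' @param track a `read_start_track`.
#' @param plus_path,minus_path output paths for the two strands.
#' @return invisibly, the two paths.
#' @export
write_bedgraph_pair <- function(track, plus_path, minus_path) {
  stopifnot(inherits(track, "read_start_track"))
  for (s in c("+", "-")) {
    path <- if (s == "+") plus_path else minus_path
    d <- track$counts[track$counts$strand == s, , drop = FALSE]
    header <- sprintf('track type=bedGraph name="%s_%s"',
                      track$meta$library_id, if (s == "+") "fwd" else "rev")
    writeLines(c(header, .bedgraph_lines(
      data.frame(replicon = d$replicon, pos = d$pos, value = d$count,
                 stringsAsFactors = FALSE))), path)
  }
  invisible(c(plus_path, minus_path))
}

#' Read a coverage bedGraph (optionally strand-split) as a coverage track
#'
#' @param plus_path bedGraph for the forward strand, or for unstranded
#'   coverage when `minus_path` is `NULL`.
#' @param minus_path optional bedGraph for the reverse strand.
#' @param seqlengths optional named replicon lengths.
#' @return a [coverage_track()]; unstranded input gets strand `"*"`.
#' @export
read_coverage_bedgraph <- function(plus_path, minus_path = NULL,
                                   seqlengths = NULL) {
  p <- .read_bedgraph_df(plus_path)
  strand_p <- if (is.null(minus_path)) "*" else "+"
  depths <- data.frame(replicon = p$replicon, strand = strand_p,
                       pos = p$pos, depth = p$value, stringsAsFactors = FALSE)
  if (!is.null(minus_path)) {
    m <- .read_bedgraph_df(minus_path)
    depths <- rbind(depths,
                    data.frame(replicon = m$replicon, strand = "-",
                               pos = m$pos, depth = m$value,
                               stringsAsFactors = FALSE))
  }
  coverage_track(depths, seqlengths = seqlengths)
}

#' Write a coverage track as bedGraph
#' @param cov a [coverage_track()].
#' @param plus_path output for `"+"` or `"*"` strand depths.
#' @param minus_path optional output for `"-"` strand depths.
#' @return invisibly, the path(s).
#' @export
write_coverage_bedgraph <- function(cov, plus_path, minus_path = NULL) {
  stopifnot(inherits(cov, "coverage_track"))
  d <- cov$depths
  sel_p <- d$strand %in% c("+", "*")
  writeLines(c('track type=bedGraph name="coverage_fwd"', .bedgraph_lines(
    data.frame(replicon = d$replicon[sel_p], pos = d$pos[sel_p],
               value = d$depth[sel_p], stringsAsFactors = FALSE))), plus_path)
  if (!is.null(minus_path)) {
    sel_m <- d$strand == "-"
    writeLines(c('track type=bedGraph name="coverage_rev"', .bedgraph_lines(
      data.frame(replicon = d$replicon[sel_m], pos = d$pos[sel_m],
                 value = d$depth[sel_m], stringsAsFactors = FALSE))), minus_path)
  }
  invisible(c(plus_path, minus_path))
}
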