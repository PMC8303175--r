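#' Strand-specific read 5'-end count track
#'
#' A `read_start_track` stores, for one sequencing library (or a pooled set
#' of libraries of the same treatment), the number of read 5' ends observed
#' at each genomic position, sparsely: only positions with at least one
#' read start are kept, zeros are implicit. dRNA-seq depletion calling
#' operates entirely on these tracks.
#'
#' @param counts data.frame with columns `replicon` (character), `strand`
#'   (`"+"`/`"-"`), `pos` (1-based integer) and `count` (positive numeric;
#'   integer for raw libraries, possibly fractional after normalization).
#'   Duplicate (replicon, strand, pos) rows are summed.
#' @param seqlengths optional named numeric vector of replicon lengths.
#'   When lengths are unknown, bounds checks are relaxed.
#' @param library_id library identifier.
#' @param treatment `"TEX_PLUS"` (exonuclease treated) or `"TEX_MINUS"`
#'   (untreated control).
#' @param condition free-text condition label (e.g. a growth time point).
#' @param replicate replicate number.
#'
#' @return An object of class `read_start_track`: a list with elements
#'   `counts`, `seqlengths` and `meta` (including `total_readstarts`, kept
#'   equal to `sum(counts$count)` by every operation in the package).
#' @export
read_start_track <- function(counts,
                             seqlengths = NULL,
                             library_id = "library",
                             treatment = c("TEX_MINUS", "TEX_PLUS"),
                             condition = NA_character_,
                             replicate = 1L) {
  treatment <- match.arg(treatment)
  counts <- .normalize_counts_df(counts, value_col = "count")
  .assert(all(counts$count > 0), "track counts must be positive (zeros are implicit)")
  if (!is.null(seqlengths)) {
    .assert(!is.null(names(seqlengths)) && !anyNA(seqlengths),
            "seqlengths must be a named vector")
    known <- counts$replicon %in% names(seqlengths)
    if (any(known)) {
      lim <- seqlengths[counts$replicon[known]]
      .assert(all(counts$pos[known] >= 1 & counts$pos[known] <= lim),
              "positions outside replicon bounds")
    }
  } else {
    warning("replicon lengths unknown; bounds checks relaxed", call. = FALSE)
  }
  structure(
    list(counts = counts,
         seqlengths = seqlengths,
         meta = list(library_id = library_id,
                     treatment = treatment,
                     condition = condition,
                     replicate = as.integer(replicate),
                     total_readstarts = sum(counts$count))),
    class = "read_start_track")
}

# canonical sorted, aggregated sparse table
.normalize_counts_df <- function(df, value_col = "count") {
  .assert(is.data.frame(df), "counts must be a data.frame")
  need <- c("replicon", "strand", "pos", value_col)
  .assert(all(need %in% names(df)), "counts must have columns %s",
          paste(need, collapse = ", "))
  df <- df[, need]
  if (nrow(df) == 0L) {
    df$replicon <- character(0); df$strand <- character(0)
    df$pos <- integer(0); df[[value_col]] <- numeric(0)
    return(df)
  }
  df$replicon <- as.character(df$replicon)
  df$strand <- .match_strand(df$strand)
  .assert(all(df$pos >= 1 & df$pos == floor(df$pos)), "positions must be 1-based integers")
  df$pos <- as.integer(df$pos)
  key <- paste(df$replicon, df$strand, df$pos, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(df[[value_col]], key)
    parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    df <- data.frame(replicon = parts[, 1], strand = parts[, 2],
                     pos = as.integer(parts[, 3]), check.names = FALSE,
                     stringsAsFactors = FALSE)
    df[[value_col]] <- as.numeric(agg[, 1])
  }
  o <- order(df$replicon, df$strand, df$pos)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.read_start_track <- function(x, ...) {
  m <- x$meta
  cat(sprintf("read_start_track '%s' (%s%s)\n", m$library_id, m$treatment,
              if (is.na(m$condition)) "" else paste0(", ", m$condition)))
  cat(sprintf("  %d non-zero positions on %d replicon(s); total read starts = %s\n",
              nrow(x$counts), length(unique(x$counts$replicon)),
              format(m$total_readstarts, big.mark = ",")))
  invisible(x)
}

#' Total read starts in a track
#' @param track a `read_start_track`.
#' @return numeric total (equals the sum of all stored counts).
#' @export
total_read_starts <- function(track) {
  stopifnot(inherits(track, "read_start_track"))
  track$meta$total_readstarts
}

# counts at given positions (zeros for unstored positions)
.counts_at <- function(track, replicon, strand, positions) {
  d <- track$counts
  sel <- d$replicon == replicon & d$strand == strand
  idx <- match(positions, d$pos[sel])
  out <- d$count[sel][idx]
  out[is.na(idx)] <- 0
  out
}

# dense count vector of length len for one (replicon, strand)
.dense_counts <- function(track, replicon, strand, len) {
  v <- numeric(len)
  d <- track$counts
  sel <- d$replicon == replicon & d$strand == strand & d$pos <= len
  v[d$pos[sel]] <- d$count[sel]
  v
}

.track_replicons <- function(track) {
  union(names(track$seqlengths), unique(track$counts$replicon))
}

#' Pool read-start tracks of the same treatment
#'
#' Position-wise sum of several libraries, as used when replicates of one
#' treatment are combined before depletion testing. Pooling across
#' treatments is refused: the TEX+ / TEX- contrast is the signal.
#'
#' @param tracks list of `read_start_track` objects with identical
#'   `treatment` labels.
#' @param library_id identifier for the pooled track.
#' @return a `read_start_track` whose counts are the position-wise sums and
#'   whose `total_readstarts` is the sum of the inputs' totals.
#' @export
pool_tracks <- function(tracks, library_id = "pooled") {
  .assert(length(tracks) >= 1L, "need at least one track")
  .assert(all(vapply(tracks, inherits, logical(1), "read_start_track")),
          "all inputs must be read_start_track objects")
  treatments <- unique(vapply(tracks, function(t) t$meta$treatment, character(1)))
  .assert(length(treatments) == 1L,
          "refusing to pool across treatments (%s)", paste(treatments, collapse = ", "))
  counts <- .normalize_counts_df(do.call(rbind, lapply(tracks, `[[`, "counts")))
  sls <- lapply(tracks, `[[`, "seqlengths")
  sl <- NULL
  for (s in sls) if (!is.null(s)) sl <- c(sl, s[setdiff(names(s), names(sl))])
  suppressWarnings(
    read_start_track(counts, seqlengths = sl, library_id = library_id,
                     treatment = treatments,
                     condition = tracks[[1]]$meta$condition))
}

#' Rescale a track's counts by a library-size factor
#' @param track a `read_start_track`.
#' @param factor positive scale factor (see [scale_factors()]).
#' @return the rescaled track; `total_readstarts` is rescaled consistently.
#' @export
scale_track <- function(track, factor) {
  stopifnot(inherits(track, "read_start_track"))
  .assert(is.numeric(factor) && length(factor) == 1L && factor > 0,
          "factor must be a positive number")
  track$counts$count <- track$counts$count * factor
  track$meta$total_readstarts <- sum(track$counts$count)
  track
}

#' Per-position coverage track
#'
#' Depth-style container used for Ribo-seq (or RNA-seq) coverage. Same
#' sparse layout as [read_start_track()] but values are depths, may be
#' fractional, and a `"*"` strand is allowed for unstranded coverage.
#'
#' @param depths data.frame with columns `replicon`, `strand`
#'   (`"+"`, `"-"` or `"*"`), `pos`, `depth` (non-negative).
#' @param seqlengths optional named replicon lengths.
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(depths, seqlengths = NULL) {
  .assert(is.data.frame(depths) &&
            all(c("replicon", "strand", "pos", "depth") %in% names(depths)),
          "depths must have columns replicon, strand, pos, depth")
  .assert(all(depths$strand %in% c("+", "-", "*")), "strand must be '+', '-' or '*'")
  .assert(all(depths$depth >= 0), "depths must be non-negative")
  depths <- depths[depths$depth > 0, , drop = FALSE]
  d <- depths
  d$replicon <- as.character(d$replicon)
  d$strand <- as.character(d$strand)
  d$pos <- as.integer(d$pos)
  key <- paste(d$replicon, d$strand, d$pos, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- rowsum(d$depth, key)
    parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    d <- data.frame(replicon = parts[, 1], strand = parts[, 2],
                    pos = as.integer(parts[, 3]), depth = as.numeric(agg[, 1]),
                    stringsAsFactors = FALSE)
  }
  o <- order(d$replicon, d$strand, d$pos)
  d <- d[o, , drop = FALSE]
  rownames(d) <- NULL
  structure(list(depths = d, seqlengths = seqlengths), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d non-zero positions on %d replicon(s)\n",
              nrow(x$depths), length(unique(x$depths$replicon))))
  invisible(x)
}

.dense_depths <- function(cov, replicon, strand, len) {
  v <- numeric(len)
  d <- cov$depths
  sel <- d$replicon == replicon & d$pos <= len &
    (d$strand == strand | d$strand == "*" | strand == "*")
  if (any(sel)) {
    agg <- rowsum(d$depth[sel], d$pos[sel])
    v[as.integer(rownames(agg))] <- agg[, 1]
  }
  v
}
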