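#' Configuration of the depletion/enrichment site caller
#'
#' Parameters of the per-position Skellam test and of the clustering of
#' significant positions into sites. The defaults reproduce the stringent
#' settings used for halophilic archaea dRNA-seq reanalysis: raw p-value
#' cutoff 1e-9, at least 10 read starts in the favored library, and
#' grouping of significant positions within 5 nt.
#'
#' @param alpha per-position p-value cutoff (no multiple-testing
#'   correction by default; see `fdr`).
#' @param min_reads minimum raw read-start count in the favored library
#'   (TEX- for mode `"TPS"`, TEX+ for mode `"TSS"`) for a position to be
#'   evaluated at all.
#' @param cluster_gap maximum nt gap between significant positions merged
#'   into one site.
#' @param background_window width W (nt) of the window centered on the
#'   focal position used to estimate the local Poisson background; the
#'   focal position itself is excluded, so W/2 positions are used on each
#'   side.
#' @param winsor_quantile window counts above this empirical quantile are
#'   capped before averaging, so genuine sites do not inflate their own
#'   null.
#' @param lambda_floor lower bound on the background rate estimate.
#' @param mode `"TPS"` calls exonuclease-depletion sites (TEX- > TEX+,
#'   processed 5' monophosphate ends); `"TSS"` swaps the library roles and
#'   calls enrichment sites (TEX+ > TEX-, primary triphosphate ends).
#' @param fdr if `TRUE`, apply Benjamini-Hochberg across all evaluated
#'   positions and filter on the adjusted value instead of the raw one.
#' @return an object of class `caller_config`.
#' @export
caller_config <- function(alpha = 1e-9,
                          min_reads = 10L,
                          cluster_gap = 5L,
                          background_window = 1000L,
                          winsor_quantile = 0.975,
                          lambda_floor = 0.01,
                          mode = c("TPS", "TSS"),
                          fdr = FALSE) {
  mode <- match.arg(mode)
  .assert(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1,
          "alpha must be in (0, 1)")
  .assert(.is_count(min_reads), "min_reads must be a non-negative integer")
  .assert(.is_count(cluster_gap), "cluster_gap must be a non-negative integer")
  .assert(.is_count(background_window) && background_window >= 50,
          "background_window must be an integer >= 50")
  .assert(is.numeric(winsor_quantile) && winsor_quantile > 0.5 &&
            winsor_quantile <= 1, "winsor_quantile must be in (0.5, 1]")
  .assert(is.numeric(lambda_floor) && lambda_floor > 0,
          "lambda_floor must be positive")
  structure(list(alpha = alpha, min_reads = as.integer(min_reads),
                 cluster_gap = as.integer(cluster_gap),
                 background_window = as.integer(background_window),
                 winsor_quantile = winsor_quantile,
                 lambda_floor = lambda_floor, mode = mode, fdr = isTRUE(fdr)),
            class = "caller_config")
}

#' @export
print.caller_config <- function(x, ...) {
  cat(sprintf(
    "caller_config (mode %s): alpha = %g%s, min_reads = %d, cluster_gap = %d nt,\n  background window = %d nt (winsor %.3f, lambda floor %g)\n",
    x$mode, x$alpha, if (x$fdr) " (BH-adjusted)" else "", x$min_reads,
    x$cluster_gap, x$background_window, x$winsor_quantile, x$lambda_floor))
  invisible(x)
}

.winsor_mean <- function(x, q) {
  if (length(x) == 0L) return(0)
  cap <- stats::quantile(x, q, names = FALSE, type = 7)
  x[x > cap] <- cap
  mean(x)
}

# background over a dense vector; focal position excluded
.local_lambda_dense <- function(v, pos, config) {
  half <- config$background_window %/% 2L
  lo <- max(1L, pos - half)
  hi <- min(length(v), pos + half)
  w <- v[lo:hi][-(pos - lo + 1L)]
  max(config$lambda_floor, .winsor_mean(w, config$winsor_quantile))
}

#' Local Poisson background rate at one position
#'
#' Mean of the per-position read-start counts (zeros included) over the
#' `background_window` centered on `position`, excluding the position
#' itself, after winsorizing the window counts at the configured
#' quantile; the result is clamped below by `lambda_floor`. The window is
#' truncated at replicon edges.
#'
#' @param track a [read_start_track()].
#' @param replicon,strand,position the focal position.
#' @param config a [caller_config()].
#' @return the background rate estimate (non-negative scalar).
#' @export
local_background <- function(track, replicon, strand, position,
                             config = caller_config()) {
  stopifnot(inherits(track, "read_start_track"), inherits(config, "caller_config"))
  strand <- .match_strand(strand)
  len <- track$seqlengths[replicon]
  half <- config$background_window %/% 2L
  hi <- if (!is.null(track$seqlengths) && !is.na(len)) {
    .assert(position >= 1 && position <= len, "position outside replicon bounds")
    min(len, position + half)
  } else position + half
  lo <- max(1L, position - half)
  wpos <- setdiff(lo:hi, position)
  w <- .counts_at(track, replicon, strand, wpos)
  max(config$lambda_floor, .winsor_mean(w, config$winsor_quantile))
}

#' Scan paired tracks for candidate depletion (or enrichment) positions
#'
#' Evaluates every position whose favored-library raw count reaches
#' `min_reads`: estimates local backgrounds in both libraries, computes
#' the observed difference d = n_favored - n_other and its Skellam
#' p-value, and keeps positions with p below `alpha` (or below the BH
#' threshold when `fdr` is on). In mode `"TPS"` the favored library is
#' TEX-; mode `"TSS"` swaps the roles.
#'
#' @param track_minus,track_plus TEX- and TEX+ [read_start_track()]s
#'   covering the same replicons (a replicon present in only one track is
#'   skipped with a warning).
#' @param config a [caller_config()].
#' @return data.frame of candidate positions with columns `replicon`,
#'   `strand`, `pos`, `n_minus`, `n_plus`, `lambda_minus`, `lambda_plus`,
#'   `d_obs`, `p_value` (and `q_value` when `fdr`).
#' @export
scan_positions <- function(track_minus, track_plus, config = caller_config()) {
  stopifnot(inherits(track_minus, "read_start_track"),
            inherits(track_plus, "read_start_track"),
            inherits(config, "caller_config"))
  reps_m <- .track_replicons(track_minus)
  reps_p <- .track_replicons(track_plus)
  common <- intersect(reps_m, reps_p)
  odd <- setdiff(union(reps_m, reps_p), common)
  if (length(odd)) {
    warning(sprintf("replicon(s) %s present in only one track; skipped",
                    paste(odd, collapse = ", ")), call. = FALSE)
  }
  fav_is_minus <- config$mode == "TPS"
  out <- list()
  for (rep_ in common) {
    len <- c(track_minus$seqlengths[rep_], track_plus$seqlengths[rep_])
    len <- len[!is.na(len)][1]
    if (is.na(len) || is.null(len)) {
      len <- max(0L,
                 track_minus$counts$pos[track_minus$counts$replicon == rep_],
                 track_plus$counts$pos[track_plus$counts$replicon == rep_]) +
        config$background_window %/% 2L
    }
    for (s in c("+", "-")) {
      vm <- .dense_counts(track_minus, rep_, s, len)
      vp <- .dense_counts(track_plus, rep_, s, len)
      fav <- if (fav_is_minus) vm else vp
      oth <- if (fav_is_minus) vp else vm
      cand <- which(fav >= config$min_reads)
      if (!length(cand)) next
      lam_f <- vapply(cand, function(p) .local_lambda_dense(fav, p, config),
                      numeric(1))
      lam_o <- vapply(cand, function(p) .local_lambda_dense(oth, p, config),
                      numeric(1))
      d <- fav[cand] - oth[cand]
      p <- skellam_pvalue(d, lam_f, lam_o)
      out[[length(out) + 1L]] <- data.frame(
        replicon = rep_, strand = s, pos = cand,
        n_minus = vm[cand], n_plus = vp[cand],
        lambda_minus = if (fav_is_minus) lam_f else lam_o,
        lambda_plus = if (fav_is_minus) lam_o else lam_f,
        d_obs = d, p_value = p, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(replicon = character(0), strand = character(0), pos = integer(0),
               n_minus = numeric(0), n_plus = numeric(0),
               lambda_minus = numeric(0), lambda_plus = numeric(0),
               d_obs = numeric(0), p_value = numeric(0))
  if (config$fdr) {
    res$q_value <- stats::p.adjust(res$p_value, method = "BH")
    res <- res[res$q_value < config$alpha, , drop = FALSE]
  } else {
    res <- res[res$p_value < config$alpha, , drop = FALSE]
  }
  o <- order(res$replicon, res$strand, res$pos)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cluster candidate positions into sites
#'
#' Consecutive candidates on the same replicon and strand whose positional
#' gap is at most `cluster_gap` are chained into one site. The
#' representative position is the member with the highest favored-library
#' count, ties broken toward the 5'-most member relative to the strand;
#' the site p-value is the minimum over members.
#'
#' @param candidates output of [scan_positions()].
#' @param config a [caller_config()].
#' @return a `tps_calls` data.frame: `tps_id`, `replicon`, `strand`,
#'   `position`, `p_value`, `n_minus`, `n_plus`, `lambda_minus`,
#'   `lambda_plus`, `d_obs`, `n_members`, `members` (comma-separated),
#'   sorted by replicon then position.
#' @export
cluster_candidates <- function(candidates, config = caller_config()) {
  stopifnot(inherits(config, "caller_config"))
  fav_col <- if (config$mode == "TPS") "n_minus" else "n_plus"
  prefix <- config$mode
  rows <- list()
  if (nrow(candidates)) {
    o <- order(candidates$replicon, candidates$strand, candidates$pos)
    candidates <- candidates[o, , drop = FALSE]
    grp_key <- paste(candidates$replicon, candidates$strand, sep = "\r")
    for (key in unique(grp_key)) {
      d <- candidates[grp_key == key, , drop = FALSE]
      cl <- cumsum(c(1L, as.integer(diff(d$pos) > config$cluster_gap)))
      for (ci in unique(cl)) {
        m <- d[cl == ci, , drop = FALSE]
        fav <- m[[fav_col]]
        best <- which(fav == max(fav))
        rep_idx <- if (m$strand[1] == "+") best[which.min(m$pos[best])] else
          best[which.max(m$pos[best])]
        r <- m[rep_idx, , drop = FALSE]
        r$p_value <- min(m$p_value)
        r$n_members <- nrow(m)
        r$members <- paste(m$pos, collapse = ",")
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicon = character(0), strand = character(0), pos = integer(0),
               n_minus = numeric(0), n_plus = numeric(0),
               lambda_minus = numeric(0), lambda_plus = numeric(0),
               d_obs = numeric(0), p_value = numeric(0),
               n_members = integer(0), members = character(0))
  names(res)[names(res) == "pos"] <- "position"
  res$tps_id <- if (nrow(res)) sprintf("%s_%s_%s_%d", prefix, res$replicon,
                                       res$strand, res$position) else character(0)
  res <- res[order(res$replicon, res$position),
             c("tps_id", "replicon", "strand", "position", "p_value",
               "n_minus", "n_plus", "lambda_minus", "lambda_plus", "d_obs",
               "n_members", "members")]
  rownames(res) <- NULL
  class(res) <- c("tps_calls", "data.frame")
  attr(res, "config") <- config
  res
}

#' Call processing (or start) sites from a TEX-/TEX+ library pair
#'
#' The central entry point of the caller: [scan_positions()] followed by
#' [cluster_candidates()]. With the default mode `"TPS"` it reports
#' positions where read 5' ends are significantly depleted by TEX
#' treatment (the 5' monophosphate signature of processed transcripts);
#' mode `"TSS"` reports TEX enrichment (primary 5' triphosphate ends).
#'
#' @inheritParams scan_positions
#' @return a `tps_calls` object (see [cluster_candidates()]).
#' @examples
#' design <- sim_design(n_genes = 5, replicon_length = 20000, seed = 1)
#' genes <- generate_annotation(design)
#' truth <- plant_truth(genes, tps_per_gene = 1, tss_per_gene = 0, seed = 1)
#' tm <- simulate_library(truth, design, "TEX_MINUS", seed = 1)
#' tp <- simulate_library(truth, design, "TEX_PLUS", seed = 1)
#' call_sites(tm, tp)
#' @export
call_sites <- function(track_minus, track_plus, config = caller_config()) {
  if (track_minus$meta$treatment != "TEX_MINUS" ||
      track_plus$meta$treatment != "TEX_PLUS") {
    warning("track treatments do not match argument roles (TEX_MINUS, TEX_PLUS)",
            call. = FALSE)
  }
  cluster_candidates(scan_positions(track_minus, track_plus, config), config)
}

#' @export
print.tps_calls <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("%s calls: %d site(s) on %d replicon(s)\n",
              if (is.null(cfg)) "site" else cfg$mode, nrow(x),
              length(unique(x$replicon))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
summary.tps_calls <- function(object, ...) {
  cfg <- attr(object, "config")
  cat(sprintf("%d %s call(s)", nrow(object),
              if (is.null(cfg)) "site" else cfg$mode))
  if (!is.null(cfg)) cat(sprintf(" at alpha %g, min_reads %d", cfg$alpha, cfg$min_reads))
  cat("\n")
  if (nrow(object)) {
    cat("per replicon/strand:\n")
    print(table(object$replicon, object$strand))
    cat(sprintf("cluster sizes: median %g, max %d\n",
                stats::median(object$n_members), max(object$n_members)))
  }
  invisible(object)
}

#' Write site calls as TSV
#' @param calls a `tps_calls` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tps_table <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write site calls as BED6
#'
#' Score column is -log10(p) capped at 300.
#' @inheritParams write_tps_table
#' @export
write_tps_bed <- function(calls, path) {
  score <- pmin(300, -log10(pmax(calls$p_value, 1e-300)))
  lines <- sprintf("%s\t%d\t%d\t%s\t%.6g\t%s",
                   calls$replicon, calls$position - 1L, calls$position,
                   calls$tps_id, score, calls$strand)
  writeLines(lines, path)
  invisible(path)
}
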