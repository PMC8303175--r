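#' Load and validate a pipeline configuration
#'
#' The configuration is one declarative YAML document (or an equivalent
#' nested list). Top-level keys: `outdir`, `seed`, `species` (a list; each
#' entry has `name`, `gff` and `libraries`, where each library carries
#' `id`, `treatment`, `condition`, `replicate`, `bedgraph_plus`,
#' `bedgraph_minus`), and the optional blocks `orthologs` (TSV path,
#' needs two species), `riboseq` (`species`, `bedgraph_plus`, optional
#' `bedgraph_minus`), `caller`, `annotation`, `conservation`,
#' `coincidence`, `quant` and `ribo` parameter blocks. `overrides` (e.g.
#' from command-line flags) take precedence over the file, which takes
#' precedence over defaults.
#'
#' @param config YAML file path or nested list.
#' @param overrides named list merged over the file values.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config, overrides = list()) {
  if (is.character(config)) {
    .assert(file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  .assert(is.list(config), "config must be a list or a YAML path")
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(over[[nm]]) && is.list(base[[nm]]))
        merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  defaults <- list(
    outdir = "tpsmap_out", seed = 1L,
    caller = list(), annotation = list(ext_up = 150L, ext_down = 150L,
                                       feature_type = "CDS"),
    conservation = list(threshold = 3),
    coincidence = list(window = 5L),
    quant = list(mode = "match_max", pseudocount = 1, effect_floor = 1,
                 halfwidth = 2L),
    ribo = list(window = 200L, min_z = 2, min_height = 5, adjacency = 10L))
  cfg <- merge_lists(merge_lists(defaults, config), overrides)
  .assert(!is.null(cfg$species) && length(cfg$species) >= 1,
          "config must define at least one species")
  for (sp in cfg$species) {
    .assert(!is.null(sp$name), "every species needs a name")
    .assert(!is.null(sp$gff) && file.exists(sp$gff),
            "species %s: annotation file not found: %s", sp$name,
            if (is.null(sp$gff)) "<missing>" else sp$gff)
    treatments <- vapply(sp$libraries, function(l) l$treatment %||% "",
                         character(1))
    .assert("TEX_MINUS" %in% treatments,
            "species %s has no TEX_MINUS library", sp$name)
    .assert("TEX_PLUS" %in% treatments,
            "species %s has no TEX_PLUS library", sp$name)
    for (l in sp$libraries) {
      for (f in c(l$bedgraph_plus, l$bedgraph_minus)) {
        .assert(file.exists(f), "species %s, library %s: file not found: %s",
                sp$name, l$id %||% "?", f)
      }
    }
  }
  if (!is.null(cfg$orthologs)) {
    .assert(length(cfg$species) >= 2,
            "ortholog comparison needs two species")
    .assert(file.exists(cfg$orthologs), "ortholog table not found: %s",
            cfg$orthologs)
  }
  if (!is.null(cfg$riboseq)) {
    .assert(!is.null(cfg$riboseq$species) &&
              cfg$riboseq$species %in% vapply(cfg$species, `[[`, character(1),
                                              "name"),
            "riboseq block must name a configured species")
    .assert(file.exists(cfg$riboseq$bedgraph_plus),
            "riboseq coverage not found: %s", cfg$riboseq$bedgraph_plus)
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full processing-site pipeline
#'
#' Executes ingest (bedGraph pairs, pooling per treatment), site calling,
#' annotation and summaries for every configured species, then the
#' cross-species layers (conservation, species-specific internal sites,
#' sense/antisense coincidence, antisense co-presence) when an ortholog
#' table is configured, Ribo-seq peak overlap when coverage is
#' configured, and a two-condition differential comparison when a species
#' has TEX- libraries from two conditions. Every stage's outputs are
#' written under `outdir` as TSV/BED files together with `manifest.tsv`
#' (file checksums) and `run_log.txt` (all effective parameters);
#' re-running with the same configuration is byte-identical. A failing
#' stage writes a `FAILED` marker naming the stage and aborts.
#'
#' @param config a [pipeline_config()] (or path / list accepted by it).
#' @param overrides optional overrides, see [pipeline_config()].
#' @return invisibly, a list with the per-species results, the
#'   cross-species tables, and the manifest.
#' @export
run_pipeline <- function(config, overrides = list()) {
  cfg <- if (inherits(config, "pipeline_config") && !length(overrides))
    config else pipeline_config(config, overrides)
  outdir <- cfg$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(outdir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 failed_marker)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  caller_cfg <- do.call(caller_config, cfg$caller)
  results <- list()
  for (sp in cfg$species) {
    nm <- sp$name
    tracks <- stage(paste0("ingest:", nm), lapply(sp$libraries, function(l) {
      read_bedgraph_pair(l$bedgraph_plus, l$bedgraph_minus,
                         library_id = l$id %||% basename(l$bedgraph_plus),
                         treatment = l$treatment,
                         condition = l$condition %||% NA_character_,
                         replicate = l$replicate %||% 1L)
    }))
    treatments <- vapply(tracks, function(t) t$meta$treatment, character(1))
    pooled_minus <- stage(paste0("pool:", nm),
                          pool_tracks(tracks[treatments == "TEX_MINUS"],
                                      paste0(nm, "_TEX_MINUS")))
    pooled_plus <- stage(paste0("pool:", nm),
                         pool_tracks(tracks[treatments == "TEX_PLUS"],
                                     paste0(nm, "_TEX_PLUS")))
    calls <- stage(paste0("call:", nm),
                   call_sites(pooled_minus, pooled_plus, caller_cfg))
    emit(calls, sprintf("%s_tps.tsv", nm))
    bed_path <- file.path(outdir, sprintf("%s_tps.bed", nm))
    stage(paste0("call:", nm), write_tps_bed(calls, bed_path))
    outputs <- c(outputs, bed_path)
    genes <- stage(paste0("annotate:", nm),
                   load_annotation(sp$gff,
                                   cfg$annotation$feature_type %||% "CDS"))
    ann <- stage(paste0("annotate:", nm),
                 assign_tps(calls, genes,
                            ext_up = cfg$annotation$ext_up %||% 150L,
                            ext_down = cfg$annotation$ext_down %||% 150L))
    emit(ann, sprintf("%s_annotation.tsv", nm))
    summ <- stage(paste0("summarize:", nm), summarize_annotations(ann))
    emit(summ$multiplicity, sprintf("%s_multiplicity.tsv", nm))
    emit(summ$d_histogram, sprintf("%s_d_histogram.tsv", nm))
    emit(summ$densest, sprintf("%s_densest_window.tsv", nm))
    coin <- stage(paste0("coincide:", nm),
                  coincident_atps(ann, cfg$coincidence$window %||% 5L))
    emit(coin, sprintf("%s_tps_atps_coincidence.tsv", nm))
    results[[nm]] <- list(tracks = tracks, calls = calls, genes = genes,
                          annotation = ann, summaries = summ,
                          coincidence = coin)
  }
  sp_names <- vapply(cfg$species, `[[`, character(1), "name")
  conserved <- NULL
  if (!is.null(cfg$orthologs)) {
    a <- sp_names[1]; b <- sp_names[2]
    pairs <- stage("conserve", read_ortholog_pairs(cfg$orthologs))
    conserved <- stage("conserve",
                       conserved_sites(results[[a]]$annotation,
                                       results[[b]]$annotation, pairs,
                                       cfg$conservation$threshold %||% 3))
    emit(conserved, "conserved_tps.tsv")
    spec_int <- stage("conserve",
                      specific_internal(results[[a]]$annotation,
                                        results[[b]]$annotation, pairs))
    emit(data.frame(locus = spec_int$a_specific),
         sprintf("%s_specific_internal.tsv", a))
    emit(data.frame(locus = spec_int$b_specific),
         sprintf("%s_specific_internal.tsv", b))
    catps <- stage("conserve",
                   conserved_atps(results[[a]]$annotation,
                                  results[[b]]$annotation, pairs))
    emit(catps, "conserved_atps.tsv")
    results$conserved <- conserved
    results$specific_internal <- spec_int
    results$conserved_atps <- catps
  }
  if (!is.null(cfg$riboseq)) {
    nm <- cfg$riboseq$species
    cov <- stage("ribo", read_coverage_bedgraph(
      cfg$riboseq$bedgraph_plus, cfg$riboseq$bedgraph_minus))
    peaks <- stage("ribo", call_ribo_peaks(
      cov, window = cfg$ribo$window %||% 200L,
      min_z = cfg$ribo$min_z %||% 2, min_height = cfg$ribo$min_height %||% 5))
    emit(peaks, "ribo_peaks.tsv")
    sites <- results[[nm]]$calls
    if (!is.null(conserved)) {
      ids <- if (nm == sp_names[1]) conserved$tps_a else conserved$tps_b
      sub <- sites[sites$tps_id %in% ids, , drop = FALSE]
      if (nrow(sub)) sites <- sub
    }
    ov <- stage("ribo", overlap_fraction(sites, peaks,
                                         cfg$ribo$adjacency %||% 10L))
    emit(ov$table, "ribo_overlap.tsv")
    emit(data.frame(n_overlapping = ov$n_overlapping, n_total = ov$n_total,
                    fraction = ov$fraction, percent = ov$percent),
         "ribo_overlap_summary.tsv")
    results$ribo <- list(peaks = peaks, overlap = ov)
  }
  for (sp in cfg$species) {
    nm <- sp$name
    conds <- unique(stats::na.omit(vapply(sp$libraries, function(l) {
      if ((l$treatment %||% "") == "TEX_MINUS") l$condition %||% NA_character_
      else NA_character_
    }, character(1))))
    if (length(conds) >= 2) {
      conds <- sort(conds)[1:2]
      tr <- results[[nm]]$tracks
      pick <- function(cond) {
        sel <- vapply(tr, function(t) t$meta$treatment == "TEX_MINUS" &&
                        identical(t$meta$condition, cond), logical(1))
        pool_tracks(tr[sel], paste0(nm, "_", cond))
      }
      diff_tab <- stage(paste0("diff:", nm), {
        ta <- pick(conds[1]); tb <- pick(conds[2])
        f <- scale_factors(stats::setNames(c(total_read_starts(ta),
                                             total_read_starts(tb)), conds),
                           mode = cfg$quant$mode %||% "match_max")
        differential_sites(scale_track(ta, f[1]), scale_track(tb, f[2]),
                           results[[nm]]$annotation, results[[nm]]$genes,
                           halfwidth = cfg$quant$halfwidth %||% 2L,
                           pseudocount = cfg$quant$pseudocount %||% 1,
                           effect_floor = cfg$quant$effect_floor %||% 1)
      })
      emit(diff_tab, sprintf("%s_differential.tsv", nm))
      results[[nm]]$differential <- diff_tab
    }
  }
  log_path <- file.path(outdir, "run_log.txt")
  writeLines(c("tpsmap run log", "effective configuration:",
               yaml::as.yaml(unclass(cfg))), log_path)
  outputs <- unique(c(outputs, log_path))
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  utils::write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  results$manifest <- manifest
  results$outdir <- outdir
  invisible(results)
}
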