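#' Pipeline run configuration
#'
#' Collects every user-facing parameter with its default: the discordance
#' level `alpha` (0.01), depth window size (100 bp), gain/loss state thresholds
#' (+0.4 / -0.4), minimum cluster support (2), mapping-quality floor (1),
#' quality-tier phred thresholds (30/20), TE identity threshold (0.9),
#' breakpoint-match tolerance (100 bp; see [define_svs()]), somatic mode, seed
#' and worker count.
#'
#' @param tumour Path to the tumour/case SAM/BAM, or a pair tibble.
#' @param normal Optional matched-normal SAM/BAM or pair tibble (required when
#'   `somatic = TRUE`).
#' @param reference Path to a FASTA, or a `DNAStringSet`.
#' @param sd_track,ssr_track,te_track Optional repeat BED paths.
#' @param alpha,window_size,gain_threshold,loss_threshold,min_support,
#'   mapq_floor,tolerance,te_min_identity Numeric parameters (see above).
#' @param library_type `"paired_end"` or `"mate_pair"`.
#' @param somatic Subtract normal-shared clusters and flag calls somatic.
#' @param seed Seed for any randomized steps (none in the core pipeline; kept
#'   for reproducibility of user extensions).
#' @param workers Per-chromosome parallel workers for classification/depth
#'   (results are identical to a serial run).
#' @return A list of class `sv_config`.
#' @export
sv_config <- function(tumour, normal = NULL, reference, sd_track = NULL,
                      ssr_track = NULL, te_track = NULL, alpha = 0.01,
                      window_size = 100, gain_threshold = 0.4,
                      loss_threshold = -0.4, min_support = 2, mapq_floor = 1,
                      tolerance = 100, te_min_identity = 0.9,
                      library_type = "paired_end", somatic = FALSE, seed = 1,
                      workers = 1) {
  if (somatic && is.null(normal)) {
    abort("somatic mode requires a matched normal sample")
  }
  stopifnot(alpha > 0, alpha < 1, window_size >= 10, min_support >= 1,
            gain_threshold > 0, loss_threshold < 0, workers >= 1)
  structure(
    list(tumour = tumour, normal = normal, reference = reference,
         sd_track = sd_track, ssr_track = ssr_track, te_track = te_track,
         alpha = alpha, window_size = window_size,
         gain_threshold = gain_threshold, loss_threshold = loss_threshold,
         min_support = min_support, mapq_floor = mapq_floor,
         tolerance = tolerance, te_min_identity = te_min_identity,
         library_type = library_type, somatic = somatic, seed = seed,
         workers = workers),
    class = "sv_config"
  )
}

load_sample <- function(x) {
  if (is.data.frame(x)) return(as_tibble(x))
  read_alignments(x)
}

load_reference <- function(x) {
  if (inherits(x, "DNAStringSet")) return(x)
  Biostrings::readDNAStringSet(x)
}

# split-apply over chromosomes, optionally in parallel; deterministic merge
per_chrom <- function(keys, items, fun, workers) {
  groups <- split(items, keys)
  groups <- groups[order(names(groups))]
  res <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(groups, fun, mc.cores = workers)
  } else {
    lapply(groups, fun)
  }
  bind_rows(res)
}

#' Run the full SV-calling workflow
#'
#' Executes classification, clustering, read-depth analysis, SV interpretation
#' and (when tracks are provided) the repeat-annotation filter, and writes the
#' results tree: `Results/clusters` (cluster tables), `Results/dofc`
#' (depth-of-coverage signal and segments), `Results/sv` (one file per
#' reported type plus putative/undefined and the filter partition), and a JSON
#' run log with the configuration and per-stage counts. Inter-chromosomal
#' pairs are routed by their lexicographically smaller chromosome so
#' per-chromosome work units are well defined; re-running an identical
#' configuration is byte-identical.
#'
#' @param config An [sv_config()].
#' @param out_dir Output directory (a `Results/` tree is created inside).
#' @return Invisibly, a list of class `sv_result`: `model`, `pairs_summary`,
#'   `clusters`, `windows`, `segments`, `calls`, `config`, `out_dir`.
#' @export
run_sv_pipeline <- function(config, out_dir = "Results") {
  stopifnot(inherits(config, "sv_config"))
  reference <- load_reference(config$reference)
  chrom_lengths <- setNames(Biostrings::width(reference), names(reference))
  tumour <- load_sample(config$tumour)
  normal <- if (!is.null(config$normal)) load_sample(config$normal)

  # insert model per sample, from properly oriented pairs
  model_t <- estimate_insert_model(tumour, alpha = config$alpha)
  route_key <- function(p) {
    k <- pmin(p$chrom1, p$chrom2, na.rm = TRUE)
    k[is.na(k)] <- "*unmapped*"
    k
  }
  classify_sample <- function(pairs, model) {
    per_chrom(route_key(pairs), pairs, function(p) {
      classify_pairs(p, model, library_type = config$library_type,
                     mapq_floor = config$mapq_floor)
    }, config$workers)
  }
  tumour <- classify_sample(tumour, model_t)

  clusters <- cluster_pairs(tumour, model_t, min_support = config$min_support)
  if (config$somatic) {
    model_n <- estimate_insert_model(normal, alpha = config$alpha)
    normal_cls <- classify_sample(normal, model_n)
    clusters <- subtract_shared(clusters, normal_cls, model_t)
  }
  clusters <- predict_breakpoints(clusters, model_t, chrom_lengths)

  # depth on the tumour sample
  reads <- reads_from_pairs(tumour)
  mean_cov <- sum(reads$end - reads$start + 1) / sum(chrom_lengths)
  windows <- bin_reads(reads, reference, window_size = config$window_size)
  windows <- gc_normalize(windows)
  windows <- transform_depth(windows)
  segments <- segment_depth(windows, gain_threshold = config$gain_threshold,
                            loss_threshold = config$loss_threshold)
  clusters <- annotate_confidence(clusters, mean_cov)

  calls <- define_svs(clusters, segments, window_size = config$window_size,
                      tolerance = config$tolerance)
  has_tracks <- !is.null(config$sd_track) || !is.null(config$ssr_track) ||
    !is.null(config$te_track)
  if (has_tracks) {
    ann <- load_repeat_tracks(config$sd_track, config$ssr_track,
                              config$te_track,
                              te_min_identity = config$te_min_identity)
    calls <- final_count_down(calls, ann)
  }

  # ---- results tree ------------------------------------------------------
  res_dir <- file.path(out_dir)
  for (d in c("clusters", "dofc", "sv")) {
    dir.create(file.path(res_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  write_clusters(clusters, file.path(res_dir, "clusters", "clusters.tsv"))
  write_insert_model(model_t, file.path(res_dir, "clusters", "insert_model.json"))
  write_depth(windows, segments, file.path(res_dir, "dofc"))
  write_sv_calls(calls, file.path(res_dir, "sv"))

  counts <- count_categories(tumour)
  log <- list(
    package = "pairsv",
    version = as.character(utils::packageVersion("pairsv")),
    config = config[!vapply(config, function(x)
      is.data.frame(x) || inherits(x, "DNAStringSet"), TRUE)],
    pairs_in = nrow(tumour),
    category_counts = setNames(as.list(counts$n), counts$category),
    n_clusters = nrow(clusters),
    n_segments = nrow(segments),
    n_calls = nrow(calls),
    mean_coverage = mean_cov
  )
  jsonlite::write_json(log, file.path(res_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(structure(
    list(model = model_t, pairs_summary = counts, clusters = clusters,
         windows = windows, segments = segments, calls = calls,
         config = config, out_dir = res_dir),
    class = "sv_result"
  ))
}

#' @export
print.sv_result <- function(x, ...) {
  cat("<sv_result> ", nrow(x$clusters), " cluster(s), ", nrow(x$segments),
      " depth segment(s), ", nrow(x$calls), " SV call(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.sv_result <- function(x, ...) x$calls

#' @export
glance.sv_result <- function(x, ...) {
  tibble(
    n_pairs = sum(x$pairs_summary$n),
    n_clusters = nrow(x$clusters),
    n_segments = nrow(x$segments),
    n_calls = nrow(x$calls),
    n_somatic = sum(x$calls$somatic),
    alpha = x$config$alpha
  )
}

#' Write SV calls, one file per reported type
#'
#' Coordinates are written 1-based inclusive. When the filter has run, the
#' partition files (`filtered_sd.tsv` etc.) are written alongside.
#'
#' @param calls SV-call tibble.
#' @param dir Output directory.
#' @export
write_sv_calls <- function(calls, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- calls
  out$cluster_ids <- vapply(out$cluster_ids, paste, "", collapse = ",")
  # 1-based inclusive on output: half-open his become inclusive ends
  for (col in c("source_hi", "insert_hi", "bp1_hi", "bp2_hi")) {
    out[[col]] <- out[[col]] - 1L
  }
  types <- c("deletion", "gain", "inversion", "intra_translocation",
             "inter_translocation", "putative", "undefined")
  for (tp in types) {
    readr::write_tsv(out[out$reported_type == tp, ],
                     file.path(dir, paste0(tp, ".tsv")))
  }
  if ("filter_verdict" %in% names(out)) {
    for (v in c("passed", "in_sd", "in_ssr", "in_te")) {
      readr::write_tsv(out[out$filter_verdict == v, ],
                       file.path(dir, paste0("filter_", v, ".tsv")))
    }
  }
  invisible(dir)
}
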