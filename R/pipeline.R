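#' Analysis configuration
#'
#' Collects every tunable of the pipeline with its standard default: 6-bp
#' scoring window, 3-SD peak threshold, 500 bp cluster gap, RD class
#' thresholds -1.0 / -0.5, 5 kb flanks with 100 bp bins, loess spans
#' 0.1 / 0.2, 50 difference points, 999 background bins, 0.90 replicate-
#' concordance gate, and 10 kb isolation radius.
#'
#' @param window Scoring/summit window, positions.
#' @param scale Depth-normalization constant.
#' @param qc_gate Minimal replicate Pearson correlation.
#' @param rd_dependent,rd_independent RD class thresholds.
#' @param weak_fraction,weak_method Weak-signal filter (see [filter_pres()]).
#' @param k_sd Peak threshold in background SD units.
#' @param max_gap Cluster gap, bp.
#' @param isolation Isolation radius, bp.
#' @param flank,bin Profile window half-width and bin width, bp.
#' @param span_profile,span_difference Loess spans.
#' @param n_points Difference evaluation points.
#' @param n_bins Random background bins.
#' @param difference_scale `"summit"` or `"none"` (see
#'   [profile_difference()]).
#' @param peak_genotype Genotype whose ChIP tracks define peaks.
#' @param peak_mode Replicate handling in [call_peaks()]: `"reproducible"`
#'   (default) or `"average"`.
#' @param seed Seed for randomized background placement.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(window = 6L, scale = 1e6, qc_gate = 0.90,
                            rd_dependent = -1.0, rd_independent = -0.5,
                            weak_fraction = 0.30, weak_method = "range",
                            k_sd = 3, max_gap = 500L, isolation = 10000,
                            flank = 5000L, bin = 100L, span_profile = 0.1,
                            span_difference = 0.2, n_points = 50L,
                            n_bins = 999L, difference_scale = "summit",
                            peak_genotype = "control",
                            peak_mode = "reproducible", seed = 1L) {
  stopifnot(window >= 1, scale > 0, qc_gate >= 0, qc_gate <= 1,
            rd_dependent <= rd_independent, weak_fraction >= 0,
            weak_fraction <= 1, k_sd >= 0, max_gap >= 0, isolation >= 0,
            flank > 0, bin > 0, span_profile > 0, span_profile <= 1,
            span_difference > 0, span_difference <= 1, n_points >= 10,
            n_bins >= 1)
  structure(
    list(window = as.integer(window), scale = scale, qc_gate = qc_gate,
         rd_dependent = rd_dependent, rd_independent = rd_independent,
         weak_fraction = weak_fraction, weak_method = weak_method,
         k_sd = k_sd, max_gap = as.integer(max_gap), isolation = isolation,
         flank = as.integer(flank), bin = as.integer(bin),
         span_profile = span_profile, span_difference = span_difference,
         n_points = as.integer(n_points), n_bins = as.integer(n_bins),
         difference_scale = difference_scale, peak_genotype = peak_genotype,
         peak_mode = peak_mode, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' The Su(z)2-1.b8 deletion interval
#'
#' The 180.6 kb deficiency removing the Psc and Su(z)2 transcription units in
#' the PRC1-deficient line; candidate elements overlapping it cannot be
#' scored in that genotype and are excluded from classification.
#'
#' @return One-row tibble (chrom, start, end), Dm3 (2006) coordinates.
#' @export
suz2_deletion <- function() {
  tibble(chrom = "chr2R", start = 8828024, end = 9009615)
}

qc_concordance <- function(scores) {
  scores |>
    dplyr::group_by(.data$genotype, .data$type) |>
    dplyr::group_modify(function(d, key) {
      wide <- tidyr::pivot_wider(
        dplyr::select(d, "name", "replicate", "norm_score"),
        names_from = "replicate", values_from = "norm_score")
      reps <- names(wide)[-1]
      pairs <- utils::combn(reps, 2, simplify = FALSE)
      purrr::map_dfr(pairs, function(p) {
        tibble(rep_a = p[1], rep_b = p[2],
               r = replicate_concordance(wide[[p[1]]], wide[[p[2]]]))
      })
    }) |>
    dplyr::ungroup()
}

#' Run the full comparative occupancy pipeline
#'
#' Scores the catalog in every library, gates on replicate concordance,
#' filters the catalog (exclusion overlap, weak control signal), classifies
#' elements by RD, compares the ChIP RD distribution with the matched input
#' RD distribution (Wilcoxon rank sum), calls peaks on the configured
#' genotype, and runs the distal-loss profile comparison around isolated
#' peaks. Re-running with identical inputs, config and seed is bit-identical.
#'
#' @param tracks Library tibble (genotype, replicate, type, track) as
#'   produced by [simulate_tracks()], or assembled from [read_bedgraph()]
#'   tracks.
#' @param catalog Candidate-element tibble (chrom, start, end, name).
#' @param exclusions Optional exclusion intervals (chrom, start, end).
#' @param config An [analysis_config()].
#' @param control,mutant Genotype labels.
#' @param out_dir Optional directory to write the report bundle into.
#' @param force Proceed despite a failed concordance gate.
#' @return List: scores, qc, filtered (catalog with reasons), classification
#'   (a `pre_classification`), class_summary, chip_vs_input, peaks,
#'   profiles, class report paths (when `out_dir` is given).
#' @export
run_pipeline <- function(tracks, catalog, exclusions = NULL,
                         config = analysis_config(), control = "control",
                         mutant = "mutant", out_dir = NULL, force = FALSE) {
  scores <- score_pres(catalog, tracks, window = config$window,
                       scale = config$scale)
  qc <- qc_concordance(scores)
  bad <- qc[qc$type == "chip" & qc$r <= config$qc_gate, , drop = FALSE]
  if (nrow(bad) > 0) {
    msg <- sprintf(
      "Replicate concordance gate failed (r <= %.2f): %s.",
      config$qc_gate,
      paste(sprintf("%s chip %s/%s r=%.3f", bad$genotype, bad$rep_a,
                    bad$rep_b, bad$r), collapse = "; "))
    if (!force) abort(msg, class = "predep_qc_error")
    warn(paste(msg, "Proceeding because force = TRUE."))
  }

  control_chip <- scores |>
    dplyr::filter(.data$genotype == control, .data$type == "chip") |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(score = mean(.data$norm_score), .groups = "drop")
  control_chip <- control_chip[match(catalog$name, control_chip$name), ]
  filtered <- filter_pres(catalog, control_chip$score, exclusions,
                          weak_fraction = config$weak_fraction,
                          method = config$weak_method)
  kept <- filtered$name[is.na(filtered$filtered_reason)]
  inform(sprintf("Catalog filter: %d of %d elements kept (%s).",
                 length(kept), nrow(catalog),
                 paste(sprintf("%s: %d",
                               names(table(filtered$filtered_reason)),
                               table(filtered$filtered_reason)),
                       collapse = ", ")))

  classification <- classify_pres(
    scores[scores$name %in% kept, , drop = FALSE],
    control = control, mutant = mutant,
    rd_dependent = config$rd_dependent,
    rd_independent = config$rd_independent
  )
  class_summary <- summarize_classes(classification)
  chip_vs_input <- if (!all(is.na(classification$rd_input))) {
    compare_distributions(classification$rd, classification$rd_input)
  } else {
    NULL
  }

  norm_tr <- function(geno, type) {
    lapply(which(tracks$genotype == geno & tracks$type == type),
           function(i) normalize_track(tracks$track[[i]], config$scale))
  }
  peak_tracks <- norm_tr(config$peak_genotype, "chip")
  peaks <- call_peaks(peak_tracks, k_sd = config$k_sd,
                      max_gap = config$max_gap, window = config$window,
                      min_distance = config$isolation,
                      mode = config$peak_mode)
  iso <- peaks[peaks$isolated, , drop = FALSE]
  profiles <- if (nrow(iso) > 0) {
    compare_profiles(norm_tr(mutant, "chip"), norm_tr(control, "chip"),
                     iso, excluded = peaks,
                     flank = config$flank, bin = config$bin,
                     span = config$span_profile,
                     n_points = config$n_points,
                     smooth_span = config$span_difference,
                     scale = config$difference_scale,
                     n_bins = config$n_bins, seed = config$seed)
  } else {
    warn("No isolated peaks; skipping profile comparison.")
    NULL
  }

  result <- list(scores = scores, qc = qc, filtered = filtered,
                 classification = classification,
                 class_summary = class_summary,
                 chip_vs_input = chip_vs_input, peaks = peaks,
                 profiles = profiles, config = config)
  if (!is.null(out_dir)) result$paths <- write_report(result, out_dir)
  result
}

write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(result$scores, p("scores.tsv"), progress = FALSE)
  readr::write_tsv(result$qc, p("qc.tsv"), progress = FALSE)
  readr::write_tsv(result$filtered, p("catalog_filtered.tsv"),
                   progress = FALSE)
  readr::write_tsv(tibble::as_tibble(result$classification),
                   p("classification.tsv"), progress = FALSE)
  write_peaks(result$peaks, p("peaks.bed"))
  if (!is.null(result$profiles)) {
    readr::write_tsv(
      dplyr::bind_rows(
        mutant = as_tibble(result$profiles$profiles$mutant),
        control = as_tibble(result$profiles$profiles$control),
        .id = "genotype"),
      p("profiles.tsv"), progress = FALSE)
    readr::write_tsv(
      dplyr::bind_rows(
        mutant = tibble::as_tibble(result$profiles$curves$mutant),
        control = tibble::as_tibble(result$profiles$curves$control),
        difference = tibble::as_tibble(result$profiles$difference),
        .id = "curve"),
      p("curves.tsv"), progress = FALSE)
  }
  summary <- list(
    n_total = result$class_summary$n_total,
    n_per_class = list(
      dependent = result$class_summary$n_dependent,
      intermediate = result$class_summary$n_intermediate,
      independent = result$class_summary$n_independent),
    fraction_independent = result$class_summary$fraction_independent,
    median_rd = median(result$classification$rd),
    median_ratio = median(result$classification$ratio, na.rm = TRUE),
    rd_formula = "2*(m - c)/(m + c)",
    wilcoxon_chip_vs_input = if (!is.null(result$chip_vs_input)) {
      as.list(result$chip_vs_input)
    },
    n_peaks = nrow(result$peaks),
    n_isolated_peaks = sum(result$peaks$isolated),
    background = if (!is.null(result$profiles)) {
      as.list(tibble::deframe(result$profiles$background))
    },
    difference_summary = if (!is.null(result$profiles)) {
      as.list(result$profiles$summary)
    },
    difference_scale = result$config$difference_scale,
    seed = result$config$seed
  )
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  cfg <- result$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, p("config.yaml"))
  log <- c(
    sprintf("predep %s", as.character(utils::packageVersion("predep"))),
    sprintf("libraries scored: %d", dplyr::n_distinct(
      paste(result$scores$genotype, result$scores$replicate,
            result$scores$type))),
    sprintf("catalog: %d elements, %d kept", nrow(result$filtered),
            sum(is.na(result$filtered$filtered_reason))),
    sprintf("filter reasons: %s", paste(
      sprintf("%s=%d", names(table(result$filtered$filtered_reason)),
              table(result$filtered$filtered_reason)), collapse = ", ")),
    sprintf("peaks: %d (%d isolated)", nrow(result$peaks),
            sum(result$peaks$isolated)),
    sprintf("seed: %d", result$config$seed)
  )
  writeLines(log, p("run_log.txt"))
  vapply(c("scores.tsv", "qc.tsv", "catalog_filtered.tsv",
           "classification.tsv", "peaks.bed", "summary.json", "config.yaml",
           "run_log.txt"), p, character(1))
}
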