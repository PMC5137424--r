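#' Highest mean over consecutive positions
#'
#' The element-level occupancy statistic: the maximum, over all contiguous
#' windows of `window` positions, of the window mean read density. With the
#' default `window = 6` this is the "mean read density for the 6 consecutive
#' positions with the highest read counts".
#'
#' @param segment Numeric vector of per-base densities.
#' @param window Window length in positions.
#' @return The maximal window mean (a scalar).
#' @export
#' @examples
#' top_window_mean(0:9)        # 6.5
#' top_window_mean(rep(5, 100))  # 5
top_window_mean <- function(segment, window = 6L) {
  n <- length(segment)
  window <- as.integer(window)
  if (n < window) {
    abort(sprintf("Segment length %d is shorter than window %d.", n, window))
  }
  cs <- c(0, cumsum(segment))
  max(cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
}

#' Depth-normalize a raw score
#'
#' @param raw Raw score (same units as the track values).
#' @param total_depth Total mapped-read mass of the library.
#' @param scale Normalization constant (default reads-per-million).
#' @return `raw * scale / total_depth`.
#' @export
normalize_score <- function(raw, total_depth, scale = 1e6) {
  if (any(total_depth <= 0)) {
    abort("total_depth must be > 0 to normalize scores.")
  }
  raw * scale / total_depth
}

#' Replicate concordance (Pearson correlation)
#'
#' QC statistic for a pair of replicate libraries: the Pearson correlation of
#' their per-element scores. The pipeline's gate passes when r exceeds the
#' configured threshold (default 0.90).
#'
#' @param scores_rep1,scores_rep2 Equal-length numeric vectors of per-element
#'   scores (length >= 3).
#' @return Pearson's r.
#' @export
replicate_concordance <- function(scores_rep1, scores_rep2) {
  if (length(scores_rep1) != length(scores_rep2) || length(scores_rep1) < 3) {
    abort("Replicate score vectors must have equal length >= 3.")
  }
  if (sd(scores_rep1) == 0 || sd(scores_rep2) == 0) {
    abort("Correlation undefined: a replicate score vector has zero variance.")
  }
  cor(scores_rep1, scores_rep2)
}

#' Relative difference between genotype means
#'
#' The signed, symmetric contrast `RD = 2 (m - c) / (m + c)` of mutant (`m`)
#' versus control (`c`) element scores. RD is antisymmetric under genotype
#' swap, bounded in (-2, 2) for positive scores, and reaches -2 at total
#' signal loss. Invariant under per-library depth rescaling applied upstream.
#'
#' @param mutant_mean,control_mean Non-negative mean scores (vectorized).
#' @return RD values.
#' @export
#' @examples
#' relative_difference(0.23, 1)  # approx -1.252
relative_difference <- function(mutant_mean, control_mean) {
  if (any(mutant_mean < 0) || any(control_mean < 0)) {
    abort("Scores must be non-negative.")
  }
  s <- mutant_mean + control_mean
  if (any(s == 0)) {
    abort("RD undefined where both genotype means are zero.")
  }
  2 * (mutant_mean - control_mean) / s
}

#' Classify dependence from RD
#'
#' Elements with `RD < rd_dependent` (default -1.0) show clear dependence of
#' PRC2 recruitment on PRC1; elements with `RD > rd_independent` (default
#' -0.5) are likely independent; the rest are intermediate.
#'
#' @param rd Finite RD values.
#' @param rd_dependent,rd_independent Class thresholds on RD.
#' @return Character vector over dependent/intermediate/independent.
#' @export
classify_pre <- function(rd, rd_dependent = -1.0, rd_independent = -0.5) {
  if (any(!is.finite(rd))) abort("RD values must be finite to classify.")
  dplyr::case_when(
    rd < rd_dependent ~ "dependent",
    rd > rd_independent ~ "independent",
    .default = "intermediate"
  )
}

#' Filter a candidate-element catalog
#'
#' Removes elements overlapping an exclusion interval (e.g. a deletion in
#' the mutant line) by >= 1 bp, and elements whose control signal falls in
#' the weak lower fraction of the catalog's signal dynamic range:
#' score `< min + weak_fraction * (max - min)` (`method = "range"`, default)
#' or below the `weak_fraction` quantile (`method = "quantile"`). Removed
#' rows are tagged, not dropped: the returned catalog carries a
#' `filtered_reason` column (`NA` = kept, else `"deletion_overlap"` or
#' `"weak_signal"`).
#'
#' @param catalog Tibble with chrom, start, end (0-based half-open).
#' @param control_scores Numeric vector of control-genotype scores aligned
#'   with `catalog` rows.
#' @param exclusion_intervals Optional tibble with chrom, start, end.
#' @param weak_fraction Fraction of the dynamic range (or quantile) below
#'   which elements are dropped.
#' @param method `"range"` or `"quantile"` interpretation of the weak-signal
#'   rule.
#' @return `catalog` plus columns control_score and filtered_reason.
#' @export
filter_pres <- function(catalog, control_scores, exclusion_intervals = NULL,
                        weak_fraction = 0.30,
                        method = c("range", "quantile")) {
  method <- match.arg(method)
  stopifnot(length(control_scores) == nrow(catalog))
  reason <- rep(NA_character_, nrow(catalog))
  if (!is.null(exclusion_intervals) && nrow(exclusion_intervals) > 0) {
    for (i in seq_len(nrow(exclusion_intervals))) {
      hit <- catalog$chrom == exclusion_intervals$chrom[i] &
        catalog$start < exclusion_intervals$end[i] &
        catalog$end > exclusion_intervals$start[i]
      reason[hit] <- "deletion_overlap"
    }
  }
  rng <- range(control_scores)
  if (method == "range") {
    if (diff(rng) == 0) {
      warn("Signal dynamic range is zero; weak-signal filter disabled.")
    } else {
      thr <- rng[1] + weak_fraction * diff(rng)
      weak <- control_scores < thr & is.na(reason)
      reason[weak] <- "weak_signal"
    }
  } else {
    thr <- quantile(control_scores, weak_fraction, names = FALSE)
    weak <- control_scores < thr & is.na(reason)
    reason[weak] <- "weak_signal"
  }
  out <- dplyr::mutate(catalog, control_score = control_scores,
                       filtered_reason = reason)
  if (all(!is.na(reason))) {
    abort("All elements were filtered out; review exclusion intervals and weak_fraction.")
  }
  out
}

#' Compare two RD (or score) distributions
#'
#' Two-sided Wilcoxon rank sum test plus both medians. Small tie-free samples
#' are tested exactly; larger or tied samples use the normal approximation
#' with tie correction and continuity correction (the standard behaviour of
#' [stats::wilcox.test()]).
#'
#' @param x,y Numeric vectors, length >= 3 each.
#' @return One-row tibble: median_x, median_y, statistic (W), p_value.
#' @export
compare_distributions <- function(x, y) {
  if (length(x) < 3 || length(y) < 3) {
    abort("Both vectors must have length >= 3.")
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  tibble(
    median_x = median(x), median_y = median(y),
    statistic = unname(ht$statistic), p_value = ht$p.value
  )
}

#' Score catalog elements in every library
#'
#' Applies [top_window_mean()] to each element interval in each library's
#' coverage track and depth-normalizes with [normalize_score()].
#'
#' @param catalog Tibble with chrom, start, end, name.
#' @param tracks Tibble of libraries with columns genotype, replicate, type
#'   and a `track` list-column of [coverage_track()]s (the `tracks` element
#'   of [simulate_tracks()] output has this shape).
#' @param window Window length for [top_window_mean()].
#' @param scale Normalization constant.
#' @return Long tibble: name, chrom, start, end, genotype, replicate, type,
#'   raw_score, norm_score.
#' @export
score_pres <- function(catalog, tracks, window = 6L, scale = 1e6) {
  stopifnot(all(c("genotype", "replicate", "type", "track") %in% names(tracks)))
  purrr::map_dfr(seq_len(nrow(tracks)), function(i) {
    tr <- tracks$track[[i]]
    rows <- catalog[catalog$chrom == tr$chrom, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    raw <- vapply(seq_len(nrow(rows)), function(j) {
      top_window_mean(track_segment(tr, rows$start[j], rows$end[j]), window)
    }, numeric(1))
    dplyr::mutate(
      dplyr::select(rows, "name", "chrom", "start", "end"),
      genotype = tracks$genotype[i], replicate = tracks$replicate[i],
      type = tracks$type[i], raw_score = raw,
      norm_score = normalize_score(raw, tr$total_depth, scale)
    )
  })
}

#' Classify elements by genotype contrast
#'
#' Averages replicate normalized scores per genotype, computes RD and the
#' mutant/control ratio from the ChIP libraries, classifies each element,
#' and (when input libraries are present) computes the matched input-track
#' RD as a processing-bias control.
#'
#' @param scores Long score tibble from [score_pres()].
#' @param control,mutant Genotype labels in `scores`.
#' @param rd_dependent,rd_independent Class thresholds (see [classify_pre()]).
#' @return A `pre_classification` tibble: one row per element with
#'   score_control, score_mutant, rd, ratio, dep_class and rd_input.
#' @export
classify_pres <- function(scores, control = "control", mutant = "mutant",
                          rd_dependent = -1.0, rd_independent = -0.5) {
  stopifnot(all(c(control, mutant) %in% scores$genotype))
  means <- scores |>
    dplyr::group_by(.data$name, .data$chrom, .data$start, .data$end,
                    .data$genotype, .data$type) |>
    dplyr::summarise(score = mean(.data$norm_score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = c("type", "genotype"),
                       values_from = "score")
  chip_c <- means[[paste0("chip_", control)]]
  chip_m <- means[[paste0("chip_", mutant)]]
  rd <- relative_difference(chip_m, chip_c)
  out <- means |>
    dplyr::transmute(
      .data$name, .data$chrom, .data$start, .data$end,
      score_control = chip_c, score_mutant = chip_m,
      rd = rd,
      ratio = ifelse(chip_c > 0, chip_m / chip_c, NA_real_),
      dep_class = classify_pre(rd, rd_dependent, rd_independent)
    )
  in_c <- means[[paste0("input_", control)]]
  in_m <- means[[paste0("input_", mutant)]]
  out$rd_input <- if (!is.null(in_c) && !is.null(in_m)) {
    relative_difference(in_m, in_c)
  } else {
    NA_real_
  }
  structure(out,
            class = c("pre_classification", class(tibble())),
            thresholds = c(dependent = rd_dependent,
                           independent = rd_independent))
}

#' Summarize a classified catalog
#'
#' @param records A [classify_pres()] result (or any tibble with a
#'   `dep_class` column).
#' @return One-row tibble: n_total, n per class, fraction per class, and
#'   `fraction_independent` (the fraction with RD above the independence
#'   threshold).
#' @export
summarize_classes <- function(records) {
  if (nrow(records) == 0) abort("No classified elements to summarize.")
  cls <- factor(records$dep_class,
                levels = c("dependent", "intermediate", "independent"))
  n <- as.integer(table(cls))
  tibble(
    n_total = nrow(records),
    n_dependent = n[1], n_intermediate = n[2], n_independent = n[3],
    fraction_dependent = n[1] / nrow(records),
    fraction_intermediate = n[2] / nrow(records),
    fraction_independent = n[3] / nrow(records)
  )
}
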