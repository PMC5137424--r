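#' Genomic background mean and standard deviation
#'
#' Mean and population standard deviation of per-base values over the whole
#' analyzed track, zero-coverage bases included. These define the
#' significance threshold for [significant_regions()].
#'
#' @param track A [coverage_track()].
#' @return One-row tibble with `mean` and `sd`.
#' @export
genomic_background <- function(track) {
  stopifnot(is_coverage_track(track))
  v <- track$values
  m <- mean(v)
  tibble(mean = m, sd = sqrt(mean((v - m)^2)))
}

#' Significantly immunoprecipitated regions
#'
#' Finds bases whose value exceeds `mean + k_sd * sd` and clusters
#' supra-threshold bases that are no more than `max_gap` bp apart into
#' regions (half-open intervals spanning the first to last qualifying base).
#'
#' @param track A [coverage_track()].
#' @param mean,sd Background statistics; computed with
#'   [genomic_background()] when `NULL`.
#' @param k_sd Threshold in background SD units (default 3).
#' @param max_gap Maximal distance between successive qualifying bases for
#'   them to share a region (default 500 bp).
#' @return Tibble of regions: chrom, start, end.
#' @export
significant_regions <- function(track, mean = NULL, sd = NULL, k_sd = 3,
                                max_gap = 500L) {
  stopifnot(is_coverage_track(track))
  if (is.null(mean) || is.null(sd)) {
    bg <- genomic_background(track)
    if (is.null(mean)) mean <- bg$mean
    if (is.null(sd)) sd <- bg$sd
  }
  if (sd < 0) abort("sd must be >= 0.")
  if (sd == 0 && any(track$values != track$values[1])) {
    warn("Background SD is zero on a nonuniform track; threshold falls back to the mean.")
  }
  thr <- mean + k_sd * sd
  cluster_coords(which(track$values > thr), max_gap, track$chrom,
                 track$origin)
}

# merge 1-based supra-threshold indices into half-open regions: successive
# qualifying coordinates <= max_gap apart share a region
cluster_coords <- function(idx, max_gap, chrom, origin) {
  if (length(idx) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  brk <- which(diff(idx) > max_gap)
  first <- idx[c(1L, brk + 1L)]
  last <- idx[c(brk, length(idx))]
  tibble(
    chrom = chrom,
    start = origin + first - 1L,
    end = origin + last  # half-open: last qualifying base included
  )
}

#' Summit of a significant region
#'
#' The summit is the center of the `window` consecutive coordinates with the
#' highest read counts within the region: the floor midpoint of the
#' maximal-sum window, leftmost window on ties. Regions shorter than
#' `window` get their midpoint, with a warning.
#'
#' @param track A [coverage_track()].
#' @param start,end Region bounds (vectors), 0-based half-open.
#' @param window Window length (default 6).
#' @return Tibble with `summit` (0-based coordinate) and `summit_score`
#'   (the maximal window mean), one row per region.
#' @export
peak_summit <- function(track, start, end, window = 6L) {
  stopifnot(is_coverage_track(track), length(start) == length(end))
  window <- as.integer(window)
  res <- lapply(seq_along(start), function(i) {
    seg <- track_segment(track, start[i], end[i])
    n <- length(seg)
    if (n < window) {
      warn(sprintf(
        "Region [%d, %d) is shorter than the %d-bp summit window; using its midpoint.",
        start[i], end[i], window))
      return(c((start[i] + end[i]) %/% 2, mean(seg)))
    }
    cs <- c(0, cumsum(seg))
    sums <- cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]
    off <- which.max(sums) - 1L  # leftmost maximal window, 0-based offset
    c(start[i] + off + window %/% 2L, max(sums) / window)
  })
  tibble(
    summit = vapply(res, `[`, numeric(1), 1),
    summit_score = vapply(res, `[`, numeric(1), 2)
  )
}

#' Select isolated peaks
#'
#' Keeps peaks whose nearest-neighbor summit on the same chromosome is
#' strictly more than `min_distance` bp away. A chromosome's only peak is
#' isolated by definition.
#'
#' @param peaks Tibble with chrom and summit columns, sorted by summit.
#' @param min_distance Isolation radius in bp (default 10 kb).
#' @return The isolated subset of `peaks`.
#' @export
isolated_peaks <- function(peaks, min_distance = 10000) {
  peaks[nearest_summit_distance(peaks) > min_distance, , drop = FALSE]
}

nearest_summit_distance <- function(peaks) {
  out <- rep(Inf, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    i <- which(peaks$chrom == ch)
    s <- sort(peaks$summit[i])
    if (length(s) > 1) {
      gaps <- diff(s)
      nn <- pmin(c(Inf, gaps), c(gaps, Inf))
      out[i[order(peaks$summit[i])]] <- nn
    }
  }
  out
}

#' Call peaks on coverage tracks
#'
#' Threshold-and-cluster peak calling: background estimation, significant
#' regions, per-region summits, and isolation flagging, in one step.
#'
#' Given a single track, regions are called on it directly. Given a list of
#' replicate tracks (`mode = "reproducible"`, the default), a coordinate
#' qualifies only when it exceeds its replicate's own 3-SD threshold in
#' *every* replicate experiment, and the jointly qualifying coordinates are
#' then clustered — single-replicate noise excursions (e.g. one-base
#' outliers above a 3-SD threshold) do not survive. `mode = "average"`
#' instead calls regions once on the replicate-averaged track. Summits are
#' always placed on the averaged track.
#'
#' @param tracks A [coverage_track()] or list of replicate tracks.
#' @inheritParams significant_regions
#' @inheritParams peak_summit
#' @param min_distance Isolation radius for [isolated_peaks()].
#' @param mode Replicate handling: `"reproducible"` (intersect per-replicate
#'   regions) or `"average"` (call on the averaged track).
#' @return Tibble of peaks: chrom, start, end, summit, summit_score,
#'   isolated.
#' @export
call_peaks <- function(tracks, k_sd = 3, max_gap = 500L, window = 6L,
                       min_distance = 10000,
                       mode = c("reproducible", "average")) {
  mode <- match.arg(mode)
  if (is_coverage_track(tracks)) tracks <- list(tracks)
  avg <- average_tracks(tracks)
  regions <- if (length(tracks) == 1L || mode == "average") {
    track <- if (mode == "average") avg else tracks[[1]]
    significant_regions(track, k_sd = k_sd, max_gap = max_gap)
  } else {
    qual <- lapply(tracks, function(tr) {
      bg <- genomic_background(tr)
      tr$values > bg$mean + k_sd * bg$sd
    })
    cluster_coords(which(Reduce(`&`, qual)), max_gap, avg$chrom, avg$origin)
  }
  if (nrow(regions) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  summit = numeric(), summit_score = numeric(),
                  isolated = logical()))
  }
  peaks <- dplyr::bind_cols(
    regions, peak_summit(avg, regions$start, regions$end, window)
  )
  peaks$isolated <- nearest_summit_distance(peaks) > min_distance
  peaks
}

#' Write peaks as BED6+ (narrowPeak-style summit offset)
#'
#' Columns: chrom, start, end, name, summit score, strand (`.`), 0-based
#' summit offset from `start`, isolation flag.
#'
#' @param peaks A [call_peaks()] result.
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  df <- tibble(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak%04d", seq_len(nrow(peaks))),
    score = peaks$summit_score, strand = ".",
    summit_offset = peaks$summit - peaks$start,
    isolated = as.integer(peaks$isolated)
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
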