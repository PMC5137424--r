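#' Cumulative occupancy profile around peak summits
#'
#' Divides the `2 * flank` bp window centered on each summit into
#' `bin`-bp bins, averages per-base density within each bin for every
#' replicate track, then averages bins across replicates. Peaks whose window
#' would leave the track are dropped with a warning.
#'
#' @param tracks A [coverage_track()] or list of replicate tracks (same
#'   chromosome).
#' @param peaks Tibble with chrom and summit columns (use isolated peaks for
#'   uncontaminated averages).
#' @param flank Half-window around each summit, bp (default 5000; 10 kb
#'   total).
#' @param bin Bin width, bp (default 100).
#' @return A `profile_matrix`: list with `matrix` (peaks x bins, replicate
#'   averaged), `bin_centers` (bp offsets from the summit), `peaks`, `bin`,
#'   `flank`, `n_replicates`.
#' @export
build_profile <- function(tracks, peaks, flank = 5000L, bin = 100L) {
  if (is_coverage_track(tracks)) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1, all(vapply(tracks, is_coverage_track,
                                            logical(1))))
  flank <- as.integer(flank)
  bin <- as.integer(bin)
  if ((2L * flank) %% bin != 0L) abort("2 * flank must be a multiple of bin.")
  tr1 <- tracks[[1]]
  peaks <- peaks[peaks$chrom == tr1$chrom, , drop = FALSE]
  lo <- tr1$origin
  hi <- tr1$origin + track_length(tr1)
  usable <- peaks$summit - flank >= lo & peaks$summit + flank <= hi
  if (any(!usable)) {
    warn(sprintf("Dropping %d peak(s) whose %d bp window leaves the track.",
                 sum(!usable), 2L * flank))
  }
  peaks <- peaks[usable, , drop = FALSE]
  if (nrow(peaks) == 0) abort("No usable peaks for profile construction.")
  n_bins <- (2L * flank) %/% bin
  layers <- lapply(tracks, function(tr) {
    t(vapply(peaks$summit, function(s) {
      w <- track_segment(tr, s - flank, s + flank)
      colMeans(matrix(w, nrow = bin))
    }, numeric(n_bins)))
  })
  structure(
    list(
      matrix = Reduce(`+`, layers) / length(layers),
      bin_centers = -flank + (seq_len(n_bins) - 0.5) * bin,
      peaks = peaks, bin = bin, flank = flank,
      n_replicates = length(tracks)
    ),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "<profile_matrix> %d peaks x %d bins (%d bp bins, +/- %d bp, %d replicate(s))\n",
    nrow(x$matrix), ncol(x$matrix), x$bin, x$flank, x$n_replicates))
  invisible(x)
}

#' @export
as_tibble.profile_matrix <- function(x, ...) {
  tidyr::expand_grid(peak = seq_len(nrow(x$matrix)),
                     offset = x$bin_centers) |>
    dplyr::mutate(density = as.vector(t(x$matrix)))
}

#' Mean profile across peaks
#'
#' @param profile A [build_profile()] result.
#' @return Tibble with `offset` (bp from summit) and `density` (mean over
#'   peaks).
#' @export
mean_profile <- function(profile) {
  stopifnot(inherits(profile, "profile_matrix"))
  tibble(offset = profile$bin_centers, density = colMeans(profile$matrix))
}

#' Locally weighted polynomial (loess) fit
#'
#' Tricube-weighted local polynomial regression over each point's
#' span-fraction nearest neighbors, evaluated exactly (no interpolation
#' surface). Deterministic.
#'
#' @param x,y Numeric vectors of equal length.
#' @param span Fraction of points in each local window (0 < span <= 1).
#' @param degree Local polynomial degree (default 2).
#' @return A `fitted_curve` tibble with columns x, y (the fit at the input
#'   x), carrying the model for later evaluation via `predict()`.
#' @export
loess_fit <- function(x, y, span, degree = 2L) {
  stopifnot(length(x) == length(y))
  if (span <= 0 || span > 1) abort("span must be in (0, 1].")
  n <- length(x)
  if (floor(n * span) < degree + 2) {
    abort(sprintf(
      "span %.3g gives local windows of %d point(s); need >= %d for degree %d.",
      span, floor(n * span), degree + 2, degree))
  }
  model <- stats::loess(y ~ x, data = data.frame(x = x, y = y), span = span,
                        degree = degree, family = "gaussian",
                        surface = "direct")
  new_fitted_curve(x, unname(predict(model, data.frame(x = x))),
                   span = span, degree = degree, model = model)
}

new_fitted_curve <- function(x, y, span, degree, model = NULL,
                             extra = list()) {
  structure(
    tibble(x = x, y = y),
    class = c("fitted_curve", class(tibble())),
    span = span, degree = degree, model = model, extra = extra
  )
}

#' Evaluate a fitted curve at new offsets
#'
#' @param object A `fitted_curve` from [loess_fit()] or
#'   [profile_difference()].
#' @param newdata Numeric vector of x positions (within the fitted range).
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.fitted_curve <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$y)
  model <- attr(object, "model")
  if (is.null(model)) abort("This fitted_curve carries no model to evaluate.")
  unname(predict(model, data.frame(x = as.numeric(newdata))))
}

#' Difference between two genotype profile curves
#'
#' Evaluates both fitted curves at `n_points` evenly spaced offsets over
#' their (common) x-range, subtracts mutant minus control, and loess-smooths
#' the differences with `smooth_span`. With `scale = "summit"` (default)
#' each curve first has its `background` subtracted and is divided by its
#' own summit (offset 0) value, so the difference reflects redistribution of
#' signal rather than overall amplitude; `scale = "none"` differences the
#' curves as given.
#'
#' @param curve_mut,curve_ctrl `fitted_curve`s over the same x-range.
#' @param n_points Number of evaluation points (default 50).
#' @param smooth_span Loess span for the difference curve (default 0.2).
#' @param scale `"summit"` or `"none"`.
#' @param background_mut,background_ctrl Flat background levels subtracted
#'   before summit scaling (see [background_level()]); used only when
#'   `scale = "summit"`.
#' @param summit_mut,summit_ctrl Summit densities used for scaling; default
#'   is the fitted value at offset 0, but for sharply peaked profiles pass
#'   the raw central-bin density (see [summit_density()]), which a
#'   wide-span fit underestimates.
#' @param degree Loess degree for the smoothing of differences.
#' @return A `fitted_curve` of the smoothed difference at the evaluation
#'   offsets; the raw (pre-smoothing) differences are kept in
#'   `attr(, "extra")$points`.
#' @export
profile_difference <- function(curve_mut, curve_ctrl, n_points = 50L,
                               smooth_span = 0.2,
                               scale = c("summit", "none"),
                               background_mut = 0, background_ctrl = 0,
                               summit_mut = NULL, summit_ctrl = NULL,
                               degree = 2L) {
  scale <- match.arg(scale)
  rm_ <- range(curve_mut$x)
  rc_ <- range(curve_ctrl$x)
  if (any(abs(rm_ - rc_) > 1e-8)) {
    abort("Curves span different x-ranges; refit them on a common window.")
  }
  xs <- seq(rm_[1], rm_[2], length.out = n_points)
  ym <- predict(curve_mut, xs)
  yc <- predict(curve_ctrl, xs)
  if (scale == "summit") {
    sm <- (summit_mut %||% predict(curve_mut, 0)) - background_mut
    sc <- (summit_ctrl %||% predict(curve_ctrl, 0)) - background_ctrl
    if (sm <= 0 || sc <= 0) {
      abort("Summit value must exceed the background to summit-scale a curve.")
    }
    ym <- (ym - background_mut) / sm
    yc <- (yc - background_ctrl) / sc
  }
  d <- ym - yc
  sm_fit <- loess_fit(xs, d, span = smooth_span, degree = degree)
  new_fitted_curve(xs, sm_fit$y, span = smooth_span, degree = degree,
                   model = attr(sm_fit, "model"),
                   extra = list(points = tibble(x = xs, difference = d),
                                scale = scale))
}

#' Summit density of a profile
#'
#' Mean density of the central bins (those whose centers lie nearest the
#' summit, offset 0) averaged across peaks — the profile's own estimate of
#' summit occupancy, unaffected by smoothing span.
#'
#' @param profile A [build_profile()] result.
#' @return Scalar density.
#' @export
summit_density <- function(profile) {
  stopifnot(inherits(profile, "profile_matrix"))
  ctr <- which(abs(profile$bin_centers) == min(abs(profile$bin_centers)))
  mean(profile$matrix[, ctr])
}

#' Summit versus distal magnitude of a difference curve
#'
#' Compares the absolute smoothed difference at the summit (offset nearest
#' 0) with its mean over distal offsets, the diagnostic for preferential
#' signal loss at a distance from binding-site summits.
#'
#' @param curve A [profile_difference()] result.
#' @param distal Absolute offset window, bp, counted as distal (default
#'   2-5 kb).
#' @return One-row tibble: summit_abs, distal_abs, distal_to_summit_ratio.
#' @export
difference_summary <- function(curve, distal = c(2000, 5000)) {
  at0 <- abs(curve$y[which.min(abs(curve$x))])
  far <- abs(curve$x) >= distal[1] & abs(curve$x) <= distal[2]
  if (!any(far)) abort("No evaluation points in the distal window.")
  tibble(
    summit_abs = at0,
    distal_abs = mean(abs(curve$y[far])),
    distal_to_summit_ratio = mean(abs(curve$y[far])) / at0
  )
}

#' Average background density from random genomic bins
#'
#' Mean of per-bin average read counts over `n_bins` randomly placed
#' `bin`-bp bins that do not overlap any excluded region (e.g. called
#' peaks). Bins may overlap each other unless `replace = FALSE`.
#'
#' @param track A [coverage_track()].
#' @param excluded Optional tibble with chrom, start, end of regions bins
#'   must avoid.
#' @param n_bins Number of random bins (default 999).
#' @param bin Bin width, bp (default 100).
#' @param seed Optional integer seed for reproducible placement.
#' @param replace Sample bin start positions with replacement (default TRUE).
#' @return Scalar mean background density.
#' @export
background_level <- function(track, excluded = NULL, n_bins = 999L,
                             bin = 100L, seed = NULL, replace = TRUE) {
  stopifnot(is_coverage_track(track))
  L <- track_length(track)
  bin <- as.integer(bin)
  if (bin > L) abort("Bin width exceeds track length.")
  bad <- logical(L)
  if (!is.null(excluded) && nrow(excluded) > 0) {
    ex <- excluded[excluded$chrom == track$chrom, , drop = FALSE]
    for (i in seq_len(nrow(ex))) {
      s <- max(ex$start[i], track$origin)
      e <- min(ex$end[i], track$origin + L)
      if (e > s) bad[(s - track$origin + 1L):(e - track$origin)] <- TRUE
    }
  }
  csb <- c(0, cumsum(bad))
  starts <- 0:(L - bin)  # candidate offsets within the track
  ok <- (csb[starts + bin + 1L] - csb[starts + 1L]) == 0
  allowed <- starts[ok]
  if (length(allowed) == 0 || (!replace && length(allowed) < n_bins)) {
    abort(sprintf(
      "Insufficient non-excluded territory: %d allowed bin position(s) for %d bins.",
      length(allowed), n_bins))
  }
  pick <- function() sample(allowed, n_bins, replace = replace)
  sel <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  cs <- c(0, cumsum(track$values))
  mean((cs[sel + bin + 1L] - cs[sel + 1L]) / bin)
}

#' Compare genotype occupancy profiles around shared peaks
#'
#' End-to-end distal-loss analysis: builds replicate-averaged profiles for
#' both genotypes around the same (isolated) peaks, loess-fits the mean
#' profiles, estimates each genotype's randomized genomic background
#' outside the peak regions, and differences the curves.
#'
#' @param tracks_mut,tracks_ctrl Lists of replicate [coverage_track()]s.
#' @param peaks Peak tibble (isolated peaks recommended) anchoring the
#'   profiles.
#' @param excluded Regions background bins must avoid (default `peaks`;
#'   pass the full bound-region set when profiling only isolated peaks).
#' @param flank,bin Profile window and bin width.
#' @param span Loess span for the genotype curves (default 0.1).
#' @param n_points,smooth_span,scale Passed to [profile_difference()].
#' @param n_bins Random bins for [background_level()].
#' @param seed Seed for background bin placement.
#' @return List: profiles (per genotype), curves (per genotype
#'   `fitted_curve`), background (tibble), difference (`fitted_curve`),
#'   summary ([difference_summary()]).
#' @export
compare_profiles <- function(tracks_mut, tracks_ctrl, peaks,
                             excluded = peaks, flank = 5000L,
                             bin = 100L, span = 0.1, n_points = 50L,
                             smooth_span = 0.2, scale = "summit",
                             n_bins = 999L, seed = NULL) {
  pm_mut <- build_profile(tracks_mut, peaks, flank = flank, bin = bin)
  pm_ctrl <- build_profile(tracks_ctrl, peaks, flank = flank, bin = bin)
  mp_mut <- mean_profile(pm_mut)
  mp_ctrl <- mean_profile(pm_ctrl)
  curve_mut <- loess_fit(mp_mut$offset, mp_mut$density, span = span)
  curve_ctrl <- loess_fit(mp_ctrl$offset, mp_ctrl$density, span = span)
  excl <- if (!is.null(excluded) &&
              all(c("start", "end") %in% names(excluded))) excluded else NULL
  if (is_coverage_track(tracks_mut)) tracks_mut <- list(tracks_mut)
  if (is_coverage_track(tracks_ctrl)) tracks_ctrl <- list(tracks_ctrl)
  bg_mut <- background_level(average_tracks(tracks_mut), excl,
                             n_bins = n_bins, bin = bin, seed = seed)
  bg_ctrl <- background_level(average_tracks(tracks_ctrl), excl,
                              n_bins = n_bins, bin = bin,
                              seed = if (is.null(seed)) NULL else seed + 1L)
  diff_curve <- profile_difference(
    curve_mut, curve_ctrl, n_points = n_points, smooth_span = smooth_span,
    scale = scale, background_mut = bg_mut, background_ctrl = bg_ctrl,
    summit_mut = summit_density(pm_mut), summit_ctrl = summit_density(pm_ctrl)
  )
  list(
    profiles = list(mutant = pm_mut, control = pm_ctrl),
    curves = list(mutant = curve_mut, control = curve_ctrl),
    background = tibble(genotype = c("mutant", "control"),
                        level = c(bg_mut, bg_ctrl)),
    difference = diff_curve,
    summary = difference_summary(diff_curve)
  )
}
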