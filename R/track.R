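#' Per-base coverage track
#'
#' A `coverage_track` holds dense per-base read density for one chromosome.
#' All genomic coordinates in the package are 0-based, half-open (BED
#' convention): base `g` of chromosome `chrom` is stored at
#' `values[g - origin + 1]`.
#'
#' @param values Numeric vector of non-negative per-base densities.
#' @param chrom Chromosome name.
#' @param origin 0-based genomic coordinate of the first value.
#' @param total_depth Total mapped-read mass the track derives from; used for
#'   depth normalization. Defaults to `sum(values)`.
#'
#' @return An object of class `coverage_track`.
#' @export
#' @examples
#' tr <- coverage_track(c(0, 0, 3, 3, 1))
#' track_length(tr)
coverage_track <- function(values, chrom = "chrS", origin = 0L,
                           total_depth = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) {
    abort("`values` must have length > 0 to form a coverage track.")
  }
  if (anyNA(values) || any(values < 0)) {
    abort("Coverage values must be non-negative and non-missing.")
  }
  structure(
    list(
      chrom = as.character(chrom),
      values = values,
      origin = as.integer(origin),
      total_depth = if (is.null(total_depth)) sum(values) else
        as.numeric(total_depth)
    ),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %s:%d-%d (%s bp), total depth %.4g\n",
    x$chrom, x$origin, x$origin + length(x$values),
    format(length(x$values), big.mark = ","), x$total_depth
  ))
  invisible(x)
}

#' @rdname coverage_track
#' @param x,track A `coverage_track`.
#' @export
track_length <- function(track) length(track$values)

#' @rdname coverage_track
#' @export
is_coverage_track <- function(x) inherits(x, "coverage_track")

#' @export
as_tibble.coverage_track <- function(x, ...) {
  r <- rle(x$values)
  ends <- x$origin + cumsum(r$lengths)
  tibble(
    chrom = x$chrom,
    start = ends - r$lengths,
    end = ends,
    value = r$values
  )
}

#' Extract per-base values for a genomic interval
#'
#' @param track A [coverage_track()].
#' @param start,end Interval in 0-based half-open genomic coordinates.
#' @return Numeric vector of length `end - start`.
#' @export
track_segment <- function(track, start, end) {
  stopifnot(is_coverage_track(track))
  if (start < track$origin || end > track$origin + track_length(track) ||
      start >= end) {
    abort(sprintf(
      "Interval [%d, %d) outside track %s:[%d, %d).",
      start, end, track$chrom, track$origin,
      track$origin + track_length(track)
    ))
  }
  track$values[(start - track$origin + 1L):(end - track$origin)]
}

#' Depth-normalize a coverage track
#'
#' Rescales per-base values to reads-per-`scale` of total depth, so tracks
#' from libraries sequenced to different depths are comparable.
#'
#' @inheritParams track_segment
#' @param scale Normalization constant (default 1e6, reads-per-million).
#' @return A `coverage_track` with rescaled values and `total_depth = scale`.
#' @export
normalize_track <- function(track, scale = 1e6) {
  stopifnot(is_coverage_track(track))
  if (track$total_depth <= 0) {
    abort("Cannot depth-normalize a track with total_depth <= 0.")
  }
  coverage_track(
    track$values * scale / track$total_depth,
    chrom = track$chrom, origin = track$origin, total_depth = scale
  )
}

#' Average several coverage tracks base-by-base
#'
#' Tracks must share chromosome, origin and length. Used to pool replicate
#' libraries before peak calling.
#'
#' @param tracks List of [coverage_track()]s.
#' @return A `coverage_track` of elementwise means; `total_depth` is the mean
#'   of the input depths.
#' @export
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L, all(vapply(tracks, is_coverage_track,
                                             logical(1))))
  chroms <- vapply(tracks, function(t) t$chrom, character(1))
  lens <- vapply(tracks, track_length, integer(1))
  origins <- vapply(tracks, function(t) t$origin, integer(1))
  if (length(unique(chroms)) != 1L || length(unique(lens)) != 1L ||
      length(unique(origins)) != 1L) {
    abort("All tracks must share chromosome, origin and length to average.")
  }
  vals <- Reduce(`+`, lapply(tracks, function(t) t$values)) / length(tracks)
  coverage_track(
    vals, chrom = chroms[1], origin = origins[1],
    total_depth = mean(vapply(tracks, function(t) t$total_depth, numeric(1)))
  )
}
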