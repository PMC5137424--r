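#' Read a bedGraph file into per-base coverage tracks
#'
#' Expands the run-length bedGraph representation (0-based, half-open) into
#' one dense [coverage_track()] per chromosome. Bases not covered by any
#' record are 0. Track/browser header lines and `#` comments are skipped.
#'
#' @param path Path to a bedGraph file.
#' @param total_depth Optional named numeric vector of per-chromosome total
#'   depths; defaults to the sum of expanded values.
#' @return Named list of `coverage_track`, one per chromosome (empty list,
#'   with a warning, for an empty file).
#' @export
read_bedgraph <- function(path, total_depth = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warn(sprintf("bedGraph file '%s' contains no records.", path))
    return(list())
  }
  df <- readr::read_tsv(
    I(paste0(lines, collapse = "\n")),
    col_names = c("chrom", "start", "end", "value"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), value = readr::col_double()
    ),
    progress = FALSE
  )
  if (any(df$start < 0) || any(df$end <= df$start)) {
    abort(sprintf("Malformed intervals in '%s': need 0 <= start < end.", path))
  }
  if (any(df$value < 0)) {
    abort(sprintf("Negative coverage values in '%s'.", path))
  }
  out <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    len <- max(d$end)
    vals <- rep(NA_real_, len)
    for (i in seq_len(nrow(d))) {
      idx <- (d$start[i] + 1L):d$end[i]
      prev <- vals[idx]
      clash <- !is.na(prev) & prev != d$value[i]
      if (any(clash)) {
        abort(sprintf(
          "Overlapping bedGraph records with conflicting values on %s near %d.",
          d$chrom[1], d$start[i]
        ))
      }
      vals[idx] <- d$value[i]
    }
    vals[is.na(vals)] <- 0
    depth <- if (!is.null(total_depth)) total_depth[[d$chrom[1]]] else NULL
    coverage_track(vals, chrom = d$chrom[1], origin = 0L, total_depth = depth)
  })
  inform(sprintf("Read %d bedGraph records (%d chromosome(s)) from '%s'.",
                 nrow(df), length(out), path))
  out
}

#' Write coverage tracks as bedGraph
#'
#' Writes one line per constant-coverage run (zero runs included, so
#' `read_bedgraph(write_bedgraph(x))` is the identity on the run-length
#' representation).
#'
#' @param tracks A `coverage_track` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path) {
  if (is_coverage_track(tracks)) tracks <- list(tracks)
  df <- dplyr::bind_rows(lapply(tracks, as_tibble))
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  inform(sprintf("Wrote %d bedGraph records to '%s'.", nrow(df), path))
  invisible(path)
}

#' Read / write BED6 interval files
#'
#' Intervals are 0-based half-open. Missing name/score/strand columns are
#' filled with `"."`, `0`, `"."`.
#'
#' @param path File path.
#' @return `read_bed()`: tibble with columns chrom, start, end, name, score,
#'   strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warn(sprintf("BED file '%s' contains no records.", path))
    return(tibble(chrom = character(), start = double(), end = double(),
                  name = character(), score = double(), strand = character()))
  }
  df <- readr::read_tsv(I(paste0(lines, collapse = "\n")), col_names = FALSE,
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (any(df$start < 0) || any(df$end <= df$start)) {
    abort(sprintf("Malformed intervals in '%s': need 0 <= start < end.", path))
  }
  df$name <- if (ncol(df) >= 4) as.character(df[[4]]) else "."
  df$score <- if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else 0
  df$strand <- if (ncol(df) >= 6) as.character(df[[6]]) else "."
  bad <- !df$strand %in% c("+", "-", ".")
  if (any(bad)) {
    abort(sprintf("Invalid strand value(s) in '%s': %s.",
                  path, paste(unique(df$strand[bad]), collapse = ", ")))
  }
  inform(sprintf("Read %d BED records from '%s'.", nrow(df), path))
  dplyr::select(df, "chrom", "start", "end", "name", "score", "strand")
}

#' @rdname read_bed
#' @param intervals Tibble with at least chrom, start, end.
#' @export
write_bed <- function(intervals, path) {
  col_or <- function(nm, default) {
    if (nm %in% names(intervals)) intervals[[nm]] else default
  }
  df <- tibble(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    name = col_or("name", "."),
    score = col_or("score", 0),
    strand = col_or("strand", ".")
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  inform(sprintf("Wrote %d BED records to '%s'.", nrow(df), path))
  invisible(path)
}
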