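#' Simulation configuration
#'
#' Defines the generative model for synthetic ChIP coverage tracks: a flat
#' Poisson (or negative binomial) background over one chromosome, plus
#' localized enrichment at regularly spaced candidate elements. Each element
#' has a 200 bp plateau centered in its 1 kb interval flanked by
#' exponentially decaying tails, emulating the punctate summit plus extended
#' low-level "tail" crosslinking seen around Polycomb binding sites. In the
#' mutant genotype the expected summit coverage is the control's times a
#' class-specific attenuation; tail attenuation may differ from summit
#' attenuation to emulate preferential distal signal loss.
#'
#' Expected coverage at base `x` of a ChIP library is
#'
#' `depth_factor * background_rate * (1 + (A a_p - 1) p(x) + (A a_t - 1) tau u(x))`
#'
#' where `A` is `summit_amplitude_control` and `a_p`/`a_t` the
#' (class-specific) summit/tail attenuations (both 1 in the control). The
#' shape has two components at distance `d` from the plateau edge:
#'
#' * the *core*: plateau indicator `p`, a sharp-edged top that makes the
#'   top-window summit statistic well defined; it attenuates with the
#'   summit attenuation because it reports core binding;
#' * the *tail*: looping-derived signal
#'   `u(d) = (1 - 2^(-d / tail_rise)) * 2^(-d / tail_halflife)`, a low-level
#'   component (relative amplitude `tau = tail_fraction`) that rises over
#'   `tail_rise` bp, peaks a few kb out, and decays with `tail_halflife`,
#'   truncated at `tail_extent`; it attenuates with the tail attenuation
#'   (looping contacts immediately adjacent to the core are subsumed in the
#'   core's own fragments, hence the onset ramp).
#'
#' Expected summit coverage is `depth * background * A` in the control and
#' `control x a_p` in the mutant, and when `a_t = a_p` the mutant enrichment
#' profile is exactly proportional to the control's (uniform loss). Input
#' libraries are background-only.
#'
#' @param chrom_length Chromosome length, bp.
#' @param n_pres Number of simulated elements.
#' @param pre_width Element width, bp.
#' @param class_fractions Named proportions over
#'   dependent/intermediate/independent; must sum to 1.
#' @param background_rate Expected background reads per bp.
#' @param summit_amplitude_control Mean fold enrichment of control summits
#'   over background.
#' @param amplitude_sigma Log-normal sigma of per-element amplitude
#'   heterogeneity (mean-preserving; element `i` gets
#'   `A_i = A exp(sigma Z_i - sigma^2/2)`). Real element catalogs span a
#'   wide signal range; this is what gives replicate score correlations
#'   their meaning and the weak-signal filter a dynamic range to act on.
#'   Set 0 for identical amplitudes.
#' @param attenuation_by_class Named per-class fold of summit signal retained
#'   in the mutant.
#' @param tail_attenuation_by_class Per-class fold of tail signal retained in
#'   the mutant; `NULL` means same as `attenuation_by_class` (uniform loss).
#' @param tail_fraction Tail amplitude relative to summit enrichment
#'   (default 0.1: tails are low-level signal, and enriched mass stays a
#'   modest fraction of the library so depth normalization behaves as on
#'   real data).
#' @param tail_rise Half-life, bp, of the tail onset ramp (looping contacts
#'   build up away from the core).
#' @param tail_halflife Exponential decay half-life of flank tails, bp.
#' @param tail_extent Maximal tail reach beyond the plateau, bp.
#' @param plateau_width Summit plateau width, bp.
#' @param n_replicates Replicate libraries per genotype.
#' @param depth_factors Per-library depth scalars, recycled over the
#'   genotype x replicate x type grid (control/mutant, replicates, chip/input
#'   in that order).
#' @param fragment_length Footprint, bp, of one sequenced fragment. The
#'   default 1 draws independent per-base counts (background is then
#'   exactly `noise` reads/bp per base); values > 1 emulate extended-read
#'   pileup, where coverage is a running count of fragment anchors and
#'   per-base values are autocorrelated over the footprint. Must not exceed
#'   `plateau_width` (the plateau top must stay flat).
#' @param noise `"poisson"` or `"negative_binomial"`.
#' @param dispersion Negative binomial dispersion (var = mu + dispersion*mu^2).
#' @param min_spacing Minimal distance between element centers, bp.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(chrom_length = 2e6,
                              n_pres = 60,
                              pre_width = 1000,
                              class_fractions = c(dependent = 1 / 3,
                                                  intermediate = 1 / 3,
                                                  independent = 1 / 3),
                              background_rate = 0.5,
                              summit_amplitude_control = 20,
                              amplitude_sigma = 0.4,
                              attenuation_by_class = c(dependent = 0.1,
                                                       intermediate = 0.4,
                                                       independent = 0.9),
                              tail_attenuation_by_class = NULL,
                              tail_fraction = 0.1,
                              tail_rise = 1000,
                              tail_halflife = 2000,
                              tail_extent = 5000,
                              plateau_width = 200,
                              n_replicates = 2,
                              depth_factors = 1,
                              fragment_length = 1,
                              noise = c("poisson", "negative_binomial"),
                              dispersion = 0.2,
                              min_spacing = 25000,
                              seed = 1L) {
  noise <- match.arg(noise)
  classes <- c("dependent", "intermediate", "independent")
  stopifnot(
    chrom_length > 0, n_pres > 0, pre_width > 0,
    background_rate >= 0, summit_amplitude_control >= 0,
    amplitude_sigma >= 0, tail_fraction >= 0, tail_rise > 0, tail_halflife > 0,
    tail_extent >= 0, plateau_width > 0,
    n_replicates >= 1, all(depth_factors > 0), dispersion > 0,
    fragment_length >= 1, fragment_length <= plateau_width
  )
  if (!setequal(names(class_fractions), classes)) {
    abort("class_fractions must be named dependent/intermediate/independent.")
  }
  class_fractions <- class_fractions[classes]
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    abort("class_fractions must sum to 1.")
  }
  if (!setequal(names(attenuation_by_class), classes)) {
    abort("attenuation_by_class must be named dependent/intermediate/independent.")
  }
  attenuation_by_class <- attenuation_by_class[classes]
  if (any(attenuation_by_class < 0)) abort("Attenuations must be >= 0.")
  if (is.null(tail_attenuation_by_class)) {
    tail_attenuation_by_class <- attenuation_by_class
  } else {
    if (!setequal(names(tail_attenuation_by_class), classes)) {
      abort("tail_attenuation_by_class must be named dependent/intermediate/independent.")
    }
    tail_attenuation_by_class <- tail_attenuation_by_class[classes]
  }
  structure(
    list(
      chrom_length = as.integer(chrom_length), n_pres = as.integer(n_pres),
      pre_width = as.integer(pre_width), class_fractions = class_fractions,
      background_rate = background_rate,
      summit_amplitude_control = summit_amplitude_control,
      amplitude_sigma = amplitude_sigma,
      attenuation_by_class = attenuation_by_class,
      tail_attenuation_by_class = tail_attenuation_by_class,
      tail_fraction = tail_fraction, tail_rise = tail_rise,
      tail_halflife = tail_halflife, tail_extent = as.integer(tail_extent),
      plateau_width = as.integer(plateau_width),
      n_replicates = as.integer(n_replicates),
      depth_factors = depth_factors,
      fragment_length = as.integer(fragment_length),
      noise = noise, dispersion = dispersion,
      min_spacing = as.integer(min_spacing), seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# deterministic class counts: floor, remainder to largest fractional parts
class_counts <- function(n, fractions) {
  raw <- n * fractions
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  as.integer(cnt)
}

#' Simulate ChIP and Input coverage tracks with known ground truth
#'
#' Draws per-base counts for every genotype x replicate x type (chip/input)
#' library under the generative model of [simulation_config()]. Elements are
#' placed on an even grid with seeded jitter so that consecutive centers stay
#' at least `min_spacing` apart and at least 10 kb from chromosome ends.
#' Identical seeds give bit-identical output.
#'
#' @param config A [simulation_config()].
#' @return List with elements:
#'   * `tracks`: tibble with columns genotype, replicate, type, depth_factor
#'     and a `track` list-column of [coverage_track()]s;
#'   * `truth`: tibble of per-element ground truth (interval, class,
#'     control/mutant summit amplitudes, tail parameters);
#'   * `catalog`: BED-style tibble of the candidate element intervals;
#'   * `config`: the configuration used.
#' @export
simulate_tracks <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  edge <- 10000L
  step <- (config$chrom_length - 2 * edge) / config$n_pres
  if (step < config$min_spacing) {
    abort(sprintf(paste0(
      "Cannot place %d elements >= %d bp apart on a %d bp chromosome ",
      "(available step %.0f bp); reduce n_pres or min_spacing, or enlarge ",
      "chrom_length."),
      config$n_pres, config$min_spacing, config$chrom_length, step))
  }
  withr::with_seed(config$seed, {
    jitter_max <- (step - config$min_spacing) / 2
    centers <- round(edge + (seq_len(config$n_pres) - 0.5) * step +
                       runif(config$n_pres, -jitter_max, jitter_max))
    classes <- c("dependent", "intermediate", "independent")
    cnt <- class_counts(config$n_pres, config$class_fractions)
    labels <- sample(rep(classes, cnt))
    # mean-preserving log-normal amplitude heterogeneity across elements
    A0 <- config$summit_amplitude_control
    A <- A0 * exp(config$amplitude_sigma * stats::rnorm(config$n_pres) -
                    config$amplitude_sigma^2 / 2)

    half_pre <- config$pre_width %/% 2L
    half_plateau <- config$plateau_width %/% 2L
    L <- config$chrom_length
    # distance-ramped looping-tail weight at distances 1..tail_extent from
    # the plateau edge (follows tail attenuation)
    d <- seq_len(config$tail_extent)
    tail_w <- config$tail_fraction * (1 - 2^(-d / config$tail_rise)) *
      2^(-d / config$tail_halflife)

    # per-base enrichment, per-element coefficients: coef_p on the plateau,
    # coef_t on the tail component
    build_enrichment <- function(coef_p, coef_t) {
      enr <- numeric(L)
      for (i in seq_len(config$n_pres)) {
        p0 <- centers[i] - half_plateau
        p1 <- centers[i] + half_plateau  # [p0, p1) plateau, 0-based
        enr[(p0 + 1L):p1] <- enr[(p0 + 1L):p1] + coef_p[i]
        if (config$tail_extent > 0) {
          flank_w <- coef_t[i] * tail_w
          right <- (p1 + 1L):min(p1 + config$tail_extent, L)
          enr[right] <- enr[right] + flank_w[seq_along(right)]
          left <- max(1L, p0 - config$tail_extent + 1L):p0
          enr[left] <- enr[left] + rev(flank_w[seq_along(left)])
        }
      }
      enr
    }
    a_p <- unname(config$attenuation_by_class[labels])
    a_t <- unname(config$tail_attenuation_by_class[labels])
    enr_control <- build_enrichment(A - 1, A - 1)
    enr_mutant <- build_enrichment(A * a_p - 1, A * a_t - 1)

    grid <- tidyr::expand_grid(
      genotype = c("control", "mutant"),
      replicate = seq_len(config$n_replicates),
      type = c("chip", "input")
    )
    grid$depth_factor <- rep_len(config$depth_factors, nrow(grid))
    flen <- config$fragment_length
    h1 <- flen %/% 2L
    lo <- pmax(seq_len(L) - h1 - 1L, 0L)
    hi <- pmin(seq_len(L) + (flen - h1 - 1L), L)
    draw <- function(mu) {
      # fragment-pileup noise: per-base fragment anchors at rate mu/flen,
      # coverage = anchors within the centered fragment footprint, so
      # values are autocorrelated over flen as in extended-read density
      # tracks (single-base spikes cannot occur)
      anchors <- if (config$noise == "poisson") rpois(L, mu / flen) else
        rnbinom(L, mu = mu / flen, size = 1 / config$dispersion)
      cs <- c(0, cumsum(anchors))
      cs[hi + 1L] - cs[lo + 1L]
    }
    grid$track <- purrr::pmap(grid, function(genotype, replicate, type,
                                             depth_factor) {
      enr <- if (type == "input") 0 else
        if (genotype == "control") enr_control else enr_mutant
      mu <- depth_factor * config$background_rate * (1 + enr)
      coverage_track(draw(mu), chrom = "chrS", origin = 0L)
    })

    truth <- tibble(
      name = sprintf("PRE%03d", seq_len(config$n_pres)),
      chrom = "chrS",
      start = centers - half_pre,
      end = centers - half_pre + config$pre_width,
      summit = centers,
      class = labels,
      control_amplitude = A,
      mutant_summit_amplitude = A * a_p,
      mutant_tail_amplitude = A * a_t,
      tail_fraction = config$tail_fraction,
      tail_rise = config$tail_rise,
      tail_halflife = config$tail_halflife,
      tail_extent = config$tail_extent
    )
  })
  catalog <- dplyr::select(truth, "chrom", "start", "end", "name")
  structure(list(tracks = grid, truth = truth, catalog = catalog,
                 config = config),
            class = "pre_simulation")
}

#' @export
print.pre_simulation <- function(x, ...) {
  cat(sprintf(
    "<pre_simulation> %d elements on %s bp, %d libraries (seed %d)\n",
    nrow(x$truth), format(x$config$chrom_length, big.mark = ","),
    nrow(x$tracks), x$config$seed
  ))
  print(table(x$truth$class))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits one bedGraph per library, the candidate-element catalog and truth
#' intervals as BED6, the truth table as TSV and a YAML echo of the
#' configuration.
#'
#' @param sim Result of [simulate_tracks()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "pre_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(sim$tracks))) {
    f <- file.path(dir, sprintf("%s_rep%d_%s.bedgraph",
                                sim$tracks$genotype[i],
                                sim$tracks$replicate[i], sim$tracks$type[i]))
    write_bedgraph(sim$tracks$track[[i]], f)
  }
  write_bed(sim$catalog, file.path(dir, "catalog.bed"))
  write_bed(dplyr::mutate(sim$truth, score = 0, strand = "."),
            file.path(dir, "truth.bed"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  cfg <- sim$config
  class(cfg) <- NULL
  cfg$class_fractions <- as.list(cfg$class_fractions)
  cfg$attenuation_by_class <- as.list(cfg$attenuation_by_class)
  cfg$tail_attenuation_by_class <- as.list(cfg$tail_attenuation_by_class)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
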