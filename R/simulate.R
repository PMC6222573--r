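# run code under a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  code
}

#' Build a synthetic MA-experiment configuration
#'
#' Describes one genotype-trait cell of an MA experiment by its generating
#' parameters: control mean `z0_true`; per-generation change in the mean
#' `rm_true` (trait units per generation, so the generating mutational
#' bias is `rm_true / z0_true`); per-generation mutational variance among
#' lines `vm_raw` (trait units squared); and within-line environmental
#' variance `ve_raw`. The sampling design (lines, individuals per line,
#' control individuals, per-line generations of divergence) is shared
#' across traits.
#'
#' @param traits Tibble with columns `population`, `genotype`, `trait`,
#'   `z0_true`, `rm_true`, `vm_raw`, `ve_raw`. Genotype identifiers must
#'   be unique across populations.
#' @param generations Named list: for each genotype, a numeric vector of
#'   per-line generations of divergence (length `n_ma_lines`, all > 0).
#' @param n_ma_lines MA lines per genotype.
#' @param n_per_ma_line Assayed individuals per MA line.
#' @param n_control Assayed control individuals per genotype.
#' @return A list of class `"ma_sim_config"`.
#' @seealso [default_sim_config()] for the standard two-population,
#'   six-genotype design; [simulate_experiment()] to draw data.
#' @export
ma_sim_config <- function(traits, generations,
                          n_ma_lines = 5, n_per_ma_line = 5, n_control = 15) {
  need <- c("population", "genotype", "trait", "z0_true", "rm_true",
            "vm_raw", "ve_raw")
  missing <- setdiff(need, names(traits))
  if (length(missing) > 0)
    stop("traits is missing column(s): ", paste(missing, collapse = ", "))
  if (any(traits$vm_raw < 0)) stop("vm_raw must be >= 0")
  if (any(traits$ve_raw <= 0)) stop("ve_raw must be > 0")
  genos <- unique(traits$genotype)
  if (anyDuplicated(unique(traits[c("population", "genotype")])$genotype))
    stop("genotype identifiers must be unique across populations")
  if (!setequal(names(generations), genos))
    stop("generations must be a named list with one entry per genotype")
  for (g in genos) {
    gi <- generations[[g]]
    if (length(gi) != n_ma_lines)
      stop("generations[['", g, "']] must have ", n_ma_lines, " entries")
    if (any(gi <= 0)) stop("generations of divergence must be > 0")
  }
  structure(
    list(traits = tibble::as_tibble(traits), generations = generations,
         n_ma_lines = as.integer(n_ma_lines),
         n_per_ma_line = as.integer(n_per_ma_line),
         n_control = as.integer(n_control)),
    class = "ma_sim_config"
  )
}

#' Default synthetic configuration: two populations, six genotypes
#'
#' The standard design this package targets: 2 populations x 3 genotypes,
#' 5 MA lines per genotype propagated by single-offspring descent for
#' roughly 19-25 generations (genotype means 19.2-24.8), 5 assayed
#' individuals per MA line and 15 per control population, and six traits
#' (age at maturity, egg number, body size, and maximum / mean / SD of
#' swimming velocity). Control means, mutational biases and evolvabilities
#' default to the published *D. magna* estimates bundled with the package
#' ([dmagna_ma_estimates()]): `z0_true` is the published control mean,
#' `rm_true = delta_m * z0`, and `vm_raw = cv_m2 * z0^2`, so the generator
#' reproduces the published effect sizes. The within-line environmental
#' SD defaults to a coefficient of variation `cv_e` of the control mean.
#' Per-line generations are the genotype mean plus `-2, -1, 0, 1, 2`.
#'
#' @param cv_e Within-line environmental coefficient of variation
#'   (default 0.15, a typical within-clone spread for life-history and
#'   behavioral assays of this kind).
#' @return An `"ma_sim_config"`.
#' @export
default_sim_config <- function(cv_e = 0.15) {
  est <- dmagna_ma_estimates()
  traits <- tibble::tibble(
    population = est$population,
    genotype = paste0(est$population, est$genotype),
    trait = est$trait,
    z0_true = est$z0,
    rm_true = est$delta_m * est$z0,
    vm_raw = est$cv_m2 * est$z0^2,
    ve_raw = (cv_e * est$z0)^2
  )
  god <- unique(tibble::tibble(genotype = paste0(est$population, est$genotype),
                               god = est$god))
  generations <- stats::setNames(
    lapply(god$god, function(g) g + c(-2, -1, 0, 1, 2)),
    god$genotype
  )
  ma_sim_config(traits, generations)
}

#' Simulate an MA experiment
#'
#' Draws a long-format phenotype table under a line-level Brownian model
#' of mutation accumulation: MA line *i* of a genotype has true mean
#' `z0_true + N(g_i * rm_true, g_i * vm_raw)` for a trait (its mutational
#' divergence accumulates linearly in its generations of divergence
#' `g_i`), each assayed MA individual adds environmental noise
#' `N(0, ve_raw)`, and each control individual is `N(z0_true, ve_raw)`.
#' Line effects are drawn independently per trait.
#'
#' @param config An [ma_sim_config()].
#' @param seed Integer seed; the output is fully reproducible from it.
#' @return Phenotype tibble in the canonical long format
#'   ([phenotype_columns()]).
#' @export
simulate_experiment <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ma_sim_config"))
  local_seed(seed, {
    rows <- lapply(seq_len(nrow(config$traits)), function(r) {
      tr <- config$traits[r, ]
      g <- config$generations[[tr$genotype]]
      line_mu <- tr$z0_true +
        stats::rnorm(length(g), mean = g * tr$rm_true, sd = sqrt(g * tr$vm_raw))
      ma <- tibble::tibble(
        population = tr$population,
        genotype = tr$genotype,
        line_class = "MA",
        line_id = rep(paste0(tr$genotype, "_L", seq_along(g)),
                      each = config$n_per_ma_line),
        individual_id = paste0("i", sequence(rep(config$n_per_ma_line, length(g)))),
        trait = tr$trait,
        value = stats::rnorm(length(g) * config$n_per_ma_line,
                             mean = rep(line_mu, each = config$n_per_ma_line),
                             sd = sqrt(tr$ve_raw)),
        generations = rep(g, each = config$n_per_ma_line)
      )
      ctrl <- tibble::tibble(
        population = tr$population,
        genotype = tr$genotype,
        line_class = "control",
        line_id = paste0(tr$genotype, "_C"),
        individual_id = paste0("c", seq_len(config$n_control)),
        trait = tr$trait,
        value = stats::rnorm(config$n_control, tr$z0_true, sqrt(tr$ve_raw)),
        generations = 0
      )
      dplyr::bind_rows(ma, ctrl)
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate correlated random-walk tracks
#'
#' Generates trajectory point tables for testing and demonstrating the
#' velocity phenotypes. Each track is a correlated random walk: headings
#' evolve by Gaussian turning increments, and per-step speeds are drawn
#' from `N(speed_mean, speed_sd)` truncated at zero, so the realized
#' step-speed distribution matches the requested moments when
#' `speed_sd << speed_mean`.
#'
#' @param n Number of tracks.
#' @param speed_mean,speed_sd Target mean and SD of step speeds
#'   (length units per second).
#' @param dt Frame interval, seconds (> 0).
#' @param duration Track duration, seconds (>= 2 * dt).
#' @param seed Integer seed.
#' @param turn_sd SD of the Gaussian heading increment per step, radians.
#' @return Tibble with columns `track_id`, `t`, `x`, `y`.
#' @export
simulate_tracks <- function(n, speed_mean, speed_sd, dt, duration,
                            seed = NULL, turn_sd = 0.4) {
  if (dt <= 0) stop("dt must be > 0")
  if (duration < 2 * dt) stop("duration must be at least 2 * dt")
  if (speed_sd < 0) stop("speed_sd must be >= 0")
  n_steps <- floor(duration / dt)
  local_seed(seed, {
    out <- lapply(seq_len(n), function(k) {
      s <- stats::rnorm(n_steps, speed_mean, speed_sd)
      while (any(s < 0)) {
        bad <- s < 0
        s[bad] <- stats::rnorm(sum(bad), speed_mean, speed_sd)
      }
      theta <- cumsum(stats::rnorm(n_steps, 0, turn_sd))
      tibble::tibble(
        track_id = sprintf("track%03d", k),
        t = seq(0, n_steps) * dt,
        x = c(0, cumsum(s * dt * cos(theta))),
        y = c(0, cumsum(s * dt * sin(theta)))
      )
    })
    dplyr::bind_rows(out)
  })
}
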