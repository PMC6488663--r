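#' Simulation configuration
#'
#' Bundles every run parameter. Defaults are the full-scale study conditions:
#' 200 prey agents on a 120 x 120 torus, 2000 time steps per generation,
#' 3000 generations, Moore radius 1, kill fraction 0.05, mutation variance
#' 5e-4 and full blocking (`p_transit = 0`). `herd_config(profile =
#' "scaled")` gives the desk-scale profile (T = 500, G = 1500) used for
#' routine analysis.
#'
#' @param width,height Lattice dimensions in cells (torus in both axes).
#' @param n_agents Population size N; at most `width * height`.
#' @param steps Time steps per generation (T). Every agent acts once per
#'   step, in a fresh random order.
#' @param generations Number of generations (G); generation 0 is the random
#'   initial population.
#' @param radius Moore-neighbourhood radius r used for neighbourhood sizes;
#'   the window holds `(2r+1)^2 - 1` cells.
#' @param kill_fraction Truncation-selection fraction mu; `round(mu * N)`
#'   lowest-scoring agents are removed each generation.
#' @param mutation_variance Variance of the Gaussian weight mutation
#'   (epsilon ~ N(0, 5e-4) by default, i.e. sd ~ 0.02236).
#' @param p_transit Probability that a move into an occupied cell succeeds by
#'   swapping positions with its occupant; 0 = full blocking, 1 = unhindered
#'   transit.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param init_weight_range Initial genotype weights are drawn uniformly from
#'   `[-init_weight_range, init_weight_range]`.
#' @param archive_every Archive the full genotype table every this many
#'   generations (plus at `epoch_generations` and the final generation).
#' @param epoch_generations Generations always archived, defaulting to the
#'   representative evolutionary epochs 0/80/200/1000.
#' @param profile `"full"` (the defaults) or `"scaled"` (T = 500, G = 1500).
#'
#' @return An object of class `herd_config` (a validated named list).
#' @examples
#' cfg <- herd_config(profile = "scaled", seed = 1)
#' cfg$steps
#' @export
herd_config <- function(width = 120L, height = 120L, n_agents = 200L,
                        steps = 2000L, generations = 3000L, radius = 1L,
                        kill_fraction = 0.05, mutation_variance = 5e-4,
                        p_transit = 0, seed = NULL,
                        init_weight_range = 1,
                        archive_every = 20L,
                        epoch_generations = c(0L, 80L, 200L, 1000L),
                        profile = c("full", "scaled")) {
  profile <- match.arg(profile)
  if (profile == "scaled") {
    if (missing(steps)) steps <- 500L
    if (missing(generations)) generations <- 1500L
  }
  cfg <- list(
    width = as.integer(width), height = as.integer(height),
    n_agents = as.integer(n_agents), steps = as.integer(steps),
    generations = as.integer(generations), radius = as.integer(radius),
    kill_fraction = kill_fraction, mutation_variance = mutation_variance,
    p_transit = p_transit,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    init_weight_range = init_weight_range,
    archive_every = as.integer(archive_every),
    epoch_generations = as.integer(epoch_generations)
  )
  class(cfg) <- "herd_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(cfg$width >= 1, cfg$height >= 1)
  if (cfg$n_agents < 0 || cfg$n_agents > cfg$width * cfg$height) {
    stop("n_agents must be between 0 and width * height (lattice capacity)",
         call. = FALSE)
  }
  if (cfg$radius < 1) stop("radius must be >= 1", call. = FALSE)
  if (2 * cfg$radius + 1 > min(cfg$width, cfg$height)) {
    stop("Moore window (2r+1) must fit on the lattice", call. = FALSE)
  }
  if (cfg$kill_fraction < 0 || cfg$kill_fraction >= 1) {
    stop("kill_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$p_transit < 0 || cfg$p_transit > 1) {
    stop("p_transit must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$mutation_variance < 0) stop("mutation_variance must be >= 0",
                                      call. = FALSE)
  stopifnot(cfg$steps >= 1, cfg$generations >= 1)
  invisible(cfg)
}

#' @export
print.herd_config <- function(x, ...) {
  cat("<herd_config>\n")
  cat(sprintf("  lattice      %d x %d (torus), Moore radius %d\n",
              x$width, x$height, x$radius))
  cat(sprintf("  population   N = %d, steps/gen T = %d, generations G = %d\n",
              x$n_agents, x$steps, x$generations))
  cat(sprintf("  selection    mu = %g (kills %d/gen), mutation var = %g\n",
              x$kill_fraction, round(x$kill_fraction * x$n_agents),
              x$mutation_variance))
  cat(sprintf("  p_transit    %g   seed %s\n", x$p_transit,
              if (is.null(x$seed)) "<unset>" else x$seed))
  invisible(x)
}

#' Read or write a configuration as a flat YAML file
#'
#' Keys match the arguments of [herd_config()]; unknown keys are rejected.
#'
#' @param path File path.
#' @return `read_herd_config()` returns a `herd_config`;
#'   `write_herd_config()` returns `path` invisibly.
#' @export
read_herd_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- setdiff(names(formals(herd_config)), "profile")
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(herd_config, vals)
}

#' @param config A `herd_config`.
#' @rdname read_herd_config
#' @export
write_herd_config <- function(config, path) {
  stopifnot(inherits(config, "herd_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Window maximum of a Moore neighbourhood
#'
#' Number of cells in the Moore window of radius `r`, i.e. `(2r+1)^2 - 1`
#' (8 for r = 1); the normalising constant for perceived neighbourhood sizes
#' and the upper bound of the neighbourhood score.
#'
#' @param r Radius (>= 1).
#' @return Integer cell count.
#' @export
window_max <- function(r = 1L) {
  stopifnot(r >= 1)
  as.integer((2L * r + 1L)^2 - 1L)
}
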