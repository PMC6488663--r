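#' Neighbourhood score of an agent
#'
#' The mean per-step neighbourhood size over a generation - the fitness
#' proxy of the model. An agent whose full Moore window (radius 1) stays
#' occupied every step scores 8; agents with the lowest scores are
#' "predated" by truncation selection.
#'
#' @param sizes Integer vector of per-step neighbourhood sizes (one per
#'   recorded time step).
#' @return The arithmetic mean.
#' @examples
#' neighbourhood_score(c(8, 8, 8))
#' @export
neighbourhood_score <- function(sizes) {
  if (length(sizes) == 0) stop("undefined score: no recorded steps",
                               call. = FALSE)
  mean(sizes)
}

#' Run one generation of the movement dynamics
#'
#' Places the agents at random (or at `positions`), runs `config$steps`
#' asynchronous time steps, and returns per-agent neighbourhood and mobility
#' scores plus the aggregated conditional leave-probability counts. With
#' `record = TRUE` the full per-step trajectory is kept, enabling
#' [generation_records()], [snapshots()] and [conditional_profile()].
#'
#' Uses the current RNG state; call `set.seed()` first for reproducibility.
#' The compiled engine (default) and the plain-R reference engine consume
#' identical RNG draws, so results agree bit-for-bit.
#'
#' @param genotypes An `n` x 44 population weight matrix (row i = agent i).
#' @param config A [herd_config()]; `width`, `height`, `steps`, `radius` and
#'   `p_transit` are used, and `n` is taken from `genotypes`.
#' @param record Keep per-step positions, neighbourhood sizes and move
#'   flags.
#' @param positions Optional data frame `id, x, y` fixing the initial
#'   placement (otherwise placement is uniform random without overlap).
#' @param engine `"cpp"` (optimised) or `"r"` (reference).
#' @return An object of class `herd_generation`: a list with `agents` (a
#'   tibble `id, neighbourhood_score, mobility_score`), `profile` (a tibble
#'   `n, occasions, moves, probability`), `final_lattice`, `config`, and the
#'   recording matrices when requested.
#' @examples
#' set.seed(1)
#' cfg <- herd_config(width = 12, height = 12, n_agents = 10, steps = 20,
#'                    generations = 1)
#' gen <- run_generation(random_genotypes(10), cfg)
#' gen$agents
#' @export
run_generation <- function(genotypes, config, record = FALSE,
                           positions = NULL, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "herd_config"), is.matrix(genotypes),
            ncol(genotypes) == 44)
  n <- nrow(genotypes)
  if (n > config$width * config$height) {
    stop("capacity error: more genotypes than lattice cells", call. = FALSE)
  }
  init_cells <- NULL
  if (!is.null(positions)) {
    stopifnot(all(c("id", "x", "y") %in% names(positions)),
              nrow(positions) == n, setequal(positions$id, seq_len(n)))
    lat0 <- herd_lattice(config$width, config$height)  # validates coords
    check_cell(lat0, positions$x, positions$y)
    init_cells <- integer(n)
    init_cells[positions$id] <- positions$y * config$width + positions$x
    if (anyDuplicated(init_cells)) stop("overlapping initial positions",
                                        call. = FALSE)
  }
  raw <- if (engine == "cpp") {
    cpp_run_generation(config$width, config$height, config$steps,
                       config$radius, config$p_transit,
                       unname(genotypes), record,
                       if (is.null(init_cells)) NULL else as.integer(init_cells))
  } else {
    r_run_generation(genotypes, config, init_cells = init_cells,
                     record = record)
  }
  wmax <- window_max(config$radius)
  profile <- tibble::tibble(
    n = 0:wmax,
    occasions = raw$occasions,
    moves = raw$moves,
    probability = ifelse(raw$occasions > 0, raw$moves / raw$occasions,
                         NA_real_))
  xy <- list(x = raw$final_cells %% config$width,
             y = raw$final_cells %/% config$width)
  final_lat <- herd_lattice(config$width, config$height,
                            data.frame(id = seq_len(n), x = xy$x, y = xy$y))
  out <- list(
    agents = tibble::tibble(id = seq_len(n),
                            neighbourhood_score = raw$neighbourhood_score,
                            mobility_score = raw$mobility_score),
    profile = profile,
    final_lattice = final_lat,
    config = config,
    n_agents = n)
  if (record) {
    out$positions <- raw$positions
    out$neighbour_sizes <- raw$neighbour_sizes
    out$moved <- raw$moved
  }
  structure(out, class = "herd_generation")
}

#' @export
print.herd_generation <- function(x, ...) {
  cat(sprintf(
    "<herd_generation> %d agents, %d steps: mean S^N = %.3f, mean S^M = %.3f\n",
    x$n_agents, x$config$steps, mean(x$agents$neighbourhood_score),
    mean(x$agents$mobility_score)))
  invisible(x)
}

#' Per-step records of a recorded generation
#'
#' Long-format pairing used by the conditional leave-probability profile:
#' for each agent and each step `t` (1..T-1), the neighbourhood size
#' recorded at the end of step `t` together with whether the agent's cell
#' changed during step `t + 1`.
#'
#' @param generation A `herd_generation` run with `record = TRUE`.
#' @return A tibble `agent_id, step, n, moved`.
#' @export
generation_records <- function(generation) {
  stopifnot(inherits(generation, "herd_generation"))
  if (is.null(generation$neighbour_sizes)) {
    stop("generation was not run with record = TRUE", call. = FALSE)
  }
  T <- ncol(generation$neighbour_sizes)
  n <- nrow(generation$neighbour_sizes)
  if (T < 2) {
    return(tibble::tibble(agent_id = integer(), step = integer(),
                          n = integer(), moved = logical()))
  }
  tibble::tibble(
    agent_id = rep(seq_len(n), T - 1L),
    step = rep(seq_len(T - 1L), each = n),
    n = as.vector(generation$neighbour_sizes[, -T, drop = FALSE]),
    moved = as.vector(generation$moved) == 1L)
}

#' Per-step agent positions of a recorded generation
#'
#' @param generation A `herd_generation` run with `record = TRUE`.
#' @param generation_index Value for the `generation` column.
#' @return A tibble `generation, step, agent_id, x, y` (0-based coordinates,
#'   x = column, y = row).
#' @export
snapshots <- function(generation, generation_index = 0L) {
  stopifnot(inherits(generation, "herd_generation"))
  if (is.null(generation$positions)) {
    stop("generation was not run with record = TRUE", call. = FALSE)
  }
  pos <- generation$positions
  w <- generation$config$width
  n <- nrow(pos); T <- ncol(pos)
  tibble::tibble(
    generation = generation_index,
    step = rep(seq_len(T), each = n),
    agent_id = rep(seq_len(n), T),
    x = as.vector(pos) %% w,
    y = as.vector(pos) %/% w)
}

#' Export per-step positions as CSV
#'
#' Columns `generation, step, agent_id, x, y`; 0-based coordinates,
#' row-major, `x` = column, `y` = row.
#'
#' @inheritParams snapshots
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_snapshots_csv <- function(generation, path, generation_index = 0L) {
  readr::write_csv(snapshots(generation, generation_index), path)
  invisible(path)
}

#' Truncation selection and refill
#'
#' Removes the `round(kill_fraction * n)` agents with the lowest scores
#' (ties at the cutoff broken uniformly at random) and restores the
#' population by creating one offspring per removed agent via
#' [crossover_mutate()] from two distinct survivors drawn uniformly at
#' random. Survivor genotypes are carried over unmodified. When all scores
#' are identical the killed set is effectively a uniform random draw.
#'
#' @param genotypes `n` x 44 population weight matrix.
#' @param scores Per-agent neighbourhood scores aligned with rows.
#' @param kill_fraction Fraction mu in `[0, 1)`.
#' @param mutation_sd Mutation standard deviation passed to
#'   [crossover_mutate()].
#' @return A list with `genotypes` (next generation, same shape), `killed`
#'   and `survivors` (sorted id vectors).
#' @examples
#' set.seed(1)
#' pop <- random_genotypes(10)
#' nxt <- select_and_reproduce(pop, runif(10), 0.2)
#' nxt$killed
#' @export
select_and_reproduce <- function(genotypes, scores, kill_fraction,
                                 mutation_sd = sqrt(5e-4)) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) == 44,
            length(scores) == nrow(genotypes),
            kill_fraction >= 0, kill_fraction < 1)
  n <- nrow(genotypes)
  k <- round(kill_fraction * n)
  if (k == 0) {
    return(list(genotypes = genotypes, killed = integer(),
                survivors = seq_len(n)))
  }
  thr <- sort(scores)[k]
  definite <- which(scores < thr)
  border <- which(scores == thr)
  need <- k - length(definite)
  chosen <- integer(0)
  if (need > 0) {
    arr <- border
    nb <- length(arr)
    for (q in seq_len(need)) {
      j <- q + min(floor(runif(1) * (nb - q + 1)), nb - q)
      tmp <- arr[q]; arr[q] <- arr[j]; arr[j] <- tmp
    }
    chosen <- arr[seq_len(need)]
  }
  killed <- sort(c(definite, chosen))
  survivors <- setdiff(seq_len(n), killed)
  ns <- length(survivors)
  offspring <- matrix(NA_real_, k, 44)
  for (q in seq_len(k)) {
    a <- min(floor(runif(1) * ns), ns - 1) + 1L
    repeat {
      b <- min(floor(runif(1) * ns), ns - 1) + 1L
      if (b != a) break
    }
    offspring[q, ] <- flatten_genotype(
      crossover_mutate(genotypes[survivors[a], ], genotypes[survivors[b], ],
                       mutation_sd = mutation_sd))
  }
  out <- genotypes
  out[killed, ] <- offspring
  list(genotypes = out, killed = killed, survivors = survivors)
}

#' Run a full evolutionary simulation
#'
#' The generational loop: random placement, `steps` asynchronous movement
#' steps, neighbourhood-score evaluation, truncation selection and refill -
#' repeated for `generations` generations (generation 0 is the random
#' initial population). Per-generation population statistics and the
#' aggregated conditional leave-probability profile are logged; full
#' genotype tables are archived at the configured cadence.
#'
#' If `config$seed` is set the global RNG is seeded first, making the entire
#' run (and its logs) reproducible bit-for-bit.
#'
#' @param config A [herd_config()].
#' @param engine `"cpp"` (optimised; use this for real runs) or `"r"`
#'   (plain-R reference, identical results, small scales only).
#' @return An object of class `herd_evolution`: `generations` (tibble with
#'   `generation`, `mean_S_N`, `mean_S_M`, `var_S_N`, `var_S_M`, and
#'   `p_move_0` .. `p_move_<wmax>`), `archives` (named list of genotype
#'   matrices keyed by generation), `final_genotypes` (population after the
#'   last selection), `killed` (per-generation killed ids) and `config`.
#' @examples
#' cfg <- herd_config(width = 15, height = 15, n_agents = 12, steps = 30,
#'                    generations = 5, seed = 1)
#' evo <- run_evolution(cfg)
#' tidy(evo)
#' @export
run_evolution <- function(config, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "herd_config"))
  validate_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  G <- config$generations
  archive_gens <- sort(unique(c(
    config$epoch_generations,
    seq(0L, G - 1L, by = max(config$archive_every, 1L)),
    G - 1L)))
  archive_gens <- archive_gens[archive_gens >= 0 & archive_gens < G]
  weights0 <- random_genotypes(config$n_agents, config$init_weight_range)
  raw <- if (engine == "cpp") {
    cpp_run_evolution(config$width, config$height, config$steps, G,
                      config$radius, config$kill_fraction,
                      sqrt(config$mutation_variance), config$p_transit,
                      unname(weights0), as.integer(archive_gens))
  } else {
    r_run_evolution(config, weights0, archive_gens)
  }
  wmax <- window_max(config$radius)
  prob <- raw$moves / ifelse(raw$occasions > 0, raw$occasions, NA_real_)
  colnames(prob) <- paste0("p_move_", 0:wmax)
  gens <- tibble::tibble(
    generation = seq_len(G) - 1L,
    mean_S_N = raw$stats[, 1],
    mean_S_M = raw$stats[, 3],
    var_S_N = raw$stats[, 2],
    var_S_M = raw$stats[, 4])
  gens <- dplyr::bind_cols(gens, tibble::as_tibble(prob))
  archives <- lapply(raw$archives, function(w) {
    colnames(w) <- weight_names()
    w
  })
  final <- raw$final_weights
  colnames(final) <- weight_names()
  structure(list(generations = gens, archives = archives,
                 final_genotypes = final, killed = raw$killed,
                 config = config, window_max = wmax),
            class = "herd_evolution")
}

#' @export
print.herd_evolution <- function(x, ...) {
  g <- x$generations
  last <- g[nrow(g), ]
  cat(sprintf("<herd_evolution> %d generations of %d agents (p_transit = %g)\n",
              nrow(g), x$config$n_agents, x$config$p_transit))
  cat(sprintf("  final generation: mean S^N = %.3f, mean S^M = %.3f\n",
              last$mean_S_N, last$mean_S_M))
  cat(sprintf("  archives at generations: %s\n",
              paste(names(x$archives), collapse = ", ")))
  invisible(x)
}

#' Export the per-generation metrics log as CSV
#'
#' Columns: `generation`, `mean_S_N`, `mean_S_M`, `var_S_N`, `var_S_M` and
#' the conditional move probabilities `p_move_0` .. `p_move_<wmax>`.
#'
#' @param evolution A `herd_evolution`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_generation_log <- function(evolution, path) {
  stopifnot(inherits(evolution, "herd_evolution"))
  readr::write_csv(evolution$generations, path)
  invisible(path)
}
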