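#' Mobility score of a trajectory
#'
#' The per-step frequency with which an agent changes cells: the fraction of
#' the `T - 1` transitions between consecutive recorded positions where the
#' cell changed. Range `[0, 1]`; a stationary agent scores 0, an agent that
#' moves every step scores 1.
#'
#' @param trajectory Either a data frame/matrix with columns `x`, `y` (one
#'   row per recorded step) or an integer vector of cell indices.
#' @return The mobility score.
#' @examples
#' mobility_score(data.frame(x = c(0, 1, 1, 2), y = 0))  # 2/3
#' @export
mobility_score <- function(trajectory) {
  cells <- if (is.data.frame(trajectory) || is.matrix(trajectory)) {
    tr <- as.data.frame(trajectory)
    stopifnot(all(c("x", "y") %in% names(tr)))
    paste(tr$x, tr$y)
  } else {
    trajectory
  }
  T <- length(cells)
  if (T < 2) stop("undefined mobility: trajectory must have >= 2 steps",
                  call. = FALSE)
  mean(cells[-1] != cells[-T])
}

#' Conditional leave-probability profile
#'
#' For each neighbourhood size `n`, the measured probability that an agent
#' left its cell on the following step given it had `n` occupied Moore
#' cells: `moves / occasions`. With full blocking the profile is pinned at
#' 1 for `n = 0` (all four targets vacant) and 0 at the window maximum (all
#' targets occupied) on settled configurations. Bins with no occasions are
#' reported as `NA`, not 0.
#'
#' @param records A data frame with columns `n` (neighbourhood size at step
#'   t) and `moved` (logical/0-1: cell changed during step t+1), e.g. from
#'   [generation_records()]. Additional columns are ignored.
#' @param window_max Largest bin (defaults to the largest `n` observed or 8,
#'   whichever is larger).
#' @return A tibble `n, occasions, moves, probability` covering
#'   `0..window_max`.
#' @examples
#' recs <- data.frame(n = c(0, 0, 2, 2), moved = c(TRUE, TRUE, TRUE, FALSE))
#' conditional_profile(recs)
#' @export
conditional_profile <- function(records, window_max = NULL) {
  records <- as.data.frame(records)
  if (!all(c("n", "moved") %in% names(records))) {
    stop("records must have columns 'n' and 'moved'", call. = FALSE)
  }
  if (any(is.na(records$n)) || any(records$n < 0) ||
      any(records$n != floor(records$n))) {
    stop("rejected records: 'n' must be non-negative integers", call. = FALSE)
  }
  wm <- window_max %||% max(8L, if (nrow(records)) max(records$n) else 0L)
  if (nrow(records) && max(records$n) > wm) {
    stop("rejected records: n exceeds window_max", call. = FALSE)
  }
  counts <- records |>
    dplyr::group_by(n = as.integer(.data$n)) |>
    dplyr::summarise(occasions = dplyr::n(),
                     moves = sum(as.logical(.data$moved)), .groups = "drop")
  out <- tibble::tibble(n = 0:wm) |>
    dplyr::left_join(counts, by = "n") |>
    dplyr::mutate(occasions = dplyr::coalesce(.data$occasions, 0L),
                  moves = dplyr::coalesce(.data$moves, 0L),
                  probability = ifelse(.data$occasions > 0,
                                       .data$moves / .data$occasions,
                                       NA_real_))
  out
}

#' Genotype likelihood (strategy similarity)
#'
#' One minus the mean absolute difference of the 44 link weights of two
#' genotypes. Symmetric, at most 1, and exactly 1 only for identical
#' genotypes; it can be negative for very distant genotypes (not clipped).
#'
#' @param a,b Genotypes in any form [as_genotype()] accepts.
#' @return A scalar likelihood value.
#' @examples
#' genotype_likelihood(rep(0, 44), rep(1, 44))  # 0
#' @export
genotype_likelihood <- function(a, b) {
  wa <- flatten_genotype(a)
  wb <- flatten_genotype(b)
  1 - mean(abs(wa - wb))
}

#' Reference strategy from an archived population
#'
#' The element-wise mean of all genotype weight tables in an archived
#' population - the "average network topology" representing the strategy
#' prevailing at that generation (signs of evolved weights are run-specific,
#' so references must come from the same run they are compared against).
#'
#' @param weights An `n` x 44 archived population matrix (e.g. an element of
#'   `herd_evolution$archives`).
#' @param label Strategy label, conventionally `"coward"`, `"explorer"` or
#'   `"dodger"`.
#' @return An 11 x 4 genotype matrix with attribute `label`.
#' @export
strategy_reference <- function(weights, label) {
  stopifnot(is.matrix(weights), ncol(weights) == 44)
  ref <- as_genotype(colMeans(weights))
  attr(ref, "label") <- label
  ref
}

#' Reference strategies at the three evolutionary epochs
#'
#' Builds the coward/explorer/dodger references from a run's archives at the
#' designated epoch generations.
#'
#' @param evolution A `herd_evolution`.
#' @param epochs Named integer vector mapping strategy labels to archived
#'   generations (defaults to the representative epochs 80/200/1000).
#' @return A named list of three reference genotypes.
#' @export
strategy_references <- function(evolution,
                                epochs = c(coward = 80L, explorer = 200L,
                                           dodger = 1000L)) {
  stopifnot(inherits(evolution, "herd_evolution"))
  missing_g <- setdiff(as.character(epochs), names(evolution$archives))
  if (length(missing_g)) {
    stop("missing epoch archive for generation(s) ",
         paste(missing_g, collapse = ", "),
         "; re-run with these in epoch_generations", call. = FALSE)
  }
  purrr::imap(as.list(epochs), function(g, lab) {
    strategy_reference(evolution$archives[[as.character(g)]], lab)
  })
}

#' Likelihood embedding of a population against reference strategies
#'
#' Positions each agent in strategy space by its genotype likelihood to each
#' reference (e.g. `L_coward`, `L_explorer`, `L_dodger`), the per-agent
#' coordinates of the adaptive-dynamics trajectory.
#'
#' @param weights An `n` x 44 population matrix.
#' @param references A named list of reference genotypes (see
#'   [strategy_references()]).
#' @return A tibble with `agent_id` and one `L_<label>` column per
#'   reference.
#' @export
strategy_embedding <- function(weights, references) {
  stopifnot(is.matrix(weights), ncol(weights) == 44, length(references) >= 1,
            !is.null(names(references)))
  out <- tibble::tibble(agent_id = seq_len(nrow(weights)))
  for (lab in names(references)) {
    ref <- flatten_genotype(references[[lab]])
    out[[paste0("L_", lab)]] <-
      vapply(seq_len(nrow(weights)),
             function(i) genotype_likelihood(weights[i, ], ref), numeric(1))
  }
  out
}

#' Epoch summary and phase boundaries of an evolutionary run
#'
#' Reports the population mean scores at requested generations and detects
#' plateau boundaries on the mean-mobility series with a simple documented
#' heuristic: the series is smoothed by a centred rolling mean and the
#' locations of dominant local jumps (absolute smoothed first difference at
#' least half of the global maximum, local maxima only, minimum separation
#' one smoothing window) are reported as change points.
#'
#' @param evolution A `herd_evolution`.
#' @param epochs Generations to summarise (clipped to the run length).
#' @param smooth Rolling-mean half window (generations).
#' @return A tibble `generation, mean_S_N, mean_S_M`; detected boundaries in
#'   attribute `change_points`.
#' @export
epoch_summary <- function(evolution, epochs = c(0L, 80L, 200L, 1000L),
                          smooth = 25L) {
  stopifnot(inherits(evolution, "herd_evolution"))
  g <- evolution$generations
  epochs <- epochs[epochs >= 0 & epochs < nrow(g)]
  out <- g[g$generation %in% epochs, c("generation", "mean_S_N", "mean_S_M")]
  attr(out, "change_points") <- detect_change_points(g$mean_S_M, smooth)
  out
}

# rolling-mean smoothing + dominant-jump heuristic; returns generation
# indices (0-based) or integer(0) for a flat series
detect_change_points <- function(series, smooth = 25L) {
  n <- length(series)
  if (n < 3) return(integer(0))
  k <- max(1L, min(smooth, floor((n - 1) / 2)))
  sm <- stats::filter(series, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- series[is.na(sm)]
  d <- abs(diff(sm))
  dmax <- max(d)
  if (!is.finite(dmax) || dmax <= 1e-12) return(integer(0))
  cand <- which(d >= 0.5 * dmax)
  # keep local maxima separated by at least one window
  cand <- cand[order(-d[cand])]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) > 2 * k)) keep <- c(keep, i)
  }
  sort(keep) - 1L  # boundary between generation (i-1) and i, 0-based
}
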