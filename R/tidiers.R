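#' Tidy a herd_evolution into its per-generation table
#'
#' @param x A `herd_evolution`.
#' @param ... Unused.
#' @return The per-generation tibble (`generation`, `mean_S_N`, `mean_S_M`,
#'   variances and conditional move probabilities).
#' @method tidy herd_evolution
#' @export
tidy.herd_evolution <- function(x, ...) x$generations

#' One-row summary of an evolutionary run
#'
#' @param x A `herd_evolution`.
#' @param tail_window Trailing generations averaged for the final state.
#' @param ... Unused.
#' @return A one-row tibble: run parameters plus final-state mean scores.
#' @method glance herd_evolution
#' @export
glance.herd_evolution <- function(x, tail_window = 100L, ...) {
  fin <- final_state(x, tail_window)
  tibble::tibble(generations = nrow(x$generations),
                 n_agents = x$config$n_agents,
                 steps = x$config$steps,
                 p_transit = x$config$p_transit,
                 kill_fraction = x$config$kill_fraction,
                 final_mean_S_N = fin$mean_S_N,
                 final_mean_S_M = fin$mean_S_M)
}

#' Tidy a recorded generation into per-agent scores
#'
#' @param x A `herd_generation`.
#' @param ... Unused.
#' @return The per-agent tibble (`id`, `neighbourhood_score`,
#'   `mobility_score`).
#' @method tidy herd_generation
#' @export
tidy.herd_generation <- function(x, ...) x$agents

#' @rdname tidy.herd_generation
#' @method glance herd_generation
#' @export
glance.herd_generation <- function(x, ...) {
  tibble::tibble(n_agents = x$n_agents, steps = x$config$steps,
                 p_transit = x$config$p_transit,
                 mean_S_N = mean(x$agents$neighbourhood_score),
                 mean_S_M = mean(x$agents$mobility_score))
}
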