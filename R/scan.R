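#' Comparative squeeze-through scan
#'
#' Runs the evolutionary simulation for each `p_transit` value and
#' replicate, recording the final-state population means - the data behind
#' the two-evolutionarily-stable-states comparison (collective motion:
#' high mobility, ~2 neighbours; stationary herds: low mobility, 4-5
#' neighbours). The study samples `p_transit` from 0 to 1 at 0.1 intervals
#' with 100 replicates each; replicates here default to a desk-scale count
#' and are a configuration choice, not a code change.
#'
#' Each run is seeded with `config$seed + 1000 * replicate_index +
#' value_index` so the scan is reproducible and rows are independent.
#'
#' @param config A [herd_config()] used for every run (its `p_transit` and
#'   `seed` fields are overridden per row; `seed` must be set).
#' @param values `p_transit` values in `[0, 1]`.
#' @param replicates Evolutionary runs per value.
#' @param tail_window Final-state statistics are means of the population
#'   means over the last `tail_window` generations.
#' @return A tibble `p_transit, replicate, seed, mean_S_N, mean_S_M` with
#'   `length(values) * replicates` rows.
#' @export
scan_ptransit <- function(config, values = seq(0, 1, by = 0.1),
                          replicates = 10L, tail_window = 100L) {
  stopifnot(inherits(config, "herd_config"),
            all(values >= 0 & values <= 1), replicates >= 1)
  if (is.null(config$seed)) {
    stop("scan_ptransit needs config$seed for per-run seed derivation",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(value_index = seq_along(values),
                             replicate = seq_len(replicates))
  purrr::pmap_dfr(grid, function(value_index, replicate) {
    cfg <- config
    cfg$p_transit <- values[value_index]
    cfg$seed <- as.integer(config$seed + 1000L * replicate + value_index)
    evo <- run_evolution(cfg)
    fin <- final_state(evo, tail_window)
    tibble::tibble(p_transit = values[value_index], replicate = replicate,
                   seed = cfg$seed,
                   mean_S_N = fin$mean_S_N, mean_S_M = fin$mean_S_M)
  })
}

#' Final-state summary of a run
#'
#' Population mean scores averaged over the last `tail_window` generations.
#'
#' @param evolution A `herd_evolution`.
#' @param tail_window Number of trailing generations to average.
#' @return A one-row tibble `mean_S_N, mean_S_M`.
#' @export
final_state <- function(evolution, tail_window = 100L) {
  stopifnot(inherits(evolution, "herd_evolution"))
  g <- evolution$generations
  tail_window <- min(tail_window, nrow(g))
  tl <- g[seq(nrow(g) - tail_window + 1L, nrow(g)), ]
  tibble::tibble(mean_S_N = mean(tl$mean_S_N), mean_S_M = mean(tl$mean_S_M))
}
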