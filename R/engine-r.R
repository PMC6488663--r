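# Plain-R reference engine.
#
# Mirrors src/engine.cpp operation-for-operation and draw-for-draw: given the
# same RNG state it produces bit-identical trajectories, scores, selection
# outcomes and offspring weights. It exists as a transparent executable
# description of the model and as the second route for equivalence tests;
# use it only at small scales.

r_run_generation <- function(weights, config, init_cells = NULL,
                             record = FALSE) {
  n <- nrow(weights)
  T <- config$steps
  r <- config$radius
  wmax <- window_max(r)
  lat <- herd_lattice(config$width, config$height)
  if (is.null(init_cells)) {
    lat <- place_agents(lat, n)
  } else {
    stopifnot(length(init_cells) == n)
    for (i in seq_len(n)) {
      xy <- cell_xy(lat, init_cells[i])
      lat <- lattice_place(lat, i, xy$x, xy$y)
    }
  }
  pos <- agent_cells(lat, n)
  prevpos <- pos
  prevn <- rep(-1L, n)
  nbrsum <- numeric(n)
  movecnt <- integer(n)
  occasions <- numeric(wmax + 1)
  moves <- numeric(wmax + 1)
  pos_rec <- if (record) matrix(NA_integer_, n, T) else NULL
  nbr_rec <- if (record) matrix(NA_integer_, n, T) else NULL
  mov_rec <- if (record) matrix(NA_integer_, n, max(T - 1, 0)) else NULL
  for (t in seq_len(T)) {
    lat <- lattice_step(lat, weights, p_transit = config$p_transit, r = r)$lattice
    pos <- agent_cells(lat, n)
    xy <- cell_xy(lat, pos)
    nn <- neighbourhood_size(lat, xy$x, xy$y, r)
    for (i in seq_len(n)) {
      moved <- pos[i] != prevpos[i]
      if (t >= 2) {
        movecnt[i] <- movecnt[i] + moved
        occasions[prevn[i] + 1L] <- occasions[prevn[i] + 1L] + 1
        moves[prevn[i] + 1L] <- moves[prevn[i] + 1L] + moved
        if (record) mov_rec[i, t - 1L] <- as.integer(moved)
      }
      nbrsum[i] <- nbrsum[i] + nn[i]
      prevn[i] <- nn[i]
      prevpos[i] <- pos[i]
      if (record) {
        pos_rec[i, t] <- pos[i]
        nbr_rec[i, t] <- nn[i]
      }
    }
  }
  out <- list(neighbourhood_score = nbrsum / T,
              mobility_score = if (T > 1) movecnt / (T - 1) else
                rep(NA_real_, n),
              occasions = occasions, moves = moves,
              final_cells = pos)
  if (record) {
    out$positions <- pos_rec
    out$neighbour_sizes <- nbr_rec
    out$moved <- mov_rec
  }
  out
}

# cell index of each agent id 1..n (0-based row-major cells)
agent_cells <- function(lat, n) {
  ag <- lattice_agents(lat)
  stopifnot(nrow(ag) == n)
  cells <- integer(n)
  cells[ag$id] <- cell_index(lat, ag$x, ag$y)
  cells
}

r_run_evolution <- function(config, weights0, archive_gens) {
  G <- config$generations
  n <- nrow(weights0)
  wmax <- window_max(config$radius)
  W <- weights0
  stats <- matrix(NA_real_, G, 4)
  occ_cnt <- matrix(NA_real_, G, wmax + 1)
  mov_cnt <- matrix(NA_real_, G, wmax + 1)
  kkill <- round(config$kill_fraction * n)
  killed_rec <- matrix(NA_integer_, G, max(kkill, 1))
  archives <- list()
  for (g in seq_len(G) - 1L) {
    if (g %in% archive_gens) archives[[as.character(g)]] <- W
    gen <- r_run_generation(W, config)
    stats[g + 1, 1] <- mean(gen$neighbourhood_score)
    stats[g + 1, 2] <- var(gen$neighbourhood_score)
    stats[g + 1, 3] <- mean(gen$mobility_score)
    stats[g + 1, 4] <- var(gen$mobility_score)
    occ_cnt[g + 1, ] <- gen$occasions
    mov_cnt[g + 1, ] <- gen$moves
    sel <- select_and_reproduce(W, gen$neighbourhood_score,
                                kill_fraction = config$kill_fraction,
                                mutation_sd = sqrt(config$mutation_variance))
    W <- sel$genotypes
    if (length(sel$killed)) killed_rec[g + 1, seq_along(sel$killed)] <- sel$killed
  }
  list(stats = stats, occasions = occ_cnt, moves = mov_cnt,
       archives = archives, final_weights = W, killed = killed_rec,
       window_max = wmax)
}
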