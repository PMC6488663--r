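# Independent brute-force oracles. Everything here is written from the model
# definition directly, without using package internals, so that package
# results can be checked against a second route.

# occupied-cell count in the wrapped Moore window of radius r around (x, y),
# given a data frame of occupant coordinates
oracle_count <- function(agents, width, height, x, y, r = 1) {
  s <- 0L
  for (dx in -r:r) {
    for (dy in -r:r) {
      if (dx == 0 && dy == 0) next
      xx <- ((x + dx) %% width + width) %% width
      yy <- ((y + dy) %% height + height) %% height
      s <- s + as.integer(any(agents$x == xx & agents$y == yy))
    }
  }
  s
}

# linear-network argmax via matrix product (ties not handled: callers use
# percepts with a unique maximum)
oracle_argmax <- function(weights44, percept) {
  w <- matrix(weights44, nrow = 11)
  out <- as.vector(t(w) %*% percept)
  c("north", "south", "east", "west")[which.max(out)]
}

oracle_likelihood <- function(a, b) 1 - sum(abs(a - b)) / 44

oracle_mobility <- function(cells) {
  ch <- 0L
  for (t in 2:length(cells)) ch <- ch + as.integer(cells[t] != cells[t - 1])
  ch / (length(cells) - 1)
}

# Straight-line re-simulation of one generation from fixed initial positions,
# consuming the documented RNG protocol. Plain vector code, no package
# functions. positions: data frame id, x, y; weights: n x 44.
oracle_generation <- function(weights, width, height, T, positions,
                              p_transit = 0, r = 1) {
  n <- nrow(weights)
  wmax <- (2 * r + 1)^2 - 1
  px <- integer(n); py <- integer(n)
  px[positions$id] <- positions$x
  py[positions$id] <- positions$y
  occ_at <- function(x, y) any(px == x & py == y)
  who_at <- function(x, y) which(px == x & py == y)[1]
  cnt <- function(x, y) {
    s <- 0L
    for (dx in -r:r) for (dy in -r:r) {
      if (dx == 0 && dy == 0) next
      s <- s + as.integer(occ_at((x + dx) %% width, (y + dy) %% height))
    }
    s
  }
  dirs <- list(north = c(0L, -1L), south = c(0L, 1L),
               east = c(1L, 0L), west = c(-1L, 0L))
  pos_rec <- matrix(NA_integer_, n, T)  # cell idx y*width+x
  nbr_rec <- matrix(NA_integer_, n, T)
  for (t in seq_len(T)) {
    perm <- seq_len(n)
    if (n > 1) {
      for (k in n:2) {
        j <- min(floor(runif(1) * k), k - 1) + 1L
        tmp <- perm[k]; perm[k] <- perm[j]; perm[j] <- tmp
      }
    }
    for (i in perm) {
      x <- px[i]; y <- py[i]
      inp <- numeric(11)
      adj <- lapply(dirs, function(d) c((x + d[1]) %% width,
                                        (y + d[2]) %% height))
      for (d in 1:4) inp[d] <- as.numeric(occ_at(adj[[d]][1], adj[[d]][2]))
      for (d in 1:4) inp[4 + d] <- cnt(adj[[d]][1], adj[[d]][2]) / wmax
      inp[9] <- cnt(x, y) / wmax
      inp[10] <- runif(1)
      inp[11] <- 1
      out <- numeric(4)
      for (o in 1:4) {
        s <- 0
        for (ii in 1:11) s <- s + weights[i, ii + 11 * (o - 1)] * inp[ii]
        out[o] <- s
      }
      ties <- which(out == max(out))
      pick <- if (length(ties) > 1) {
        ties[min(floor(runif(1) * length(ties)), length(ties) - 1) + 1L]
      } else ties
      tx <- adj[[pick]][1]; ty <- adj[[pick]][2]
      if (!occ_at(tx, ty)) {
        px[i] <- tx; py[i] <- ty
      } else if (p_transit > 0 && runif(1) < p_transit) {
        j <- who_at(tx, ty)
        px[j] <- x; py[j] <- y
        px[i] <- tx; py[i] <- ty
      }
    }
    for (i in seq_len(n)) {
      pos_rec[i, t] <- as.integer(py[i] * width + px[i])
      nbr_rec[i, t] <- as.integer(cnt(px[i], py[i]))
    }
  }
  list(positions = pos_rec, neighbour_sizes = nbr_rec)
}

# all permutations of 1..n as rows of a matrix
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# small random lattice for property tests
random_lattice <- function(width, height, n) {
  cells <- sample(width * height, n) - 1L
  data.frame(id = seq_len(n), x = cells %% width, y = cells %/% width)
}

always_north_pop <- function(n) {
  w <- matrix(0, n, 44)
  w[, match("bias->north", crowdherd:::weight_names())] <- 1
  colnames(w) <- crowdherd:::weight_names()
  w
}
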