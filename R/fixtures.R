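#' Deterministic test fixtures
#'
#' Writes small hand-built lattices and hand-set genotypes used by the test
#' suite and for demonstrations. Known names:
#'
#' * `"always_north"`: a single genotype whose only nonzero weight is
#'   bias -> north, plus a 6 x 6 lattice with one agent.
#' * `"all_zero"`: the all-zero tie genotype (uniform random direction).
#' * `"block_2x2"`: four "always north" agents in a 2 x 2 block on an 8 x 8
#'   lattice.
#' * `"full_lattice"`: a 3 x 3 torus with all 9 cells occupied (every agent
#'   permanently enclosed: neighbourhood size 8, blocked under full
#'   blocking).
#' * `"neigh_5x5"`: a 5 x 5 lattice with a documented occupancy pattern and
#'   a CSV of brute-force neighbourhood counts for every cell.
#'
#' @param name Fixture name.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of written file paths.
#' @export
make_fixture <- function(name, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  north <- matrix(0, 1, 44)
  north[1, match("bias->north", weight_names())] <- 1
  colnames(north) <- weight_names()
  files <- switch(
    name,
    always_north = {
      lat <- herd_lattice(6, 6, data.frame(id = 1, x = 2, y = 3))
      list(lattice = write_lattice_json(lat, p("always_north_lattice.json")),
           genotypes = write_genotype_archive(
             north, p("always_north_genotypes.json")))
    },
    all_zero = {
      g <- matrix(0, 1, 44)
      colnames(g) <- weight_names()
      list(genotypes = write_genotype_archive(g, p("all_zero_genotypes.json")))
    },
    block_2x2 = {
      lat <- herd_lattice(8, 8, data.frame(id = 1:4, x = c(3, 4, 3, 4),
                                           y = c(3, 3, 4, 4)))
      g <- north[rep(1, 4), , drop = FALSE]
      list(lattice = write_lattice_json(lat, p("block_2x2_lattice.json")),
           genotypes = write_genotype_archive(g, p("block_2x2_genotypes.json")))
    },
    full_lattice = {
      xy <- expand.grid(x = 0:2, y = 0:2)
      lat <- herd_lattice(3, 3, data.frame(id = seq_len(9), x = xy$x,
                                           y = xy$y))
      g <- north[rep(1, 9), , drop = FALSE]
      list(lattice = write_lattice_json(lat, p("full_lattice.json")),
           genotypes = write_genotype_archive(g, p("full_lattice_genotypes.json")))
    },
    neigh_5x5 = {
      occ <- data.frame(id = 1:7,
                        x = c(0L, 1L, 2L, 2L, 3L, 4L, 0L),
                        y = c(0L, 0L, 1L, 2L, 3L, 4L, 3L))
      lat <- herd_lattice(5, 5, occ)
      grid <- expand.grid(x = 0:4, y = 0:4)
      # independent brute-force recount over the wrapped 3 x 3 window
      cnt <- integer(nrow(grid))
      for (i in seq_len(nrow(grid))) {
        s <- 0L
        for (dx in -1:1) for (dy in -1:1) {
          if (dx == 0 && dy == 0) next
          xx <- (grid$x[i] + dx) %% 5
          yy <- (grid$y[i] + dy) %% 5
          s <- s + any(occ$x == xx & occ$y == yy)
        }
        cnt[i] <- s
      }
      counts <- data.frame(x = grid$x, y = grid$y, count = cnt)
      f <- p("neigh_5x5_counts.csv")
      utils::write.csv(counts, f, row.names = FALSE)
      list(lattice = write_lattice_json(lat, p("neigh_5x5_lattice.json")),
           counts = f)
    },
    stop("unknown fixture name: ", name, call. = FALSE)
  )
  invisible(files)
}
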