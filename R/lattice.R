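#' Torus occupancy lattice
#'
#' A `herd_lattice` is a wrapped-around grid in which every cell is either
#' vacant or holds exactly one agent. Coordinates are 0-based with `x` the
#' column (0..width-1, east increases x) and `y` the row (0..height-1, north
#' decreases y); both axes wrap.
#'
#' @param width,height Lattice dimensions in cells.
#' @param agents Optional data frame with columns `id`, `x`, `y` of initial
#'   occupants (distinct cells, distinct ids).
#' @return An object of class `herd_lattice`.
#' @examples
#' lat <- herd_lattice(5, 5, data.frame(id = 1:2, x = c(1, 2), y = c(2, 2)))
#' lattice_agents(lat)
#' @export
herd_lattice <- function(width, height, agents = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 1, height >= 1)
  occ <- matrix(NA_integer_, nrow = height, ncol = width)
  lat <- structure(list(width = width, height = height, occ = occ),
                   class = "herd_lattice")
  if (!is.null(agents)) {
    stopifnot(all(c("id", "x", "y") %in% names(agents)))
    if (anyDuplicated(agents$id)) stop("duplicate agent ids", call. = FALSE)
    for (i in seq_len(nrow(agents))) {
      lat <- lattice_place(lat, agents$id[i], agents$x[i], agents$y[i])
    }
  }
  lat
}

# place a single agent; errors if the cell is occupied
lattice_place <- function(lat, id, x, y) {
  check_cell(lat, x, y)
  if (!is.na(lat$occ[y + 1L, x + 1L])) {
    stop("cell (", x, ",", y, ") already occupied", call. = FALSE)
  }
  lat$occ[y + 1L, x + 1L] <- as.integer(id)
  lat
}

check_cell <- function(lat, x, y) {
  if (any(x != floor(x)) || any(y != floor(y)) ||
      any(x < 0) || any(x >= lat$width) || any(y < 0) || any(y >= lat$height)) {
    stop("invalid cell coordinate: x must be in 0..width-1, y in 0..height-1",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.herd_lattice <- function(x, ...) {
  cat(sprintf("<herd_lattice> %d x %d torus, %d/%d cells occupied\n",
              x$width, x$height, sum(!is.na(x$occ)), x$width * x$height))
  invisible(x)
}

#' Agents currently on a lattice
#'
#' @param lattice A `herd_lattice`.
#' @return A tibble with columns `id`, `x`, `y`, ordered by `id`.
#' @export
lattice_agents <- function(lattice) {
  idx <- which(!is.na(lattice$occ))
  if (!length(idx)) {
    return(tibble::tibble(id = integer(), x = integer(), y = integer()))
  }
  rc <- arrayInd(idx, dim(lattice$occ))
  out <- tibble::tibble(id = lattice$occ[idx],
                        x = as.integer(rc[, 2] - 1L),
                        y = as.integer(rc[, 1] - 1L))
  out[order(out$id), ]
}

# cell index <-> coordinates (0-based, row-major: idx = y * width + x)
cell_index <- function(lat, x, y) as.integer(y) * lat$width + as.integer(x)
cell_xy <- function(lat, idx) {
  list(x = as.integer(idx %% lat$width), y = as.integer(idx %/% lat$width))
}

wrap_x <- function(lat, x) ((x %% lat$width) + lat$width) %% lat$width
wrap_y <- function(lat, y) ((y %% lat$height) + lat$height) %% lat$height

is_occupied <- function(lat, x, y) !is.na(lat$occ[y + 1L, x + 1L])

#' Moore-neighbourhood size of lattice cells
#'
#' Counts the occupied cells in the Moore window of radius `r` around each
#' given cell, excluding the cell itself; torus wrapping applies. This is the
#' local "neighbourhood size" an agent perceives and the per-step summand of
#' its neighbourhood score.
#'
#' @param lattice A `herd_lattice`.
#' @param x,y Cell coordinates (0-based, vectorised).
#' @param r Moore radius (>= 1).
#' @return Integer vector of counts in `0..(2r+1)^2-1`.
#' @examples
#' lat <- herd_lattice(5, 5, data.frame(id = 1:3, x = c(1, 2, 4), y = c(1, 2, 4)))
#' neighbourhood_size(lat, 2, 2)
#' @export
neighbourhood_size <- function(lattice, x, y, r = 1L) {
  stopifnot(inherits(lattice, "herd_lattice"))
  if (r < 1) stop("r must be >= 1", call. = FALSE)
  check_cell(lattice, x, y)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  vapply(seq_along(x), function(i) {
    xx <- wrap_x(lattice, x[i] + offs$dx)
    yy <- wrap_y(lattice, y[i] + offs$dy)
    sum(!is.na(lattice$occ[cbind(yy + 1L, xx + 1L)]))
  }, integer(1))
}

#' Place agents uniformly at random without overlap
#'
#' Draws `n` distinct cells by rejection sampling from the current RNG
#' stream (the documented placement protocol shared with the compiled
#' engine) and places agents with ids `1..n`.
#'
#' @param lattice An (empty or partially filled) `herd_lattice`.
#' @param n Number of agents; together with existing occupants at most
#'   `width * height`.
#' @return The updated lattice; retrieve positions with [lattice_agents()].
#' @examples
#' set.seed(1)
#' lat <- place_agents(herd_lattice(10, 10), 5)
#' nrow(lattice_agents(lat))
#' @export
place_agents <- function(lattice, n) {
  stopifnot(inherits(lattice, "herd_lattice"))
  n <- as.integer(n)
  free <- sum(is.na(lattice$occ))
  if (n > free) stop("capacity error: ", n, " agents but only ", free,
                     " vacant cells", call. = FALSE)
  ncell <- lattice$width * lattice$height
  for (i in seq_len(n)) {
    repeat {
      c0 <- min(floor(runif(1) * ncell), ncell - 1)
      xy <- cell_xy(lattice, c0)
      if (!is_occupied(lattice, xy$x, xy$y)) {
        lattice <- lattice_place(lattice, i, xy$x, xy$y)
        break
      }
    }
  }
  lattice
}

#' Cardinal directions and their lattice offsets
#'
#' The four movement targets of an agent, in the fixed N, S, E, W convention
#' used everywhere in the package: north is `y - 1`, south `y + 1`, east
#' `x + 1`, west `x - 1` (torus wrapped).
#'
#' @return A tibble with columns `direction`, `dx`, `dy`.
#' @export
directions <- function() {
  tibble::tibble(direction = c("north", "south", "east", "west"),
                 dx = c(0L, 0L, 1L, -1L),
                 dy = c(-1L, 1L, 0L, 0L))
}

direction_offset <- function(dir) {
  d <- directions()
  i <- match(dir, d$direction)
  if (is.na(i)) stop("invalid direction: ", dir, call. = FALSE)
  list(dx = d$dx[i], dy = d$dy[i])
}

#' Attempt a crowding-constrained move
#'
#' Moves agent `id` one cell in `dir`. A vacant target always succeeds
#' (`"moved"`). An occupied target blocks the move (`"blocked"`) unless a
#' uniform draw falls below `p_transit`, in which case the two agents swap
#' cells atomically (`"swapped"`). The squeeze-through draw is taken from the
#' current RNG stream only when the target is occupied and `p_transit > 0`.
#'
#' @param lattice A `herd_lattice`.
#' @param id Agent id present on the lattice.
#' @param dir One of `"north"`, `"south"`, `"east"`, `"west"`.
#' @param p_transit Squeeze-through probability in `[0, 1]`.
#' @return A list with elements `lattice` (updated) and `outcome`
#'   (`"moved"`, `"blocked"` or `"swapped"`).
#' @export
attempt_move <- function(lattice, id, dir, p_transit = 0) {
  stopifnot(inherits(lattice, "herd_lattice"))
  if (p_transit < 0 || p_transit > 1) stop("p_transit must be in [0, 1]",
                                           call. = FALSE)
  pos <- which(lattice$occ == id, arr.ind = TRUE)
  if (nrow(pos) != 1) stop("agent ", id, " is not on the lattice",
                           call. = FALSE)
  x <- pos[1, 2] - 1L; y <- pos[1, 1] - 1L
  off <- direction_offset(dir)
  tx <- wrap_x(lattice, x + off$dx); ty <- wrap_y(lattice, y + off$dy)
  if (!is_occupied(lattice, tx, ty)) {
    lattice$occ[y + 1L, x + 1L] <- NA_integer_
    lattice$occ[ty + 1L, tx + 1L] <- as.integer(id)
    return(list(lattice = lattice, outcome = "moved"))
  }
  if (p_transit > 0 && runif(1) < p_transit) {
    other <- lattice$occ[ty + 1L, tx + 1L]
    lattice$occ[ty + 1L, tx + 1L] <- as.integer(id)
    lattice$occ[y + 1L, x + 1L] <- other
    return(list(lattice = lattice, outcome = "swapped"))
  }
  list(lattice = lattice, outcome = "blocked")
}

#' One asynchronous time step of the movement dynamics
#'
#' Every agent acts exactly once, in a fresh uniform random permutation
#' (drawn by Fisher-Yates from the current RNG stream unless `order` is
#' supplied); each decision reads the lattice state current at the agent's
#' turn. This is the transparent reference implementation of the engine's
#' inner loop; [run_generation()] with `engine = "cpp"` executes the same
#' rule and RNG protocol in compiled code.
#'
#' @param lattice A `herd_lattice` whose occupant ids index rows of
#'   `genotypes`.
#' @param genotypes Numeric matrix with 44 columns, one row per agent id.
#' @param p_transit Squeeze-through probability.
#' @param r Moore radius used for perception.
#' @param order Optional explicit id ordering (a permutation of the ids on
#'   the lattice); when `NULL` a random permutation is drawn.
#' @return A list with elements `lattice` (updated), `moved` (named logical
#'   per id: did the agent's cell change this step) and `order`.
#' @export
lattice_step <- function(lattice, genotypes, p_transit = 0, r = 1L,
                         order = NULL) {
  stopifnot(inherits(lattice, "herd_lattice"))
  ag <- lattice_agents(lattice)
  n <- nrow(ag)
  ids <- ag$id
  if (is.null(order)) {
    order <- ids[rng_permutation(n)]
  } else {
    stopifnot(setequal(order, ids))
  }
  before <- lattice$occ
  for (id in order) {
    pos <- which(lattice$occ == id, arr.ind = TRUE)
    x <- pos[1, 2] - 1L; y <- pos[1, 1] - 1L
    p <- build_percept(lattice, x, y, r = r)
    g <- genotypes[id, , drop = TRUE]
    dir <- decide_direction(g, p)
    lattice <- attempt_move(lattice, id, dir, p_transit)$lattice
  }
  moved <- vapply(ids, function(id) {
    !identical(which(before == id), which(lattice$occ == id))
  }, logical(1))
  names(moved) <- ids
  list(lattice = lattice, moved = moved, order = order)
}

# Fisher-Yates permutation consuming runif draws in the engine's order
rng_permutation <- function(n) {
  perm <- seq_len(n)
  if (n > 1) {
    for (k in n:2) {
      j <- min(floor(runif(1) * k), k - 1) + 1L
      tmp <- perm[k]; perm[k] <- perm[j]; perm[j] <- tmp
    }
  }
  perm
}

#' Lattice JSON round-trip
#'
#' Serialises a lattice as a JSON document with `width`, `height` and an
#' `agents` array of `{id, x, y}` records (0-based coordinates); used for
#' fixtures and run resumption.
#'
#' @param lattice A `herd_lattice`.
#' @param path File path.
#' @return `read_lattice_json()` returns a `herd_lattice`;
#'   `write_lattice_json()` returns `path` invisibly.
#' @export
write_lattice_json <- function(lattice, path) {
  stopifnot(inherits(lattice, "herd_lattice"))
  ag <- lattice_agents(lattice)
  obj <- list(width = lattice$width, height = lattice$height,
              agents = ag)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_lattice_json
#' @export
read_lattice_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ag <- obj$agents
  if (is.null(ag) || !length(ag)) ag <- NULL
  herd_lattice(obj$width, obj$height, agents = ag)
}
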