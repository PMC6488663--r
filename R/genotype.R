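#' @rdname build_percept
#' @export
percept_names <- function() {
  c("occ_n", "occ_s", "occ_e", "occ_w",
    "nbr_n", "nbr_s", "nbr_e", "nbr_w",
    "nbr_here", "noise", "bias")
}

direction_names <- function() c("north", "south", "east", "west")

# names of the 44 weights in the canonical (input within output) order
weight_names <- function() {
  as.vector(outer(percept_names(), direction_names(),
                  function(i, o) paste(i, o, sep = "->")))
}

#' Coerce to an 11 x 4 genotype weight table
#'
#' A genotype is a fully connected two-layer linear network: 11 input nodes
#' (occupancy of the four adjacent cells in N,S,E,W order; their
#' neighbourhood sizes divided by the window maximum; the focal cell's
#' normalised neighbourhood size; a uniform noise node; a constant bias of
#' 1) feeding 4 output nodes, one per cardinal direction. Weights are stored
#' either as an 11 x 4 matrix `w[input, output]` or flattened to 44 values
#' in column-major (input-within-output) order.
#'
#' @param g An 11 x 4 matrix, a length-44 vector, or one row of a
#'   population weight matrix.
#' @return An 11 x 4 named numeric matrix.
#' @examples
#' g <- as_genotype(rep(0, 44))
#' g["bias", "north"] <- 1   # an "always north" walker
#' @export
as_genotype <- function(g) {
  if (is.matrix(g) && all(dim(g) == c(11, 4))) {
    w <- g
  } else if (length(g) == 44) {
    w <- matrix(as.numeric(g), nrow = 11, ncol = 4)
  } else {
    stop("genotype must be 11 x 4 or length 44 (got ",
         paste(dim(g) %||% length(g), collapse = " x "), ")", call. = FALSE)
  }
  dimnames(w) <- list(percept_names(), direction_names())
  storage.mode(w) <- "double"
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flatten_genotype <- function(g) as.vector(as_genotype(g))

#' Random initial genotypes
#'
#' Draws all 44 weights of each genotype independently and uniformly from
#' `[-range, range]` (the initial-weight distribution of the first
#' generation), consuming `n * 44` uniform draws from the current RNG stream
#' in column-major order of the returned matrix.
#'
#' @param n Number of genotypes.
#' @param range Half-width of the uniform support.
#' @return An `n` x 44 matrix; row i is agent i's flattened genotype
#'   (columns named by [as_genotype()] order).
#' @examples
#' set.seed(1)
#' pop <- random_genotypes(5)
#' dim(pop)
#' @export
random_genotypes <- function(n, range = 1) {
  w <- matrix(runif(n * 44, -range, range), nrow = n)
  colnames(w) <- weight_names()
  w
}

#' Build the 11-entry percept of a lattice cell
#'
#' Assembles the network inputs an agent at `(x, y)` perceives: occupancy
#' states (0/1) of the four adjacent cells in N,S,E,W order, the
#' neighbourhood sizes of those cells and of the focal cell divided by the
#' window maximum `(2r+1)^2 - 1`, a uniform noise value and the bias 1. The
#' noise entry consumes one uniform draw unless supplied via `noise`.
#' Note the querying agent itself is counted by the windows of its adjacent
#' cells: it occupies a real cell.
#'
#' @param lattice A `herd_lattice`.
#' @param x,y Focal cell (0-based).
#' @param r Moore radius.
#' @param noise Optional fixed value for the noise node (for deterministic
#'   analysis); by default drawn from the current RNG stream.
#' @return Named numeric vector of length 11.
#' @export
build_percept <- function(lattice, x, y, r = 1L, noise = NULL) {
  stopifnot(inherits(lattice, "herd_lattice"))
  check_cell(lattice, x, y)
  d <- directions()
  ax <- wrap_x(lattice, x + d$dx)
  ay <- wrap_y(lattice, y + d$dy)
  wmax <- window_max(r)
  p <- numeric(11)
  p[1:4] <- as.numeric(!is.na(lattice$occ[cbind(ay + 1L, ax + 1L)]))
  p[5:8] <- neighbourhood_size(lattice, ax, ay, r) / wmax
  p[9] <- neighbourhood_size(lattice, x, y, r) / wmax
  p[10] <- if (is.null(noise)) runif(1) else noise
  p[11] <- 1
  names(p) <- percept_names()
  p
}

#' Choose a movement direction from a genotype and percept
#'
#' Computes the four output values as weighted sums of the 11 inputs (linear
#' activation) and returns the direction of the maximum output; exact ties
#' are broken uniformly at random (one uniform draw, taken only when a tie
#' occurs). Accumulation is sequential over inputs so the compiled engine
#' produces bit-identical outputs.
#'
#' @param genotype Anything [as_genotype()] accepts.
#' @param percept Length-11 numeric percept (see [build_percept()]).
#' @return One of `"north"`, `"south"`, `"east"`, `"west"`.
#' @examples
#' g <- as_genotype(rep(0, 44)); g["bias", "east"] <- 1
#' decide_direction(g, build_percept(herd_lattice(3, 3,
#'   data.frame(id = 1, x = 1, y = 1)), 1, 1, noise = 0.5))
#' @export
decide_direction <- function(genotype, percept) {
  w <- as_genotype(genotype)
  if (length(percept) != 11) stop("percept must have 11 entries",
                                  call. = FALSE)
  out <- numeric(4)
  for (o in 1:4) {
    s <- 0
    for (i in 1:11) s <- s + w[i, o] * percept[[i]]
    out[o] <- s
  }
  if (!all(is.finite(out))) stop("corrupt genotype: non-finite network output",
                                 call. = FALSE)
  best <- max(out)
  ties <- which(out == best)
  pick <- if (length(ties) > 1) {
    ties[min(floor(runif(1) * length(ties)), length(ties) - 1) + 1L]
  } else {
    ties
  }
  direction_names()[pick]
}

#' Uniform crossover with Gaussian mutation
#'
#' Produces one offspring genotype: each of the 44 weights is copied from
#' `parent_a` or `parent_b` with probability 1/2 and then perturbed by an
#' independent Gaussian draw of standard deviation `mutation_sd` (the study
#' default is variance 5e-4, sd `sqrt(5e-4)`). Draws are interleaved per
#' weight (one uniform, one normal) in canonical weight order - the exact
#' protocol of the compiled engine's reproduction step; the normal draw is
#' consumed even when `mutation_sd = 0`.
#'
#' @param parent_a,parent_b Parent genotypes (any form [as_genotype()]
#'   accepts).
#' @param mutation_sd Mutation standard deviation (>= 0).
#' @return An 11 x 4 genotype matrix.
#' @examples
#' set.seed(1)
#' kid <- crossover_mutate(random_genotypes(1), random_genotypes(1))
#' @export
crossover_mutate <- function(parent_a, parent_b, mutation_sd = sqrt(5e-4)) {
  a <- flatten_genotype(parent_a)
  b <- flatten_genotype(parent_b)
  stopifnot(mutation_sd >= 0)
  off <- numeric(44)
  for (k in 1:44) {
    v <- if (runif(1) < 0.5) a[k] else b[k]
    off[k] <- v + rnorm(1) * mutation_sd
  }
  as_genotype(off)
}

#' Genotype archive JSON round-trip
#'
#' Writes a population weight matrix as JSON: the generation index, the
#' input/output node names documenting weight order, and one record per
#' agent with its id and 44 weights (column-major, input within output).
#' Numbers are serialised at full precision so the round-trip is bit-exact.
#'
#' @param weights An `n` x 44 population matrix (rows = agent ids 1..n).
#' @param path File path.
#' @param generation Generation index stored alongside (default `NA`).
#' @return `read_genotype_archive()` returns a list with `generation` and
#'   `weights`; `write_genotype_archive()` returns `path` invisibly.
#' @export
write_genotype_archive <- function(weights, path, generation = NA) {
  stopifnot(is.matrix(weights), ncol(weights) == 44)
  agents <- lapply(seq_len(nrow(weights)), function(i) {
    list(id = i, weights = as.numeric(weights[i, ]))
  })
  obj <- list(generation = generation,
              inputs = percept_names(), outputs = direction_names(),
              weight_order = "input-within-output (column-major of 11 x 4)",
              agents = agents)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_genotype_archive
#' @export
read_genotype_archive <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- length(obj$agents)
  w <- matrix(NA_real_, nrow = n, ncol = 44)
  for (a in obj$agents) {
    w[a$id, ] <- unlist(a$weights)
  }
  colnames(w) <- weight_names()
  gen <- obj$generation
  list(generation = if (is.null(gen)) NA else gen, weights = w)
}
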