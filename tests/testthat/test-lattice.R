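test_that("neighbourhood_size counts occupied Moore cells with wrapping", {
  # all 8 Moore cells occupied -> 8
  ring <- expand.grid(x = 1:3, y = 1:3)
  ring <- ring[!(ring$x == 2 & ring$y == 2), ]
  lat <- herd_lattice(6, 6, data.frame(id = 1:8, x = ring$x, y = ring$y))
  expect_identical(neighbourhood_size(lat, 2, 2), 8L)
  # empty window -> 0
  expect_identical(neighbourhood_size(herd_lattice(6, 6), 3, 3), 0L)
  # 3 agents inside the r=1 window, 2 outside -> 3
  lat2 <- herd_lattice(7, 7, data.frame(id = 1:5,
                                        x = c(2, 3, 4, 0, 6),
                                        y = c(2, 3, 2, 0, 6)))
  expect_identical(neighbourhood_size(lat2, 3, 2), 3L)
  # wrapping: occupants across the seam are neighbours of (0, 0)
  lat3 <- herd_lattice(5, 5, data.frame(id = 1:2, x = c(4, 0), y = c(4, 1)))
  expect_identical(neighbourhood_size(lat3, 0, 0), 2L)
})

test_that("neighbourhood_size rejects invalid input", {
  lat <- herd_lattice(5, 5)
  expect_error(neighbourhood_size(lat, 5, 0), "invalid cell")
  expect_error(neighbourhood_size(lat, -1, 0), "invalid cell")
  expect_error(neighbourhood_size(lat, 1, 1, r = 0), "r must be")
})

test_that("neighbourhood_size agrees with a brute-force window count", {
  set.seed(401)
  for (rep in 1:250) {
    w <- sample(9:14, 1); h <- sample(9:14, 1)
    r <- sample(1:4, 1)
    n <- sample(1:20, 1)
    ag <- random_lattice(w, h, n)
    lat <- herd_lattice(w, h, ag)
    for (q in 1:4) {
      x <- sample(0:(w - 1), 1); y <- sample(0:(h - 1), 1)
      expect_identical(neighbourhood_size(lat, x, y, r),
                       oracle_count(ag, w, h, x, y, r))
    }
  }
})

test_that("place_agents fills distinct cells and respects capacity", {
  set.seed(1)
  lat <- place_agents(herd_lattice(4, 4), 16)  # pigeonhole: every cell
  expect_false(anyNA(lat$occ))
  set.seed(2)
  lat2 <- place_agents(herd_lattice(120, 120), 200)
  ag <- lattice_agents(lat2)
  expect_identical(nrow(ag), 200L)
  expect_identical(anyDuplicated(paste(ag$x, ag$y)), 0L)
  lat3 <- place_agents(herd_lattice(5, 5), 0)
  expect_identical(nrow(lattice_agents(lat3)), 0L)
  expect_error(place_agents(herd_lattice(3, 3), 10), "capacity")
})

test_that("attempt_move honours vacancy, blocking and swapping", {
  lat <- herd_lattice(5, 5, data.frame(id = 1:2, x = c(1, 1), y = c(1, 0)))
  # vacant target
  res <- attempt_move(lat, 1, "east", p_transit = 0)
  expect_identical(res$outcome, "moved")
  expect_identical(lattice_agents(res$lattice)$x[1], 2L)
  # occupied target, full blocking
  res2 <- attempt_move(lat, 1, "north", p_transit = 0)
  expect_identical(res2$outcome, "blocked")
  expect_identical(res2$lattice$occ, lat$occ)
  # occupied target, unhindered transit: atomic swap
  res3 <- attempt_move(lat, 1, "north", p_transit = 1)
  expect_identical(res3$outcome, "swapped")
  ag3 <- lattice_agents(res3$lattice)
  expect_identical(ag3$y, c(0L, 1L))
  expect_identical(nrow(ag3), 2L)
  expect_error(attempt_move(lat, 1, "north", p_transit = 2), "p_transit")
  expect_error(attempt_move(lat, 1, "up"), "invalid direction")
})

test_that("torus wrapping moves agents across the seam", {
  lat <- herd_lattice(4, 4, data.frame(id = 1, x = 0, y = 0))
  res <- attempt_move(lat, 1, "north")
  expect_identical(lattice_agents(res$lattice)$y, 3L)
  res2 <- attempt_move(res$lattice, 1, "west")
  expect_identical(lattice_agents(res2$lattice)$x, 3L)
})

test_that("a lone agent always relocates; an enclosed agent never does", {
  set.seed(11)
  lat <- herd_lattice(6, 6, data.frame(id = 1, x = 3, y = 3))
  st <- lattice_step(lat, random_genotypes(1))
  expect_true(st$moved[["1"]])
  # centre agent enclosed by its four adjacent cells, full blocking
  plus <- data.frame(id = 1:5, x = c(2, 2, 2, 1, 3), y = c(2, 1, 3, 2, 2))
  lat2 <- herd_lattice(6, 6, plus)
  for (rep in 1:20) {
    g <- random_genotypes(5)
    # outer agents point at the centre so they stay blocked too
    res <- attempt_move(lat2, 1, decide_direction(g[1, ],
      build_percept(lat2, 2, 2)), p_transit = 0)
    expect_identical(res$outcome, "blocked")
  }
})

test_that("2x2 always-north block evolves consistently with some agent order", {
  # brute-force oracle: enumerate all 4! orders of sequential always-north
  # moves and collect every reachable occupancy set
  block <- data.frame(id = 1:4, x = c(3, 4, 3, 4), y = c(3, 3, 4, 4))
  w <- 8L; h <- 8L
  outcomes <- list()
  for (perm in asplit(gtools_permutations(4), 1)) {
    px <- block$x; py <- block$y
    for (i in perm) {
      ty <- (py[i] - 1) %% h
      if (!any(px == px[i] & py == ty)) py[i] <- ty
    }
    outcomes[[length(outcomes) + 1]] <- sort(paste(px, py))
  }
  outcomes <- unique(outcomes)
  set.seed(77)
  for (rep in 1:10) {
    st <- lattice_step(herd_lattice(w, h, block), always_north_pop(4))
    ag <- lattice_agents(st$lattice)
    expect_identical(nrow(ag), 4L)  # occupancy conserved
    expect_true(list(sort(paste(ag$x, ag$y))) %in% outcomes)
  }
})

test_that("occupancy count and exclusion hold over many random steps", {
  # conservation suite: ~1e5 agent-steps across p_transit 0 / 0.5 / 1
  cfg0 <- herd_config(width = 20, height = 20, n_agents = 120, steps = 280,
                      generations = 1)
  for (p in c(0, 0.5, 1)) {
    cfg <- cfg0; cfg$p_transit <- p
    set.seed(500 + p * 10)
    gen <- run_generation(random_genotypes(120), cfg, record = TRUE)
    expect_identical(dim(gen$positions), c(120L, 280L))
    dup <- apply(gen$positions, 2, anyDuplicated)
    expect_true(all(dup == 0L))  # no two agents ever share a cell
    expect_identical(nrow(lattice_agents(gen$final_lattice)), 120L)
  }
})

test_that("blocked-move frequency does not increase with p_transit", {
  freqs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    cfg <- herd_config(width = 12, height = 12, n_agents = 90, steps = 150,
                       generations = 1, p_transit = p)
    set.seed(600)
    g <- random_genotypes(90)
    gen <- run_generation(g, cfg)
    1 - mean(gen$agents$mobility_score)  # stay frequency
  }, numeric(1))
  expect_true(all(diff(freqs) <= 0.03))
})

test_that("dynamics are equivariant under torus translation", {
  set.seed(31)
  g <- random_genotypes(6)
  base <- data.frame(id = 1:6, x = c(1, 2, 3, 5, 0, 4), y = c(1, 1, 2, 5, 3, 0))
  cfg <- herd_config(width = 7, height = 7, n_agents = 6, steps = 10,
                     generations = 1)
  set.seed(99)
  a <- run_generation(g, cfg, record = TRUE, positions = base)
  shifted <- transform(base, x = (x + 3) %% 7, y = (y + 5) %% 7)
  set.seed(99)
  b <- run_generation(g, cfg, record = TRUE, positions = shifted)
  ax <- a$positions %% 7; ay <- a$positions %/% 7
  expect_identical((ax + 3) %% 7, b$positions %% 7)
  expect_identical((ay + 5) %% 7, b$positions %/% 7)
  expect_identical(a$agents, b$agents)
})

test_that("lattice JSON round-trips", {
  lat <- herd_lattice(9, 7, data.frame(id = c(3, 1, 2), x = c(0, 8, 4),
                                       y = c(6, 0, 3)))
  f <- withr::local_tempfile(fileext = ".json")
  write_lattice_json(lat, f)
  back <- read_lattice_json(f)
  expect_identical(back$width, 9L)
  expect_identical(back$height, 7L)
  expect_identical(lattice_agents(back), lattice_agents(lat))
  # empty lattice round-trips too
  f2 <- withr::local_tempfile(fileext = ".json")
  write_lattice_json(herd_lattice(4, 4), f2)
  expect_identical(nrow(lattice_agents(read_lattice_json(f2))), 0L)
})
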