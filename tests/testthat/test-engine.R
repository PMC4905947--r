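test_that("neighbor_count matches hand-enumerated cases", {
  blinker <- life_universe(life_fixture("blinker"))  # (0,0),(1,0),(2,0)
  expect_identical(neighbor_count(blinker, c(1, 0)), 2L)  # centre of the row
  expect_identical(neighbor_count(blinker, c(0, 0)), 1L)
  expect_identical(neighbor_count(blinker, c(1, 1)), 3L)  # birth site below
  expect_identical(neighbor_count(life_universe(), c(5, -3)), 0L)
  full <- life_universe(as.matrix(expand.grid(x = 0:2, y = 0:2)))
  expect_identical(neighbor_count(full, c(1, 1)), 8L)
})

test_that("neighbor_count wraps on the torus and rejects out-of-bounds cells", {
  u <- life_universe(cbind(c(0L, 4L), c(0L, 4L)), topology = "torus",
                     width = 5, height = 5)
  # (4,4) is diagonally adjacent to (0,0) across both seams
  expect_identical(neighbor_count(u, c(0, 0)), 1L)
  expect_error(neighbor_count(u, c(5, 0)), "outside the torus")
})

test_that("single-step updates match the canonical worked examples", {
  # horizontal blinker -> vertical: ends die, cells above/below centre born
  s <- life_step(life_universe(life_fixture("blinker")))
  expect_identical(s$universe$cells,
                   life_universe(cbind(1L, c(-1L, 0L, 1L)))$cells)
  expect_identical(nrow(s$births), 2L)
  expect_identical(nrow(s$deaths), 2L)

  # the 2x2 block is invariant
  block <- life_universe(life_fixture("block"))
  expect_identical(life_step(block)$universe$cells, block$cells)

  # a lone cell dies from isolation
  lone <- life_step(life_universe(matrix(c(0L, 0L), 1)))
  expect_identical(population(lone$universe), 0L)

  # the L-tromino binds into a block in one step
  lt <- life_step(life_universe(life_fixture("l_tromino")))
  expect_identical(canonical_hash(lt$universe),
                   canonical_hash(life_universe(life_fixture("block"))))
})

test_that("run returns n+1 states with the generation counter advancing by 1", {
  tr <- life_run(life_universe(life_fixture("blinker")), n_generations = 2)
  expect_length(tr, 3L)
  expect_identical(vapply(tr, function(u) u$generation, 0L), 0:2)
  expect_identical(tr[[3]]$cells, tr[[1]]$cells)  # period 2

  tr0 <- life_run(life_universe(life_fixture("glider")), n_generations = 0)
  expect_length(tr0, 1L)

  tr5 <- life_run(life_universe(matrix(c(0L, 0L), 1)), n_generations = 5)
  expect_true(all(vapply(tr5[-1], population, 0L) == 0L))
})

test_that("canonical hashes identify states up to the requested invariance", {
  b <- life_fixture("blinker")$cells
  shifted <- b
  shifted[, 1L] <- shifted[, 1L] + 5L
  shifted[, 2L] <- shifted[, 2L] + 7L
  expect_identical(canonical_hash(life_universe(b)),
                   canonical_hash(life_universe(shifted)))
  expect_false(canonical_hash(life_universe(b), translation_invariant = FALSE) ==
               canonical_hash(life_universe(shifted), translation_invariant = FALSE))
  vert <- cbind(0L, 0:2)
  expect_false(canonical_hash(life_universe(b)) ==
               canonical_hash(life_universe(vert)))
  expect_identical(canonical_hash(life_universe()), "<empty>")
})

test_that("the step commutes with translation on the infinite plane", {
  for (seed in 1:5) {
    cells <- random_soup_cells(10, 10, 0.4, seed)
    v <- c(seed * 3L - 7L, 11L - seed)
    stepped <- life_step(life_universe(cells))$universe$cells
    moved <- cells
    moved[, 1L] <- moved[, 1L] + v[1L]
    moved[, 2L] <- moved[, 2L] + v[2L]
    stepped_moved <- life_step(life_universe(moved))$universe$cells
    shifted_step <- stepped
    if (nrow(shifted_step)) {
      shifted_step[, 1L] <- shifted_step[, 1L] + v[1L]
      shifted_step[, 2L] <- shifted_step[, 2L] + v[2L]
    }
    expect_identical(cellset(stepped_moved), cellset(shifted_step))
  }
})

test_that("the step commutes with the 8 symmetries of the square grid", {
  cells <- random_soup_cells(9, 9, 0.4, 42)
  stepped <- life_step(life_universe(cells))$universe$cells
  for (nm in names(square_symmetries)) {
    tf <- square_symmetries[[nm]]
    stepped_tf <- life_step(life_universe(tf(cells)))$universe$cells
    expect_identical(cellset(stepped_tf), cellset(tf(stepped)), label = nm)
  }
})

test_that("population change equals births minus deaths on random soups", {
  for (seed in 1:10) {
    u <- life_universe(random_soup_cells(12, 12, 0.35, seed))
    for (g in 1:10) {
      s <- life_step(u)
      expect_identical(population(s$universe),
                       population(u) + nrow(s$births) - nrow(s$deaths))
      # births are new, deaths come from the previous live set
      expect_length(intersect(cellset(s$births), cellset(u$cells)), 0L)
      expect_true(all(cellset(s$deaths) %in% cellset(u$cells)))
      u <- s$universe
    }
  }
})

test_that("sparse engine agrees with the dense oracle on torus soups", {
  for (seed in 1:20) {
    cells <- random_soup_cells(16, 16, 0.35, seed)
    u <- life_universe(cells, topology = "torus", width = 16, height = 16)
    mat <- cells_to_dense(cells, 16, 16)
    for (g in 1:20) {
      u <- life_step(u)$universe
      mat <- dense_step(mat, wrap = TRUE)
      expect_identical(cellset(u$cells), cellset(dense_to_cells(mat)))
    }
  }
})

test_that("sparse engine agrees with a padded dense oracle on the infinite plane", {
  for (seed in 1:5) {
    cells <- random_soup_cells(12, 12, 0.4, seed)
    pad <- 30L  # activity cannot travel faster than one cell per generation
    u <- life_universe(cells)
    mat <- cells_to_dense(cells, 12L + 2L * pad, 12L + 2L * pad,
                          x0 = -pad, y0 = -pad)
    for (g in 1:25) {
      u <- life_step(u)$universe
      mat <- dense_step(mat, wrap = FALSE)
      expect_identical(cellset(u$cells),
                       cellset(dense_to_cells(mat, x0 = -pad, y0 = -pad)))
    }
  }
})

test_that("a glider on a torus wraps around and returns home", {
  u0 <- life_universe(life_fixture("glider")$cells, topology = "torus",
                      width = 8, height = 8)
  tr <- life_run(u0, n_generations = 32)  # (1,1) per 4 gens, mod 8
  expect_identical(cellset(tr[[33]]$cells), cellset(u0$cells))
})

test_that("non-default rules drive the update (Seeds-like and HighLife)", {
  # B2/S: every live cell dies, pairs breed
  seeds <- parse_rule("B2/S")
  s <- life_step(life_universe(cbind(0:1, 0L)), seeds)
  expect_identical(nrow(s$deaths), 2L)
  expect_true(nrow(s$births) > 0L)
  # B36/S23 equals B3/S23 wherever no 6-neighbour births occur
  b <- life_step(life_universe(life_fixture("blinker")), parse_rule("B36/S23"))
  expect_identical(cellset(b$universe$cells), cellset(cbind(1L, c(-1L, 0L, 1L))))
})
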