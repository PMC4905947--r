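test_that("bernoulli soups hit their density limits and reproduce bitwise", {
  expect_identical(population(make_soup(soup_spec(16, 16, density = 0, seed = 1))),
                   0L)
  full <- make_soup(soup_spec(7, 5, density = 1, seed = 1))
  expect_identical(population(full), 35L)
  a <- make_soup(soup_spec(16, 16, density = 0.35, seed = 7))
  b <- make_soup(soup_spec(16, 16, density = 0.35, seed = 7))
  expect_identical(a$cells, b$cells)
  c2 <- make_soup(soup_spec(16, 16, density = 0.35, seed = 8))
  expect_false(identical(a$cells, c2$cells))
  expect_error(soup_spec(16, 16, density = 1.2), "\\[0, 1\\]")
})

test_that("scribble soups are reproducible walks confined to the grid", {
  sp <- soup_spec(20, 20, mode = "scribble", strokes = 3, seed = 5)
  a <- make_soup(sp)
  expect_identical(a$cells, make_soup(sp)$cells)
  expect_true(population(a) > 0L)
  expect_true(all(a$cells[, 1L] >= 0L & a$cells[, 1L] < 20L))
  expect_true(all(a$cells[, 2L] >= 0L & a$cells[, 2L] < 20L))
})

test_that("soup generation leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_soup(soup_spec(8, 8, seed = 99)))
  expect_identical(.Random.seed, before)
})

test_that("free evolution records the blinker's metabolism", {
  series <- free_evolution(life_universe(life_fixture("blinker")),
                           n_generations = 4)
  expect_identical(series$population, rep(3L, 5))
  expect_identical(series$births[-1], rep(2L, 4))
  expect_identical(series$deaths[-1], rep(2L, 4))
  expect_identical(series$n_oscillator, rep(1L, 5))
})

test_that("free evolution of an empty universe is all zeros", {
  series <- free_evolution(life_universe(), n_generations = 3)
  expect_true(all(series$population == 0L))
  expect_true(all(series$n_objects == 0L))
})

test_that("the conservation identity holds along a soup's census series", {
  u <- make_soup(soup_spec(20, 20, density = 0.4, seed = 3))
  series <- free_evolution(u, n_generations = 30)
  expect_identical(series$population[-1],
                   head(series$population, -1) + series$births[-1] -
                     series$deaths[-1])
})

test_that("the reference 32x32 soup run reproduces its golden-master census", {
  u <- make_soup(soup_spec(32, 32, density = 0.35, seed = 42))
  series <- free_evolution(u, n_generations = 125)
  path <- withr::local_tempfile(fileext = ".csv")
  write_census_csv(series, path)
  expect_identical(readLines(path), readLines(test_path("fixtures", "soup32_census.csv")))
})

test_that("golden-master populations match an independent dense-engine run", {
  u <- make_soup(soup_spec(32, 32, density = 0.35, seed = 42))
  mat <- cells_to_dense(u$cells, 32, 32)
  fixture <- read.csv(test_path("fixtures", "soup32_census.csv"))
  pops <- integer(126)
  pops[1] <- sum(mat)
  for (g in 1:125) {
    mat <- dense_step(mat, wrap = TRUE)
    pops[g + 1] <- sum(mat)
  }
  expect_identical(fixture$population, pops)
})

test_that("stabilization detection reports first entry into a global cycle", {
  expect_identical(detect_stabilization(life_universe(life_fixture("block")))[
    c("generation", "period")], list(generation = 0L, period = 1L))
  expect_identical(detect_stabilization(life_universe(life_fixture("l_tromino")))[
    c("generation", "period")], list(generation = 1L, period = 1L))
  # position-sensitive: a travelling glider never repeats a global state
  far <- life_universe(rbind(life_fixture("blinker")$cells,
                             shift_cells(life_fixture("glider")$cells, 40L, 40L)))
  expect_false(detect_stabilization(far, max_generations = 60)$stabilized)
})

test_that("any torus soup stabilizes given an exhaustive budget", {
  for (seed in 1:5) {
    u <- make_soup(soup_spec(4, 4, density = 0.5, seed = seed))
    res <- detect_stabilization(u, max_generations = 2^16 + 1)
    expect_true(res$stabilized, label = paste("seed", seed))
  }
})

test_that("the detected period divides longer recurrence intervals", {
  u <- make_soup(soup_spec(6, 6, density = 0.4, seed = 2))
  res <- detect_stabilization(u, max_generations = 500)
  expect_true(res$stabilized)
  # brute-force: every later recurrence of the entry state is a multiple
  entry <- life_run(u, n_generations = res$generation)[[res$generation + 1L]]
  h <- canonical_hash(entry, translation_invariant = FALSE)
  cur <- entry
  hits <- integer(0)
  for (g in 1:(4 * res$period)) {
    cur <- life_step(cur)$universe
    if (canonical_hash(cur, translation_invariant = FALSE) == h)
      hits <- c(hits, g)
  }
  expect_true(length(hits) >= 1L)
  expect_true(all(hits %% res$period == 0L))
})

test_that("a glider escaping a region is reported once, when its box clears", {
  region <- c(0L, 0L, 9L, 9L)
  margin <- 2L
  start <- life_universe(shift_cells(life_fixture("glider")$cells, 7L, 7L))
  tr <- life_run(start, n_generations = 40)
  events <- detect_escapes(tr, region, margin = margin)
  expect_length(events, 1L)
  expect_identical(events[[1]]$classification$kind, "spaceship")
  # independent geometry: first generation the object's box clears the
  # expanded region, from the raw trajectory
  expanded <- region + c(-margin, -margin, margin, margin)
  clear <- NA_integer_
  for (i in seq_along(tr)) {
    cells <- tr[[i]]$cells
    b <- c(min(cells[, 1L]), min(cells[, 2L]), max(cells[, 1L]), max(cells[, 2L]))
    outside <- b[3] < expanded[1] || expanded[3] < b[1] ||
               b[4] < expanded[2] || expanded[4] < b[2]
    if (outside) { clear <- tr[[i]]$generation; break }
  }
  expect_identical(events[[1]]$generation, clear)
})

test_that("two outward gliders give two escape events; still lifes give none", {
  se <- shift_cells(life_fixture("glider")$cells, 6L, 6L)
  g <- life_fixture("glider")$cells
  nw <- shift_cells(cbind(-g[, 1L], -g[, 2L]), 2L, 2L)  # heading (-1,-1)
  tr <- life_run(life_universe(rbind(se, nw)), n_generations = 40)
  events <- detect_escapes(tr, c(0L, 0L, 8L, 8L), margin = 2L)
  expect_length(events, 2L)

  blocks <- life_universe(rbind(life_fixture("block")$cells,
                                shift_cells(life_fixture("block")$cells, 5L, 5L)))
  tr2 <- life_run(blocks, n_generations = 10)
  expect_length(detect_escapes(tr2, c(0L, 0L, 8L, 8L), margin = 2L), 0L)
})

test_that("non-interacting patterns collide into an unchanged census", {
  out <- collide(life_fixture("block"), life_fixture("block"), c(10, 0))
  expect_identical(out$generations_to_stability, 0L)
  expect_identical(out$period, 1L)
  expect_identical(out$population_final, 8L)
  kc <- attr(out$survivor_census, "kind_counts")
  expect_identical(kc[["still_life"]], 2L)
})

test_that("overlapping placements are rejected", {
  expect_error(collide(life_fixture("block"), life_fixture("block"), c(1, 1)),
               "overlap")
})

test_that("head-on glider collisions reproduce their recorded outcomes", {
  g <- life_fixture("glider")
  back <- life_pattern(cbind(-g$cells[, 1L], -g$cells[, 2L]))  # heading (-1,-1)
  # frozen from an independent dense-engine run of the same configurations
  ann <- collide(g, back, c(10, 10), max_generations = 200)
  expect_identical(ann$generations_to_stability, 24L)
  expect_identical(ann$population_final, 0L)

  blk <- collide(g, back, c(11, 11), max_generations = 200)
  expect_identical(blk$generations_to_stability, 22L)
  expect_identical(blk$population_final, 4L)
  expect_identical(attr(blk$survivor_census, "kind_counts")[["still_life"]], 1L)
  # cross-check the annihilation against the dense oracle
  cells <- rbind(g$cells, shift_cells(back$cells, 10L, 10L))
  pad <- 40L
  mat <- cells_to_dense(cells, 14L + 2L * pad, 14L + 2L * pad,
                        x0 = -pad, y0 = -pad)
  for (i in 1:30) mat <- dense_step(mat, wrap = FALSE)
  expect_identical(sum(mat), 0L)
})

test_that("a glider missing a block leaves a still life plus a mover", {
  out <- collide(life_fixture("glider"), life_fixture("block"), c(25, 5),
                 max_generations = 60)
  expect_true(is.na(out$generations_to_stability))  # the mover never lets the
  kc <- attr(out$survivor_census, "kind_counts")    # global state repeat
  expect_identical(kc[["still_life"]], 1L)
  expect_identical(kc[["spaceship"]], 1L)
})

test_that("box counting recovers the dimension of elementary sets", {
  sq <- as.matrix(expand.grid(x = 0:15, y = 0:15))
  expect_equal(box_counting_dimension(life_universe(sq), c(1, 2, 4))$dimension,
               2, tolerance = 1e-6)
  lone <- life_universe(matrix(c(0L, 0L), 1))
  expect_equal(box_counting_dimension(lone, c(1, 2, 4))$dimension, 0,
               tolerance = 1e-6)
  line <- life_universe(cbind(0:63, 0L))
  bc <- box_counting_dimension(line, c(1, 2, 4, 8))
  expect_equal(bc$dimension, 1, tolerance = 1e-6)
  expect_identical(bc$counts$boxes, c(64L, 32L, 16L, 8L))
})

test_that("box counting rejects degenerate inputs", {
  expect_error(box_counting_dimension(life_universe(), c(1, 2)), "empty")
  expect_error(box_counting_dimension(life_universe(matrix(c(0L, 0L), 1)), 2),
               "two distinct")
})
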