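# Experiment harness: seeded random/scribble soups, free evolution with
# per-generation census, global stabilization detection, mover escapes,
# pattern collisions, and the box-counting dimension statistic.

# run code with a private, fully determined RNG stream, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specify a reproducible random soup
#'
#' Two modes emulate the two ways an initial configuration arises: `bernoulli`
#' fills each grid cell independently with probability `density`; `scribble`
#' emulates a hand-drawn analog shape by the union of `strokes` seeded random
#' walks of a single-cell brush mapped onto the grid (uniform over the 8
#' directions, stroke length twice the grid perimeter, clamped at the edges).
#' An identical spec always produces an identical soup.
#'
#' @param width,height grid dimensions (positive integers).
#' @param density live fraction in `[0, 1]` (bernoulli mode).
#' @param mode `"bernoulli"` or `"scribble"`.
#' @param strokes number of scribble strokes (scribble mode), default 3.
#' @param seed RNG seed integer.
#' @return An object of class `soup_spec`.
#' @export
soup_spec <- function(width, height, density = 0.35,
                      mode = c("bernoulli", "scribble"), strokes = 3L,
                      seed = 1L) {
  mode <- match.arg(mode)
  if (density < 0 || density > 1) stop("'density' must lie in [0, 1]")
  stopifnot(width >= 1, height >= 1, strokes >= 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 density = density, mode = mode, strokes = as.integer(strokes),
                 seed = as.integer(seed)),
            class = "soup_spec")
}

#' Generate the soup a spec describes
#'
#' @param spec a [soup_spec()].
#' @param topology `"torus"` (default — ecosystem experiments need bounded
#'   space for stabilization to be well-defined) or `"infinite"`.
#' @return A [life_universe] with the soup's cells; deterministic given the
#'   spec.
#' @examples
#' u <- make_soup(soup_spec(16, 16, density = 0.35, seed = 7))
#' population(u)
#' @export
make_soup <- function(spec, topology = c("torus", "infinite")) {
  stopifnot(inherits(spec, "soup_spec"))
  topology <- match.arg(topology)
  cells <- with_seed(spec$seed, {
    if (spec$mode == "bernoulli") {
      live <- stats::runif(spec$width * spec$height) < spec$density
      cbind(x = rep(0:(spec$width - 1L), times = spec$height)[live],
            y = rep(0:(spec$height - 1L), each = spec$width)[live])
    } else {
      len <- 2L * (spec$width + spec$height)  # ~ stroke length of a scribble
      xs <- ys <- integer(0)
      for (s in seq_len(spec$strokes)) {
        x <- sample.int(spec$width, 1L) - 1L
        y <- sample.int(spec$height, 1L) - 1L
        dirs <- .MOORE[sample.int(8L, len, replace = TRUE), , drop = FALSE]
        px <- pmin(pmax(cumsum(c(x, dirs[, 1L])), 0L), spec$width - 1L)
        py <- pmin(pmax(cumsum(c(y, dirs[, 2L])), 0L), spec$height - 1L)
        xs <- c(xs, px); ys <- c(ys, py)
      }
      cbind(x = xs, y = ys)
    }
  })
  if (topology == "torus")
    life_universe(cells, topology = "torus", width = spec$width,
                  height = spec$height)
  else
    life_universe(cells)
}

kind_cols <- c("n_dies_out", "n_still_life", "n_oscillator", "n_spaceship",
               "n_unresolved")

census_record <- function(generation, universe, births, deaths, rule,
                          link_radius, classify_budget) {
  cen <- life_census(universe, rule = rule, link_radius = link_radius,
                     max_generations = classify_budget)
  kc <- attr(cen, "kind_counts")
  rec <- data.frame(generation = generation, population = population(universe),
                    births = births, deaths = deaths,
                    n_objects = attr(cen, "n_objects"))
  rec[kind_cols] <- as.integer(kc[c("dies_out", "still_life", "oscillator",
                                    "spaceship", "unresolved")])
  rec
}

#' Free evolution with per-generation census
#'
#' Runs a universe forward and records, at every generation, the population,
#' the births and deaths of the step that produced it, the number of
#' connected objects, and the per-kind object census. Row `t` satisfies the
#' conservation identity
#' `population(t) = population(t-1) + births(t) - deaths(t)`.
#'
#' @param universe a [life_universe] (typically from [make_soup()]).
#' @param rule a [life_rule].
#' @param n_generations number of steps (>= 1).
#' @param link_radius object-linking radius for the census.
#' @param classify_budget per-object classification budget at each census;
#'   default 20 generations — active debris is reported as `unresolved`
#'   rather than chased.
#' @return A `life_census_series` data frame with columns `generation`,
#'   `population`, `births`, `deaths`, `n_objects`, and one `n_<kind>`
#'   column per taxonomy kind.
#' @examples
#' free_evolution(life_universe(life_fixture("blinker")), n_generations = 4)
#' @export
free_evolution <- function(universe, rule = life_rule(), n_generations,
                           link_radius = 1L, classify_budget = 20L) {
  stopifnot(n_generations >= 1)
  recs <- vector("list", n_generations + 1L)
  recs[[1L]] <- census_record(0L, universe, 0L, 0L, rule, link_radius,
                              classify_budget)
  u <- universe
  for (g in seq_len(n_generations)) {
    st <- life_step(u, rule)
    u <- st$universe
    recs[[g + 1L]] <- census_record(g, u, nrow(st$births), nrow(st$deaths),
                                    rule, link_radius, classify_budget)
  }
  out <- do.call(rbind, recs)
  class(out) <- c("life_census_series", "data.frame")
  out
}

#' Write a census time series as CSV
#' @param series a `life_census_series` from [free_evolution()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Detect entry into a global cycle
#'
#' Hash-map cycle detection on the translation-*sensitive* global state:
#' position matters at ecosystem scale, so a lone glider drifting across the
#' infinite plane never repeats a global state (and is reported unresolved),
#' while any bounded-torus soup must eventually cycle.
#'
#' @param universe a [life_universe].
#' @param rule a [life_rule].
#' @param max_generations search budget.
#' @return A list with `stabilized` (logical), and when `TRUE`, `generation`
#'   (first entry into the cycle) and `period` (global period).
#' @examples
#' detect_stabilization(life_universe(life_fixture("block")))     # gen 0, period 1
#' detect_stabilization(life_universe(life_fixture("l_tromino"))) # gen 1, period 1
#' @export
detect_stabilization <- function(universe, rule = life_rule(),
                                 max_generations = 1000L) {
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  assign(canonical_hash(universe, translation_invariant = FALSE), 0L,
         envir = seen)
  u <- universe
  for (g in seq_len(max_generations)) {
    u <- life_step(u, rule)$universe
    h <- canonical_hash(u, translation_invariant = FALSE)
    if (exists(h, envir = seen, inherits = FALSE)) {
      g0 <- get(h, envir = seen, inherits = FALSE)
      return(list(stabilized = TRUE, generation = g0, period = g - g0))
    }
    assign(h, g, envir = seen)
  }
  list(stabilized = FALSE, generation = NA_integer_, period = NA_integer_)
}

boxes_disjoint <- function(a, b) {
  a[3L] < b[1L] || b[3L] < a[1L] || a[4L] < b[2L] || b[4L] < a[2L]
}

#' Detect movers escaping a region
#'
#' Scans a trajectory for objects that have crossed entirely outside the
#' initial region (expanded by `margin`) and classify as spaceships. An
#' escape event is reported at the first generation an object's bounding box
#' clears the expanded region, having been (or overlapped something) inside
#' or crossing at the previous generation; an escaped mover travelling
#' further away is not re-reported.
#'
#' @param trajectory a `life_trajectory` from [life_run()].
#' @param initial_region bounding box `c(xmin, ymin, xmax, ymax)`.
#' @param margin expansion of the region, default 2.
#' @param rule a [life_rule] (for classifying the escapers).
#' @param link_radius object-linking radius.
#' @param max_generations classification budget per candidate object.
#' @return A list of events, each `list(generation, object)` with `object` a
#'   [life_pattern] carrying its `offset` attribute.
#' @export
detect_escapes <- function(trajectory, initial_region, margin = 2L,
                           rule = life_rule(), link_radius = 1L,
                           max_generations = 64L) {
  stopifnot(length(trajectory) >= 1L, length(initial_region) == 4L)
  region <- initial_region + c(-margin, -margin, margin, margin)
  events <- list()
  obj_boxes <- function(u) {
    objs <- extract_objects(u, link_radius)
    list(objs = objs,
         boxes = lapply(objs, function(p) {
           off <- attr(p, "offset")
           b <- bbox(p$cells)
           c(b[1L] + off[1L], b[2L] + off[2L], b[3L] + off[1L], b[4L] + off[2L])
         }))
  }
  prev <- obj_boxes(trajectory[[1L]])
  prev_outside <- vapply(prev$boxes, boxes_disjoint, TRUE, b = region)
  for (i in seq_along(trajectory)[-1L]) {
    cur <- obj_boxes(trajectory[[i]])
    cur_outside <- vapply(cur$boxes, boxes_disjoint, TRUE, b = region)
    for (j in seq_along(cur$objs)) {
      if (!cur_outside[j]) next
      # grow the box by one cell: a predecessor object must overlap it
      grown <- cur$boxes[[j]] + c(-1L, -1L, 1L, 1L)
      pred <- which(vapply(prev$boxes, function(b) !boxes_disjoint(b, grown),
                           TRUE))
      newly <- length(pred) > 0L && any(!prev_outside[pred])
      if (newly) {
        cl <- classify_exact(cur$objs[[j]], rule = rule,
                             max_generations = max_generations)
        if (cl$kind == "spaceship")
          events[[length(events) + 1L]] <-
            list(generation = trajectory[[i]]$generation,
                 object = cur$objs[[j]], classification = cl)
      }
    }
    prev <- cur
    prev_outside <- cur_outside
  }
  events
}

#' Collide two patterns
#'
#' Places `a` at the origin and `b` at `offset` on an infinite plane, runs to
#' global stabilization (translation-sensitive cycle detection) or to the
#' budget, and reports the survivor census. Deterministic: the same patterns
#' and offset always give the same outcome.
#'
#' @param a,b [life_pattern]s.
#' @param offset length-2 integer vector placing `b` relative to `a`.
#' @param rule a [life_rule].
#' @param max_generations run budget.
#' @param link_radius object-linking radius for the survivor census.
#' @param classify_budget per-object classification budget for the census.
#' @return A `collision_outcome`: `offset`, `generations_to_stability`
#'   (`NA` if unresolved within budget), `period`, `survivor_census` (a
#'   `life_census`), and `population_final`.
#' @examples
#' out <- collide(life_fixture("block"), life_fixture("block"), c(10, 0))
#' out$survivor_census # two untouched still lifes
#' @export
collide <- function(a, b, offset, rule = life_rule(), max_generations = 500L,
                    link_radius = 1L, classify_budget = 100L) {
  stopifnot(inherits(a, "life_pattern"), inherits(b, "life_pattern"),
            length(offset) == 2L)
  offset <- as.integer(offset)
  bc <- b$cells
  bc[, 1L] <- bc[, 1L] + offset[1L]
  bc[, 2L] <- bc[, 2L] + offset[2L]
  ka <- cell_key(a$cells[, 1L], a$cells[, 2L])
  kb <- cell_key(bc[, 1L], bc[, 2L])
  if (length(intersect(ka, kb)))
    stop("initial placements overlap; choose a non-overlapping offset")
  u <- life_universe(rbind(a$cells, bc))
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  states <- vector("list", max_generations + 1L)
  states[[1L]] <- u
  assign(canonical_hash(u, translation_invariant = FALSE), 0L, envir = seen)
  entry <- NA_integer_; period <- NA_integer_
  final <- u
  for (g in seq_len(max_generations)) {
    u <- life_step(u, rule)$universe
    states[[g + 1L]] <- u
    h <- canonical_hash(u, translation_invariant = FALSE)
    if (exists(h, envir = seen, inherits = FALSE)) {
      entry <- get(h, envir = seen, inherits = FALSE)
      period <- g - entry
      final <- states[[entry + 1L]]
      break
    }
    assign(h, g, envir = seen)
    final <- u
  }
  cen <- life_census(final, rule = rule, link_radius = link_radius,
                     max_generations = classify_budget)
  structure(list(offset = offset, generations_to_stability = entry,
                 period = period, survivor_census = cen,
                 population_final = population(final)),
            class = "collision_outcome")
}

#' @export
print.collision_outcome <- function(x, ...) {
  st <- if (is.na(x$generations_to_stability)) "unresolved within budget"
  else sprintf("stabilized at generation %d (period %d)",
               x$generations_to_stability, x$period)
  cat(sprintf("<collision_outcome> offset (%d,%d): %s, final population %d\n",
              x$offset[1], x$offset[2], st, x$population_final))
  print(x$survivor_census)
  invisible(x)
}

#' Box-counting dimension of a live set
#'
#' Overlays square boxes of each size on the pattern's bounding box, counts
#' boxes containing at least one live cell, and estimates the box-counting
#' (Minkowski) dimension as the least-squares slope of `log(count)` against
#' `log(1/size)`.
#'
#' @param universe a nonempty [life_universe], [life_pattern], or cell
#'   matrix.
#' @param box_sizes at least two distinct positive box sizes, e.g.
#'   `c(1, 2, 4, 8)`.
#' @return A list with `dimension` (the slope) and `counts` (data frame of
#'   `size`, `boxes`).
#' @examples
#' sq <- as.matrix(expand.grid(x = 0:15, y = 0:15))
#' box_counting_dimension(life_universe(sq), c(1, 2, 4))$dimension # ~2
#' @export
box_counting_dimension <- function(universe, box_sizes = c(1L, 2L, 4L, 8L)) {
  cells <- as_cell_matrix(universe)
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (length(box_sizes) < 2L || any(box_sizes < 1L))
    stop("'box_sizes' must contain at least two distinct positive sizes")
  if (nrow(cells) == 0L)
    stop("box-counting dimension is undefined for an empty universe")
  x <- cells[, 1L] - min(cells[, 1L])
  y <- cells[, 2L] - min(cells[, 2L])
  boxes <- vapply(box_sizes, function(s) {
    length(unique(cell_key(x %/% s, y %/% s)))
  }, 0L)
  fit <- stats::lm(log(boxes) ~ log(1 / box_sizes))
  list(dimension = unname(stats::coef(fit)[2L]),
       counts = data.frame(size = box_sizes, boxes = boxes))
}
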