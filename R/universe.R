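# Sparse universe representation: live cells as an n x 2 integer matrix of
# (x, y) coordinates, x rightward, y downward, plus a topology and a
# generation counter. The sparse set is the "existential" state on which the
# conditional update rules act.

# Coordinates are packed into doubles for hashing/matching: exact for
# |x|, |y| < 2^20, far beyond any reachable extent in practice.
.KOFF <- 2^20
.KBASE <- 2^21

cell_key <- function(x, y) (x + .KOFF) * .KBASE + (y + .KOFF)

key_cell <- function(k) {
  ey <- k %% .KBASE
  cbind(x = as.integer(k %/% .KBASE - .KOFF), y = as.integer(ey - .KOFF))
}

as_cell_matrix <- function(cells) {
  if (is.null(cells)) cells <- matrix(integer(0), 0L, 2L)
  if (inherits(cells, "life_pattern")) cells <- cells$cells
  if (inherits(cells, "life_universe")) cells <- cells$cells
  if (is.data.frame(cells)) cells <- as.matrix(cells)
  if (!is.matrix(cells) || ncol(cells) != 2L)
    stop("'cells' must be a two-column (x, y) matrix, data frame or pattern")
  storage.mode(cells) <- "integer"
  colnames(cells) <- c("x", "y")
  cells
}

# deterministic row-major order (y, then x) with duplicates removed
sort_cells <- function(cells) {
  if (nrow(cells) == 0L) return(cells)
  cells <- cells[!duplicated(cell_key(cells[, 1L], cells[, 2L])), , drop = FALSE]
  cells[order(cells[, 2L], cells[, 1L]), , drop = FALSE]
}

#' Construct a Life universe
#'
#' A universe is a set of live cells on integer coordinates (x rightward, y
#' downward) plus a topology and a generation counter. The default topology is
#' the infinite plane; a bounded torus of given width and height is available
#' for ecosystem-scale experiments where stabilization must be well-defined.
#' Torus wrap applies to neighbour lookup only; stored coordinates satisfy
#' `0 <= x < width`, `0 <= y < height`.
#'
#' @param cells a two-column (x, y) matrix/data frame, a [life_pattern], or
#'   `NULL` for an empty universe.
#' @param topology `"infinite"` (default) or `"torus"`.
#' @param width,height torus dimensions (required when `topology = "torus"`).
#' @param generation nonnegative generation counter, default 0.
#' @return An object of class `life_universe`.
#' @examples
#' u <- life_universe(life_fixture("blinker"))
#' population(u)
#' @export
life_universe <- function(cells = NULL, topology = c("infinite", "torus"),
                          width = NULL, height = NULL, generation = 0L) {
  topology <- match.arg(topology)
  cells <- as_cell_matrix(cells)
  if (topology == "torus") {
    if (is.null(width) || is.null(height) || width < 1L || height < 1L)
      stop("torus topology requires positive 'width' and 'height'")
    width <- as.integer(width); height <- as.integer(height)
    if (nrow(cells) && (any(cells[, 1L] < 0L | cells[, 1L] >= width) ||
                        any(cells[, 2L] < 0L | cells[, 2L] >= height)))
      stop("torus cells must satisfy 0 <= x < width, 0 <= y < height")
  } else {
    width <- height <- NULL
  }
  structure(list(cells = sort_cells(cells), topology = topology,
                 width = width, height = height,
                 generation = as.integer(generation)),
            class = "life_universe")
}

#' Number of live cells
#' @param universe a [life_universe].
#' @return integer population count.
#' @export
population <- function(universe) nrow(universe$cells)

# wrap coordinates onto the torus; identity on the infinite plane
wrap_cells <- function(x, y, universe) {
  if (universe$topology == "torus") {
    x <- x %% universe$width
    y <- y %% universe$height
  }
  cbind(x, y)
}

.MOORE <- cbind(x = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L),
                y = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L))

#' Count live Moore neighbours of one cell
#'
#' Counts live cells among the 8 neighbours (chessboard-adjacent cells) of
#' `cell`, wrapping around the edges under torus topology.
#'
#' @param universe a [life_universe].
#' @param cell length-2 integer vector (x, y); must lie inside the torus
#'   bounds when the topology is a torus.
#' @return integer in 0..8.
#' @examples
#' u <- life_universe(life_fixture("blinker")) # cells (0,0),(1,0),(2,0)
#' neighbor_count(u, c(1, 0))                  # the centre cell has 2
#' @export
neighbor_count <- function(universe, cell) {
  stopifnot(inherits(universe, "life_universe"), length(cell) == 2L)
  cell <- as.integer(cell)
  if (universe$topology == "torus" &&
      (cell[1L] < 0L || cell[1L] >= universe$width ||
       cell[2L] < 0L || cell[2L] >= universe$height))
    stop("cell lies outside the torus bounds")
  if (nrow(universe$cells) == 0L) return(0L)
  nb <- wrap_cells(cell[1L] + .MOORE[, 1L], cell[2L] + .MOORE[, 2L], universe)
  live <- cell_key(universe$cells[, 1L], universe$cells[, 2L])
  sum(cell_key(nb[, 1L], nb[, 2L]) %in% live)
}

#' Advance a universe by one generation
#'
#' Applies the rule simultaneously to every cell: a live cell survives iff its
#' Moore neighbour count is in the rule's survival set; an empty cell becomes
#' live iff its count is in the birth set. Only live cells and their
#' neighbours are examined (candidate-set method), which is exact and permits
#' the infinite topology.
#'
#' @param universe a [life_universe].
#' @param rule a [life_rule]; default Conway's B3/S23.
#' @return An object of class `life_step`: a list with the advanced
#'   `universe` (generation incremented by 1) and the step delta — `births`
#'   and `deaths`, each an (x, y) matrix. The delta satisfies
#'   `population(t+1) = population(t) + nrow(births) - nrow(deaths)`.
#' @examples
#' s <- life_step(life_universe(life_fixture("blinker")))
#' s$births  # ends of the vertical phase come alive
#' @export
life_step <- function(universe, rule = life_rule()) {
  stopifnot(inherits(universe, "life_universe"), inherits(rule, "life_rule"))
  if (0L %in% rule$birth && universe$topology == "infinite")
    stop("rules with birth on 0 neighbours are not representable on the infinite plane")
  cells <- universe$cells
  n <- nrow(cells)
  empty <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("x", "y")))
  if (n == 0L && !(0L %in% rule$birth)) {
    nxt <- universe
    nxt$generation <- universe$generation + 1L
    return(structure(list(universe = nxt, births = empty, deaths = empty),
                     class = "life_step"))
  }
  # candidate counts: each live cell contributes +1 to each of its 8 neighbours
  nx <- rep(cells[, 1L], times = 8L) + rep(.MOORE[, 1L], each = n)
  ny <- rep(cells[, 2L], times = 8L) + rep(.MOORE[, 2L], each = n)
  nb <- wrap_cells(nx, ny, universe)
  keys <- cell_key(nb[, 1L], nb[, 2L])
  ukeys <- unique(keys)
  counts <- tabulate(match(keys, ukeys), nbins = length(ukeys))
  live_keys <- if (n) cell_key(cells[, 1L], cells[, 2L]) else numeric(0)

  live_counts <- counts[match(live_keys, ukeys)]
  live_counts[is.na(live_counts)] <- 0L
  survives <- live_counts %in% rule$survival

  if (0L %in% rule$birth) {
    # zero-count empties only exist on a bounded torus: enumerate the grid
    allk <- cell_key(rep(0:(universe$width - 1L), times = universe$height),
                     rep(0:(universe$height - 1L), each = universe$width))
    extra <- setdiff(allk, c(ukeys, live_keys))
    ukeys <- c(ukeys, extra)
    counts <- c(counts, integer(length(extra)))
  }
  is_live <- ukeys %in% live_keys
  birth_keys <- ukeys[!is_live & counts %in% rule$birth]

  births <- if (length(birth_keys)) key_cell(birth_keys) else empty
  deaths <- if (any(!survives)) cells[!survives, , drop = FALSE] else empty
  new_cells <- rbind(cells[survives, , drop = FALSE], births)
  nxt <- universe
  nxt$cells <- sort_cells(new_cells)
  nxt$generation <- universe$generation + 1L
  structure(list(universe = nxt, births = sort_cells(births),
                 deaths = sort_cells(deaths)),
            class = "life_step")
}

#' Run a universe for a fixed number of generations
#'
#' @param universe a [life_universe].
#' @param rule a [life_rule].
#' @param n_generations nonnegative number of steps.
#' @return A `life_trajectory`: list of `n_generations + 1` universes,
#'   element `i + 1` being `i` applications of [life_step()] to the input.
#' @examples
#' tr <- life_run(life_universe(life_fixture("blinker")), n_generations = 2)
#' identical(tr[[1]]$cells, tr[[3]]$cells) # period 2
#' @export
life_run <- function(universe, rule = life_rule(), n_generations) {
  stopifnot(n_generations >= 0)
  n_generations <- as.integer(n_generations)
  out <- vector("list", n_generations + 1L)
  out[[1L]] <- universe
  u <- universe
  if (n_generations > 0L) for (i in seq_len(n_generations)) {
    u <- life_step(u, rule)$universe
    out[[i + 1L]] <- u
  }
  structure(out, class = "life_trajectory")
}

#' Canonical state hash
#'
#' A perfect hash of the live set: equal live sets give equal hashes. With
#' `translation_invariant = TRUE` the live set is normalized to its
#' bounding-box origin first, so live sets equal up to translation hash
#' equally — the form needed to detect oscillators and spaceships. The empty
#' universe hashes to a fixed sentinel.
#'
#' @param universe a [life_universe].
#' @param translation_invariant normalize to bounding-box origin before
#'   hashing? Default `TRUE`.
#' @return A character scalar usable as a hash-map key.
#' @export
canonical_hash <- function(universe, translation_invariant = TRUE) {
  cells <- as_cell_matrix(universe)
  if (nrow(cells) == 0L) return("<empty>")
  x <- cells[, 1L]; y <- cells[, 2L]
  if (translation_invariant) {
    x <- x - min(x); y <- y - min(y)
  }
  k <- sort(cell_key(x, y))
  paste(k, collapse = " ")
}

# bounding-box origin (min x, min y); only valid for nonempty universes
bbox_origin <- function(universe) {
  cells <- as_cell_matrix(universe)
  c(min(cells[, 1L]), min(cells[, 2L]))
}

# bounding box as (xmin, ymin, xmax, ymax)
bbox <- function(cells) {
  cells <- as_cell_matrix(cells)
  c(min(cells[, 1L]), min(cells[, 2L]), max(cells[, 1L]), max(cells[, 2L]))
}

#' @export
print.life_universe <- function(x, ...) {
  top <- if (x$topology == "torus")
    sprintf("torus %dx%d", x$width, x$height) else "infinite plane"
  cat(sprintf("<life_universe> %d live cells, generation %d, %s\n",
              nrow(x$cells), x$generation, top))
  if (nrow(x$cells) > 0L && nrow(x$cells) <= 400L) {
    b <- bbox(x$cells)
    if ((b[3] - b[1]) <= 60L && (b[4] - b[2]) <= 30L) {
      grid <- matrix(".", b[4] - b[2] + 1L, b[3] - b[1] + 1L)
      grid[cbind(x$cells[, 2L] - b[2] + 1L, x$cells[, 1L] - b[1] + 1L)] <- "O"
      cat(apply(grid, 1L, paste, collapse = ""), sep = "\n")
    }
  }
  invisible(x)
}

#' Plot the live cells of a universe
#' @param x a [life_universe].
#' @param ... passed to [graphics::rect()].
#' @return `x`, invisibly.
#' @export
plot.life_universe <- function(x, ...) {
  cells <- x$cells
  if (nrow(cells) == 0L) {
    plot.new()
    title(main = "empty universe")
    return(invisible(x))
  }
  b <- bbox(cells)
  plot(NA, xlim = c(b[1] - 1, b[3] + 2), ylim = c(b[4] + 2, b[2] - 1),
       asp = 1, xlab = "x", ylab = "y",
       main = sprintf("generation %d, %d cells", x$generation, nrow(cells)))
  rect(cells[, 1L], cells[, 2L] + 1, cells[, 1L] + 1, cells[, 2L],
       col = "black", ...)
  invisible(x)
}

#' @export
print.life_step <- function(x, ...) {
  cat(sprintf("<life_step> -> generation %d: %d births, %d deaths, population %d\n",
              x$universe$generation, nrow(x$births), nrow(x$deaths),
              population(x$universe)))
  invisible(x)
}

#' @export
print.life_trajectory <- function(x, ...) {
  cat(sprintf("<life_trajectory> %d states, generations %d..%d, population %d -> %d\n",
              length(x), x[[1]]$generation, x[[length(x)]]$generation,
              population(x[[1]]), population(x[[length(x)]])))
  invisible(x)
}
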