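# Emergent-form taxonomy: still lifes (stable), oscillators (periodic in
# place), spaceships (periodic up to a nonzero translation), die-outs, and
# unresolved patterns. Two modes are provided because "is periodic" and
# "becomes periodic" are different questions: classify_exact() asks whether
# the pattern as given recurs; classify_fate() follows the pattern until any
# state recurs and reports the cycle it falls into plus the transient length.

new_classification <- function(kind, period = NA_integer_,
                               displacement = c(NA_integer_, NA_integer_),
                               transient = NA_integer_,
                               generations_examined = NA_integer_) {
  structure(list(kind = kind, period = as.integer(period),
                 displacement = as.integer(displacement),
                 transient = as.integer(transient),
                 generations_examined = as.integer(generations_examined)),
            class = "life_classification")
}

#' @export
print.life_classification <- function(x, ...) {
  extra <- switch(x$kind,
    still_life = "",
    oscillator = sprintf(", period %d", x$period),
    spaceship  = sprintf(", period %d, displacement (%d,%d)",
                         x$period, x$displacement[1], x$displacement[2]),
    dies_out   = sprintf(" at generation %d", x$transient),
    "")
  tr <- if (!is.na(x$transient) && x$transient > 0L && x$kind != "dies_out")
    sprintf(" after transient %d", x$transient) else ""
  cat(sprintf("<life_classification> %s%s%s (%d generations examined)\n",
              x$kind, extra, tr, x$generations_examined))
  invisible(x)
}

#' @export
format.life_classification <- function(x, ...) x$kind

as_start_universe <- function(pattern) {
  if (inherits(pattern, "life_universe")) {
    if (pattern$topology != "infinite")
      life_universe(pattern$cells)  # classification runs on the infinite plane
    else pattern
  } else if (inherits(pattern, "life_pattern")) {
    as_universe(pattern)
  } else {
    life_universe(as_cell_matrix(pattern))
  }
}

#' Classify a pattern by recurrence of its initial state
#'
#' Simulates the pattern on an infinite plane and watches for the first
#' generation whose translation-canonical form equals the initial one. A
#' recurrence at generation `t` with total bounding-box displacement `d`
#' gives: `still_life` if `t = 1` and `d = (0,0)`; `oscillator` (with
#' `period = t`) if `t >= 2` and `d = (0,0)`; `spaceship` (with minimal
#' period `t` and `displacement = d`) if `d != (0,0)`. A pattern whose live
#' set empties is `dies_out` (with `transient` the generation it first became
#' empty); no recurrence within the budget is `unresolved`.
#'
#' @param pattern a [life_pattern], [life_universe], or (x, y) cell matrix.
#' @param rule a [life_rule].
#' @param max_generations simulation budget (default 1000, comfortably above
#'   the longest oscillator period the package's experiments encounter).
#' @return A `life_classification`: `kind`, `period`, `displacement`,
#'   `transient`, `generations_examined`.
#' @examples
#' classify_exact(life_fixture("blinker")) # oscillator, period 2
#' classify_exact(life_fixture("block"))   # still life
#' classify_exact(life_fixture("glider"))  # spaceship, period 4, (1,1)
#' @export
classify_exact <- function(pattern, rule = life_rule(), max_generations = 1000L) {
  stopifnot(max_generations >= 1)
  u <- as_start_universe(pattern)
  if (population(u) == 0L)
    return(new_classification("dies_out", transient = 0L,
                              generations_examined = 0L))
  h0 <- canonical_hash(u)
  o0 <- bbox_origin(u)
  for (g in seq_len(max_generations)) {
    u <- life_step(u, rule)$universe
    if (population(u) == 0L)
      return(new_classification("dies_out", transient = g,
                                generations_examined = g))
    if (canonical_hash(u) == h0) {
      d <- bbox_origin(u) - o0
      kind <- if (all(d == 0L)) {
        if (g == 1L) "still_life" else "oscillator"
      } else "spaceship"
      return(new_classification(kind, period = g, displacement = d,
                                transient = 0L, generations_examined = g))
    }
  }
  new_classification("unresolved", transient = 0L,
                     generations_examined = max_generations)
}

#' Classify the eventual fate of a pattern
#'
#' Like [classify_exact()], but keeps a hash map from every
#' translation-canonical state seen to its (generation, position); the first
#' repeat of *any* state identifies the cycle the pattern falls into. The
#' reported `transient` is the generation of the cycle's first occurrence —
#' e.g. the L-tromino grows a binding fourth cell in one step and is a still
#' life (the block) with transient 1. Patterns that shed gliders on the
#' infinite plane never repeat a whole-universe state and come back
#' `unresolved`.
#'
#' @inheritParams classify_exact
#' @return A `life_classification`.
#' @examples
#' classify_fate(life_fixture("l_tromino")) # still_life, transient 1
#' @export
classify_fate <- function(pattern, rule = life_rule(), max_generations = 1000L) {
  stopifnot(max_generations >= 1)
  u <- as_start_universe(pattern)
  if (population(u) == 0L)
    return(new_classification("dies_out", transient = 0L,
                              generations_examined = 0L))
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  assign(canonical_hash(u), list(gen = 0L, origin = bbox_origin(u)),
         envir = seen)
  for (g in seq_len(max_generations)) {
    u <- life_step(u, rule)$universe
    if (population(u) == 0L)
      return(new_classification("dies_out", transient = g,
                                generations_examined = g))
    h <- canonical_hash(u)
    prev <- if (exists(h, envir = seen, inherits = FALSE))
      get(h, envir = seen, inherits = FALSE) else NULL
    if (!is.null(prev)) {
      period <- g - prev$gen
      d <- bbox_origin(u) - prev$origin
      kind <- if (all(d == 0L)) {
        if (period == 1L) "still_life" else "oscillator"
      } else "spaceship"
      return(new_classification(kind, period = period, displacement = d,
                                transient = prev$gen, generations_examined = g))
    }
    assign(h, list(gen = g, origin = bbox_origin(u)), envir = seen)
  }
  new_classification("unresolved", generations_examined = max_generations)
}

#' Partition live cells into connected objects
#'
#' Two live cells belong to the same object when their Chebyshev distance
#' `max(|dx|, |dy|)` is at most `link_radius`. The default radius 1
#' (8-connectivity) matches visual object identity; a larger radius merges
#' closely adjacent pseudo-objects that interact.
#'
#' @param universe a [life_universe].
#' @param link_radius positive linking radius (Chebyshev), default 1.
#' @return A list of [life_pattern]s, each carrying an `offset` attribute
#'   (the component's bounding-box origin in universe coordinates). The
#'   components are pairwise disjoint and their union is the live set.
#' @examples
#' u <- life_universe(rbind(life_fixture("block")$cells,
#'                          life_fixture("blinker")$cells + 10L))
#' length(extract_objects(u)) # 2
#' @export
extract_objects <- function(universe, link_radius = 1L) {
  stopifnot(inherits(universe, "life_universe"), link_radius >= 1)
  link_radius <- as.integer(link_radius)
  cells <- universe$cells
  n <- nrow(cells)
  if (n == 0L) return(list())
  keys <- cell_key(cells[, 1L], cells[, 2L])
  # half of the (2r+1)^2 - 1 offsets; the other half gives the same edges
  offs <- expand.grid(dx = -link_radius:link_radius,
                      dy = -link_radius:link_radius)
  offs <- offs[offs$dy > 0L | (offs$dy == 0L & offs$dx > 0L), , drop = FALSE]
  from <- to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- wrap_cells(cells[, 1L] + offs$dx[r], cells[, 2L] + offs$dy[r],
                     universe)
    hit <- match(cell_key(nb[, 1L], nb[, 2L]), keys)
    ok <- !is.na(hit)
    from <- c(from, which(ok))
    to <- c(to, hit[ok])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # order components by first appearance in row-major cell order
  comp_ids <- unique(memb)
  lapply(comp_ids, function(id) {
    cc <- cells[memb == id, , drop = FALSE]
    p <- life_pattern(cc)
    attr(p, "offset") <- c(min(cc[, 1L]), min(cc[, 2L]))
    p
  })
}

#' Per-object census of a universe
#'
#' Extracts connected objects and classifies each in isolation on its own
#' infinite plane with [classify_exact()]; interactions between objects are
#' the experiment harness's concern, not the census's.
#'
#' @inheritParams extract_objects
#' @param rule a [life_rule].
#' @param max_generations per-object classification budget.
#' @return A `life_census`: a data frame with one row per distinct
#'   (kind, period, displacement) combination and a `count` column, plus
#'   attributes `n_objects` and `kind_counts` (named integer vector over the
#'   five kinds).
#' @examples
#' u <- life_universe(rbind(life_fixture("block")$cells,
#'                          life_fixture("blinker")$cells + 10L))
#' life_census(u)
#' @export
life_census <- function(universe, rule = life_rule(), link_radius = 1L,
                        max_generations = 1000L) {
  objs <- extract_objects(universe, link_radius)
  kinds <- c("dies_out", "still_life", "oscillator", "spaceship", "unresolved")
  if (length(objs) == 0L) {
    df <- data.frame(kind = character(0), period = integer(0),
                     dx = integer(0), dy = integer(0), count = integer(0),
                     stringsAsFactors = FALSE)
  } else {
    cl <- lapply(objs, classify_exact, rule = rule,
                 max_generations = max_generations)
    df <- data.frame(
      kind = vapply(cl, `[[`, "", "kind"),
      period = vapply(cl, `[[`, NA_integer_, "period"),
      dx = vapply(cl, function(x) x$displacement[1L], NA_integer_),
      dy = vapply(cl, function(x) x$displacement[2L], NA_integer_),
      stringsAsFactors = FALSE)
    key <- paste(df$kind, df$period, df$dx, df$dy)
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$count <- as.integer(table(key)[paste(df$kind, df$period, df$dx, df$dy)])
    df <- df[order(df$kind, df$period), , drop = FALSE]
    rownames(df) <- NULL
  }
  kc <- vapply(kinds, function(k) sum(df$count[df$kind == k]), 0L)
  structure(df, n_objects = length(objs), kind_counts = kc,
            class = c("life_census", "data.frame"))
}

#' @export
print.life_census <- function(x, ...) {
  cat(sprintf("<life_census> %d objects\n", attr(x, "n_objects")))
  if (nrow(x)) print.data.frame(x, ...) else cat("(empty universe)\n")
  invisible(x)
}

#' Serialize a census as JSON records
#' @param census a `life_census`.
#' @return JSON text: an array of `{kind, period, displacement, count}`
#'   records.
#' @export
census_json <- function(census) {
  recs <- lapply(seq_len(nrow(census)), function(i) {
    r <- list(kind = census$kind[i], count = census$count[i])
    if (!is.na(census$period[i])) r$period <- census$period[i]
    if (!is.na(census$dx[i])) r$displacement <- c(census$dx[i], census$dy[i])
    r
  })
  jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE)
}
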