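# Pattern I/O: the two standard plain-text Life formats (run-length encoded
# ".rle" in the Golly/LifeWiki dialect, and dots-and-Os ".cells" plaintext)
# plus the embedded fixture library of canonical forms.

#' Construct a pattern
#'
#' A pattern is a set of live cells normalized to its bounding-box origin
#' (min x = min y = 0), with an optional name and an optional rule hint
#' carried over from a file header.
#'
#' @param cells two-column (x, y) matrix or data frame (may be empty).
#' @param name optional text label.
#' @param rule_hint optional rule string (e.g. `"B3/S23"`) from a file header.
#' @return An object of class `life_pattern` with elements `cells`, `name`,
#'   `rule_hint`.
#' @export
life_pattern <- function(cells = NULL, name = "", rule_hint = NULL) {
  cells <- sort_cells(as_cell_matrix(cells))
  if (nrow(cells)) {
    cells[, 1L] <- cells[, 1L] - min(cells[, 1L])
    cells[, 2L] <- cells[, 2L] - min(cells[, 2L])
  }
  structure(list(cells = cells, name = name, rule_hint = rule_hint),
            class = "life_pattern")
}

#' @export
print.life_pattern <- function(x, ...) {
  nm <- if (nzchar(x$name)) paste0(" '", x$name, "'") else ""
  cat(sprintf("<life_pattern>%s %d cells\n", nm, nrow(x$cells)))
  if (nrow(x$cells)) {
    b <- bbox(x$cells)
    if (b[3] <= 60L && b[4] <= 30L) {
      grid <- matrix(".", b[4] + 1L, b[3] + 1L)
      grid[cbind(x$cells[, 2L] + 1L, x$cells[, 1L] + 1L)] <- "O"
      cat(apply(grid, 1L, paste, collapse = ""), sep = "\n")
    }
  }
  invisible(x)
}

#' Place a pattern into a universe
#'
#' @param pattern a [life_pattern].
#' @param at length-2 offset added to the pattern's (normalized) coordinates.
#' @inheritParams life_universe
#' @return A [life_universe].
#' @export
as_universe <- function(pattern, at = c(0L, 0L),
                        topology = c("infinite", "torus"),
                        width = NULL, height = NULL) {
  stopifnot(inherits(pattern, "life_pattern"))
  cells <- pattern$cells
  if (nrow(cells)) {
    cells[, 1L] <- cells[, 1L] + as.integer(at[1L])
    cells[, 2L] <- cells[, 2L] + as.integer(at[2L])
  }
  life_universe(cells, topology = topology, width = width, height = height)
}

rle_error <- function(line, col, msg) {
  stop(sprintf("RLE parse error at line %d, column %d: %s", line, col, msg),
       call. = FALSE)
}

#' Parse a run-length-encoded (RLE) pattern
#'
#' Follows the de-facto Golly/LifeWiki dialect: optional `#` comment lines,
#' an optional header line `x = <w>, y = <h>[, rule = <rule>]`, then a body
#' of `<count><tag>` items with tags `b` (dead), `o` (alive), `$` (end of
#' row), terminated by `!`. The header is optional on read; when present, the
#' body must not exceed the declared extents.
#'
#' @param text RLE text (single string, possibly multi-line) or a character
#'   vector of lines.
#' @param name optional pattern name.
#' @return A [life_pattern]; `rule_hint` is populated from the header when
#'   present.
#' @examples
#' parse_rle("bob$2bo$3o!")  # the 5-cell glider
#' parse_rle("2o$2o!")       # the 4-cell block
#' @export
parse_rle <- function(text, name = "") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  if (length(lines) == 0L) lines <- ""
  body_lines <- integer(0)
  rule_hint <- NULL
  declared <- NULL
  header_seen <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*#", ln)) next
    if (!header_seen && grepl("^\\s*x\\s*=", ln)) {
      header_seen <- TRUE
      hx <- regmatches(ln, regexec(
        "^\\s*x\\s*=\\s*(\\d+)\\s*,\\s*y\\s*=\\s*(\\d+)\\s*(?:,\\s*rule\\s*=\\s*(\\S+)\\s*)?$",
        ln))[[1]]
      if (length(hx) == 0L)
        rle_error(i, 1L, sprintf("malformed header line '%s'", trimws(ln)))
      declared <- c(as.integer(hx[2]), as.integer(hx[3]))
      if (nzchar(hx[4])) rule_hint <- hx[4]
      next
    }
    body_lines <- c(body_lines, i)
  }
  x <- y <- 0L
  xs <- ys <- integer(0)
  count <- 0L
  have_count <- FALSE
  done <- FALSE
  for (i in body_lines) {
    chars <- strsplit(lines[i], "")[[1]]
    for (j in seq_along(chars)) {
      if (done) break
      ch <- chars[j]
      if (ch %in% c(" ", "\t", "\r")) {
        if (have_count) rle_error(i, j, "run count split by whitespace")
        next
      }
      if (grepl("[0-9]", ch)) {
        count <- count * 10L + as.integer(ch)
        have_count <- TRUE
        next
      }
      n <- if (have_count) count else 1L
      if (have_count && count == 0L) rle_error(i, j, "run count of zero")
      if (ch == "b") {
        x <- x + n
      } else if (ch == "o") {
        xs <- c(xs, x + seq_len(n) - 1L)
        ys <- c(ys, rep.int(y, n))
        x <- x + n
      } else if (ch == "$") {
        y <- y + n
        x <- 0L
      } else if (ch == "!") {
        if (have_count) rle_error(i, j, "run count before '!'")
        done <- TRUE
      } else {
        rle_error(i, j, sprintf("unexpected character '%s'", ch))
      }
      count <- 0L
      have_count <- FALSE
    }
    if (done) break
  }
  if (!done) {
    ll <- if (length(body_lines)) max(body_lines) else length(lines)
    rle_error(ll, nchar(lines[ll]) + 1L, "missing terminating '!'")
  }
  if (!is.null(declared) && length(xs) &&
      (max(xs) >= declared[1L] || max(ys) >= declared[2L]))
    rle_error(body_lines[1L], 1L,
              sprintf("body extends beyond declared extents x = %d, y = %d",
                      declared[1L], declared[2L]))
  life_pattern(cbind(xs, ys), name = name, rule_hint = rule_hint)
}

#' Write a pattern as RLE text
#'
#' Emits a header declaring the bounding-box extents and the rule, then the
#' run-length-encoded body. `parse_rle(write_rle(p))` recovers exactly the
#' cell set of `p`.
#'
#' @param pattern a [life_pattern].
#' @param rule a [life_rule] for the header's rule string.
#' @return RLE text as a single string.
#' @examples
#' cat(write_rle(life_fixture("glider")))
#' @export
write_rle <- function(pattern, rule = life_rule()) {
  stopifnot(inherits(pattern, "life_pattern"))
  cells <- pattern$cells
  if (nrow(cells) == 0L)
    return(sprintf("x = 0, y = 0, rule = %s\n!\n", rule$name))
  w <- max(cells[, 1L]) + 1L
  h <- max(cells[, 2L]) + 1L
  items <- character(0)
  run <- function(n, tag) if (n == 1L) tag else paste0(n, tag)
  rows <- sort(unique(cells[, 2L]))  # populated rows only; blanks become $-runs
  for (i in seq_along(rows)) {
    rx <- sort(cells[cells[, 2L] == rows[i], 1L])
    pos <- 0L
    while (length(rx)) {
      if (rx[1L] > pos) {
        items <- c(items, run(rx[1L] - pos, "b"))
        pos <- rx[1L]
      }
      len <- 1L
      while (len < length(rx) && rx[len + 1L] == rx[len] + 1L) len <- len + 1L
      items <- c(items, run(len, "o"))
      pos <- pos + len
      rx <- rx[-seq_len(len)]
    }
    if (i < length(rows))
      items <- c(items, run(rows[i + 1L] - rows[i], "$"))
  }
  items <- c(items, "!")
  # wrap body at <= 70 characters per line, never splitting an item
  body <- character(0)
  cur <- ""
  for (it in items) {
    if (nchar(cur) + nchar(it) > 70L) {
      body <- c(body, cur)
      cur <- ""
    }
    cur <- paste0(cur, it)
  }
  body <- c(body, cur)
  paste0(sprintf("x = %d, y = %d, rule = %s\n", w, h, rule$name),
         paste(body, collapse = "\n"), "\n")
}

#' Parse a plaintext ".cells" pattern
#'
#' Lines of `.` (dead) and `O` (alive); lines starting with `!` are comments.
#' Blank lines are rows of dead cells, not separators.
#'
#' @param text plaintext (single string or character vector of lines).
#' @param name optional pattern name.
#' @return A [life_pattern].
#' @examples
#' parse_plaintext("OOO")        # horizontal blinker
#' parse_plaintext(".O\n.O\n.O") # vertical blinker
#' @export
parse_plaintext <- function(text, name = "") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[!grepl("^!", lines)]
  xs <- ys <- integer(0)
  for (y in seq_along(lines)) {
    chars <- strsplit(sub("\r$", "", lines[y]), "")[[1]]
    bad <- which(!chars %in% c(".", "O"))
    if (length(bad))
      stop(sprintf("plaintext parse error at line %d, column %d: illegal character '%s'",
                   y, bad[1L], chars[bad[1L]]), call. = FALSE)
    hit <- which(chars == "O")
    xs <- c(xs, hit - 1L)
    ys <- c(ys, rep.int(y - 1L, length(hit)))
  }
  life_pattern(cbind(xs, ys), name = name)
}

#' Write a pattern as plaintext ".cells"
#' @param pattern a [life_pattern].
#' @return plaintext as a single string.
#' @export
write_plaintext <- function(pattern) {
  stopifnot(inherits(pattern, "life_pattern"))
  cells <- pattern$cells
  if (nrow(cells) == 0L) return("")
  w <- max(cells[, 1L]) + 1L
  h <- max(cells[, 2L]) + 1L
  grid <- matrix(".", h, w)
  grid[cbind(cells[, 2L] + 1L, cells[, 1L] + 1L)] <- "O"
  paste0(paste(apply(grid, 1L, paste, collapse = ""), collapse = "\n"), "\n")
}

#' Read a pattern file
#'
#' Dispatches on extension: `.rle` via [parse_rle()], `.cells` (or anything
#' else) via [parse_plaintext()].
#'
#' @param path file path.
#' @return A [life_pattern].
#' @export
read_pattern <- function(path) {
  if (!file.exists(path)) stop(sprintf("pattern file '%s' not found", path))
  txt <- readLines(path, warn = FALSE)
  name <- sub("\\.[^.]*$", "", basename(path))
  if (grepl("\\.rle$", path, ignore.case = TRUE))
    parse_rle(txt, name = name)
  else
    parse_plaintext(txt, name = name)
}

# canonical forms; RLE strings in the standard Golly/LifeWiki orientations
.FIXTURES <- list(
  block       = "2o$2o!",
  blinker     = "3o!",
  l_tromino   = "o$2o!",
  glider      = "bob$2bo$3o!",
  lwss        = "bo2bo$o$o3bo$4o!",
  mwss        = "2bo$o3bo$5bo$o4bo$b5o!",
  hwss        = "2b2o$o4bo$6bo$o5bo$b6o!",
  r_pentomino = "b2o$2o$bo!"
)

#' Canonical pattern fixtures
#'
#' The embedded library of canonical forms: the 4-cell `block` still life,
#' the 3-cell `blinker` oscillator, the `l_tromino` (which grows a fourth
#' cell and binds into a block), the four known moving forms (`glider`,
#' `lwss`, `mwss`, `hwss` — the light-, middle- and heavy-weight spaceships),
#' and the long-lived `r_pentomino` methuselah.
#'
#' @param name one of `"block"`, `"blinker"`, `"l_tromino"`, `"glider"`,
#'   `"lwss"`, `"mwss"`, `"hwss"`, `"r_pentomino"`.
#' @return A [life_pattern].
#' @examples
#' life_fixture("block")
#' classify_exact(life_fixture("glider"))
#' @export
life_fixture <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!name %in% names(.FIXTURES))
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(.FIXTURES), collapse = ", ")))
  parse_rle(.FIXTURES[[name]], name = name)
}
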