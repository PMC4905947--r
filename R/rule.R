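#' Totalistic birth/survival rule
#'
#' A Life-family rule is given by two sets of Moore-neighbourhood counts: an
#' empty cell becomes live when its live-neighbour count is in `birth`, and a
#' live cell stays live when its count is in `survival`. The default is
#' Conway's rule B3/S23: birth on exactly three neighbours; survival on two or
#' three; death otherwise, by isolation (one neighbour or none) or
#' overpopulation (four or more).
#'
#' @param birth integer vector of neighbour counts (each in 0..8) that create
#'   a cell.
#' @param survival integer vector of neighbour counts (each in 0..8) that keep
#'   a live cell alive.
#' @param name optional label; defaults to B/S notation, e.g. `"B3/S23"`.
#' @return An object of class `life_rule` with elements `birth`, `survival`,
#'   `name`.
#' @examples
#' life_rule()              # Conway's B3/S23
#' life_rule(3, c(2, 3, 4)) # a more permissive variant
#' @seealso [parse_rule()] for B/S notation strings.
#' @export
life_rule <- function(birth = 3L, survival = c(2L, 3L), name = NULL) {
  birth <- sort(unique(as.integer(birth)))
  survival <- sort(unique(as.integer(survival)))
  if (length(birth) && (anyNA(birth) || any(birth < 0L | birth > 8L)))
    stop("'birth' counts must be integers in 0..8")
  if (length(survival) && (anyNA(survival) || any(survival < 0L | survival > 8L)))
    stop("'survival' counts must be integers in 0..8")
  if (is.null(name))
    name <- sprintf("B%s/S%s", paste(birth, collapse = ""),
                    paste(survival, collapse = ""))
  structure(list(birth = birth, survival = survival, name = name),
            class = "life_rule")
}

#' Parse a rule string in B/S notation
#'
#' @param text a string like `"B3/S23"` (case-insensitive). Unknown notations
#'   are rejected rather than guessed.
#' @return A [life_rule()].
#' @examples
#' parse_rule("B3/S23")
#' parse_rule("B36/S23") # HighLife
#' @export
parse_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^[Bb]([0-8]*)/[Ss]([0-8]*)$", text))[[1]]
  if (length(m) != 3L)
    stop(sprintf("cannot parse rule string '%s'; expected B/S notation like 'B3/S23'",
                 text))
  digits <- function(s) if (nzchar(s)) as.integer(strsplit(s, "")[[1]]) else integer(0)
  life_rule(digits(m[2]), digits(m[3]))
}

#' @export
format.life_rule <- function(x, ...) x$name

#' @export
print.life_rule <- function(x, ...) {
  cat(sprintf("<life_rule> %s  (birth: {%s}; survival: {%s})\n", x$name,
              paste(x$birth, collapse = ","), paste(x$survival, collapse = ",")))
  invisible(x)
}
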