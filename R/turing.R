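# Linear stability of an m-morphogen reaction-diffusion system on a ring of
# N cells. Perturbations about the homogeneous equilibrium decompose into
# discrete Fourier modes; the circulant coupling makes mode k's dynamics
# governed by J - 4 sin^2(pi k / N) diag(mu), with J the reaction Jacobian
# and mu the cell-to-cell exchange rates. Each mode is classed on Turing's
# two axes: stationary vs oscillatory (dominant eigenvalue real vs complex)
# and extremely-long / extremely-short / finite wavelength (position of the
# wavenumber k on the ring).

#' Reaction-diffusion model on a ring of cells
#'
#' @param jacobian m x m real matrix: the reaction terms linearized at the
#'   homogeneous equilibrium; entry (i, j) is the sensitivity of morphogen
#'   i's production rate to morphogen j.
#' @param diffusion length-m vector of nonnegative cell-to-cell exchange
#'   rates, one per morphogen.
#' @param n_cells number of cells N on the ring (>= 3).
#' @return An object of class `ring_model`.
#' @examples
#' ring_model(diag(c(-1, -2)), c(0.1, 1), n_cells = 12)
#' @export
ring_model <- function(jacobian, diffusion, n_cells) {
  jacobian <- as.matrix(jacobian)
  m <- nrow(jacobian)
  if (ncol(jacobian) != m || !is.numeric(jacobian) || anyNA(jacobian))
    stop("'jacobian' must be a square real matrix")
  diffusion <- as.numeric(diffusion)
  if (length(diffusion) != m || any(diffusion < 0) || anyNA(diffusion))
    stop("'diffusion' must be m nonnegative exchange rates")
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells < 3L) stop("'n_cells' must be at least 3")
  structure(list(jacobian = jacobian, diffusion = diffusion,
                 n_cells = n_cells, n_morphogens = m),
            class = "ring_model")
}

#' @export
print.ring_model <- function(x, ...) {
  cat(sprintf("<ring_model> %d morphogens on a ring of %d cells\n",
              x$n_morphogens, x$n_cells))
  cat("reaction Jacobian:\n"); print(x$jacobian)
  cat("diffusion: ", paste(signif(x$diffusion, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Linearized dynamics of one ring mode
#'
#' Mode `k`'s perturbation evolves under
#' `J - 4 sin^2(pi k / N) diag(diffusion)`. At `k = 0` diffusion drops out
#' entirely; at `k = N/2` (N even) damping is maximal.
#'
#' @param model a [ring_model()].
#' @param k wavenumber, integer in `0..N-1`.
#' @return An m x m real matrix.
#' @export
mode_matrix <- function(model, k) {
  stopifnot(inherits(model, "ring_model"))
  k <- as.integer(k)
  if (is.na(k) || k < 0L || k >= model$n_cells)
    stop(sprintf("wavenumber k must lie in 0..%d", model$n_cells - 1L))
  s <- 4 * sin(pi * k / model$n_cells)^2
  model$jacobian - diag(s * model$diffusion, model$n_morphogens)
}

wavelength_class <- function(k, n, long_frac, short_frac) {
  keff <- min(k, n - k)
  if (k == 0L || keff / n <= long_frac) "extremely_long"
  else if (keff == n %/% 2L || keff / n >= short_frac) "extremely_short"
  else "finite"
}

#' Classify one mode of the ring
#'
#' Computes the eigenvalues of [mode_matrix()] and classes the mode on
#' Turing's two axes. Stability comes from the sign of the largest real part
#' against `growth_tol`; the temporal class is `oscillatory` when the
#' dominant eigenvalue has imaginary part beyond `imag_tol` and `stationary`
#' otherwise. Both tolerances are taken relative to the mode matrix's
#' Frobenius norm. The wavelength class places `k` on the ring: `k = 0` (or
#' `k/N` within `long_frac`) is extremely long, `k = floor(N/2)` (or within
#' `short_frac` of it) extremely short, anything between is finite.
#'
#' @param model a [ring_model()].
#' @param k wavenumber in `0..N-1`.
#' @param growth_tol,imag_tol positive tolerances relative to the matrix
#'   norm; default `1e-9`.
#' @param long_frac,short_frac wavelength-class boundaries on `k/N`
#'   (defaults 0.05 and 0.45; the qualitative categories carry no canonical
#'   numeric boundary, so these are configurable).
#' @return A `ring_mode`: `k`, `eigenvalues`, `max_re`, `temporal_class`
#'   (`stationary`/`oscillatory`), `stability`
#'   (`growing`/`decaying`/`marginal`), `wavelength_class`.
#' @examples
#' m <- ring_model(matrix(c(0, 1, -1, 0), 2), c(0, 0), n_cells = 8)
#' classify_mode(m, 1) # oscillatory, marginal (eigenvalues +/- i)
#' @export
classify_mode <- function(model, k, growth_tol = 1e-9, imag_tol = 1e-9,
                          long_frac = 0.05, short_frac = 0.45) {
  stopifnot(growth_tol > 0, imag_tol > 0)
  M <- mode_matrix(model, k)
  ev <- eigen(M, only.values = TRUE)$values
  scale <- max(1, norm(M, "F"))
  dom <- ev[which.max(Re(ev))]
  max_re <- Re(dom)
  stability <- if (max_re > growth_tol * scale) "growing"
  else if (max_re < -growth_tol * scale) "decaying"
  else "marginal"
  temporal <- if (abs(Im(dom)) > imag_tol * scale) "oscillatory"
  else "stationary"
  structure(list(k = as.integer(k), eigenvalues = ev, max_re = max_re,
                 temporal_class = temporal, stability = stability,
                 wavelength_class = wavelength_class(as.integer(k),
                                                     model$n_cells,
                                                     long_frac, short_frac)),
            class = "ring_mode")
}

#' @export
print.ring_mode <- function(x, ...) {
  cat(sprintf("<ring_mode> k = %d: %s, %s, %s wavelength (max Re = %.6g)\n",
              x$k, x$temporal_class, x$stability,
              sub("_", " ", sub("extremely_", "extremely ", x$wavelength_class)),
              x$max_re))
  invisible(x)
}

#' Classify every mode of the ring and find the dominant one
#'
#' Evaluates [classify_mode()] for every wavenumber `k = 0..N-1` (using the
#' `k` and `N - k` conjugacy of the circulant coupling, which makes those two
#' modes identical) and reports the dominant mode: the one with the largest
#' real-part eigenvalue, ties broken toward the smallest `k`. The dominant
#' mode's class is the system's class — a growing stationary mode is a
#' Turing (pattern-forming) instability, a growing oscillatory mode a wave
#' instability.
#'
#' @inheritParams classify_mode
#' @return A `ring_stability`: list with `modes` (data frame over all `k`
#'   with columns `k`, `max_re`, `dominant_im`, `temporal_class`,
#'   `stability`, `wavelength_class`), `dominant` (a `ring_mode`), and the
#'   `model`.
#' @examples
#' m <- ring_model(diag(c(-1, -2)), c(0.1, 1), n_cells = 12)
#' classify_system(m)$dominant # decaying: the homogeneous state persists
#' @export
classify_system <- function(model, growth_tol = 1e-9, imag_tol = 1e-9,
                            long_frac = 0.05, short_frac = 0.45) {
  n <- model$n_cells
  half <- n %/% 2L
  base <- lapply(0:half, classify_mode, model = model,
                 growth_tol = growth_tol, imag_tol = imag_tol,
                 long_frac = long_frac, short_frac = short_frac)
  results <- vector("list", n)
  for (k in 0:(n - 1L)) {
    src <- base[[min(k, n - k) + 1L]]
    src$k <- k
    results[[k + 1L]] <- src
  }
  modes <- data.frame(
    k = 0:(n - 1L),
    max_re = vapply(results, `[[`, 0, "max_re"),
    dominant_im = vapply(results, function(r) {
      Im(r$eigenvalues[which.max(Re(r$eigenvalues))])
    }, 0),
    temporal_class = vapply(results, `[[`, "", "temporal_class"),
    stability = vapply(results, `[[`, "", "stability"),
    wavelength_class = vapply(results, `[[`, "", "wavelength_class"),
    stringsAsFactors = FALSE)
  dominant <- results[[which.max(modes$max_re)]]  # ties -> smallest k
  structure(list(model = model, modes = modes, results = results,
                 dominant = dominant),
            class = "ring_stability")
}

#' @export
print.ring_stability <- function(x, ...) {
  cat(sprintf("<ring_stability> %d morphogens, ring of %d cells\n",
              x$model$n_morphogens, x$model$n_cells))
  cat("dominant mode: "); print(x$dominant)
  invisible(x)
}

#' @export
as.data.frame.ring_stability <- function(x, ...) x$modes

#' Write a per-mode classification table as CSV
#' @param system a `ring_stability` from [classify_system()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mode_csv <- function(system, path) {
  utils::write.csv(system$modes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Random search for oscillatory finite-wavelength instabilities
#'
#' Samples random ring models — Jacobian entries uniform on `[-1, 1]`,
#' diffusion rates uniform on `[0, 1]` — and counts how many have a dominant
#' mode that is growing, oscillatory, and of finite wavelength. With two
#' morphogens and diagonal diffusion the count is zero: among modes with a
#' complex dominant eigenvalue the real part is half the trace, which
#' diffusion only lowers, so the uniform (`k = 0`) mode always dominates any
#' oscillatory finite-wavelength candidate. Three or more morphogens admit
#' such modes, and the search locates examples empirically.
#'
#' @param m number of morphogens.
#' @param n_samples number of random models to draw.
#' @param seed RNG seed.
#' @param n_cells ring size for every sampled model, default 20.
#' @param keep number of hit models to return as examples, default 1.
#' @inheritParams classify_mode
#' @return A list with `count` (number of hits), `n_samples`, and `examples`
#'   (up to `keep` hit [ring_model()]s, each with its dominant `ring_mode`
#'   attached as attribute `"dominant"`).
#' @examples
#' scan_for_oscillatory_finite(1, 100, seed = 1)$count # 0: real scalar modes
#' @export
scan_for_oscillatory_finite <- function(m, n_samples, seed = 1L,
                                        n_cells = 20L, keep = 1L,
                                        growth_tol = 1e-9, imag_tol = 1e-9,
                                        long_frac = 0.05, short_frac = 0.45) {
  stopifnot(m >= 1, n_samples >= 1)
  n_cells <- as.integer(n_cells)
  count <- 0L
  examples <- list()
  # distinct mode dampings: k and N-k are conjugate, so 0..floor(N/2) suffices
  half <- n_cells %/% 2L
  svals <- 4 * sin(pi * (0:half) / n_cells)^2
  with_seed(seed, {
    for (i in seq_len(n_samples)) {
      J <- matrix(stats::runif(m * m, -1, 1), m, m)
      mu <- stats::runif(m, 0, 1)
      # locate the dominant wavenumber (ties -> smallest k), then classify it
      best_re <- -Inf
      best_k <- 0L
      for (j in seq_along(svals)) {
        ev <- eigen(J - diag(svals[j] * mu, m), only.values = TRUE)$values
        re <- max(Re(ev))
        if (re > best_re) {
          best_re <- re
          best_k <- j - 1L
        }
      }
      model <- ring_model(J, mu, n_cells)
      dom <- classify_mode(model, best_k, growth_tol = growth_tol,
                           imag_tol = imag_tol, long_frac = long_frac,
                           short_frac = short_frac)
      if (dom$stability == "growing" && dom$temporal_class == "oscillatory" &&
          dom$wavelength_class == "finite") {
        count <- count + 1L
        if (length(examples) < keep) {
          attr(model, "dominant") <- dom
          examples[[length(examples) + 1L]] <- model
        }
      }
    }
  })
  list(count = count, n_samples = as.integer(n_samples), examples = examples)
}
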