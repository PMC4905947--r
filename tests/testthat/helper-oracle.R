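# Independent dense-grid oracle: a naive boolean-matrix Life engine used to
# cross-check the sparse candidate-set engine. Kept deliberately simple and
# separate from the package internals.

# neighbour counts by shifting the matrix in all 8 directions
dense_neighbors <- function(mat, wrap = TRUE) {
  h <- nrow(mat)
  w <- ncol(mat)
  n <- matrix(0L, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0L && dy == 0L) next
    if (wrap) {
      ri <- ((seq_len(h) - 1L + dy) %% h) + 1L
      ci <- ((seq_len(w) - 1L + dx) %% w) + 1L
      n <- n + mat[ri, ci]
    } else {
      sh <- matrix(0L, h, w)
      rs <- seq_len(h) + dy
      cs <- seq_len(w) + dx
      okr <- rs >= 1L & rs <= h
      okc <- cs >= 1L & cs <= w
      sh[okr, okc] <- mat[rs[okr], cs[okc], drop = FALSE]
      n <- n + sh
    }
  }
  n
}

dense_step <- function(mat, birth = 3L, survival = c(2L, 3L), wrap = TRUE) {
  n <- dense_neighbors(mat, wrap)
  res <- (mat == 1L & matrix(n %in% survival, nrow(mat))) |
         (mat == 0L & matrix(n %in% birth, nrow(mat)))
  mode(res) <- "integer"
  res
}

# rows index y, columns x; cell (x, y) -> mat[y + 1, x + 1]
cells_to_dense <- function(cells, width, height, x0 = 0L, y0 = 0L) {
  mat <- matrix(0L, height, width)
  if (nrow(cells)) mat[cbind(cells[, 2L] - y0 + 1L, cells[, 1L] - x0 + 1L)] <- 1L
  mat
}

dense_to_cells <- function(mat, x0 = 0L, y0 = 0L) {
  idx <- which(mat == 1L, arr.ind = TRUE)
  cbind(x = idx[, 2L] - 1L + x0, y = idx[, 1L] - 1L + y0)
}

# sorted packed-key representation for set comparison
cellset <- function(cells) {
  if (nrow(cells) == 0L) return(numeric(0))
  unname(sort((cells[, 1L] + 2^20) * 2^21 + (cells[, 2L] + 2^20)))
}

shift_cells <- function(cells, dx, dy) cbind(cells[, 1L] + dx, cells[, 2L] + dy)

random_soup_cells <- function(width, height, density, seed) {
  set.seed(seed)
  live <- runif(width * height) < density
  cbind(x = rep(0:(width - 1L), times = height)[live],
        y = rep(0:(height - 1L), each = width)[live])
}

# 8 square symmetries as (x, y) -> (x', y') cell-matrix transforms
square_symmetries <- list(
  identity = function(c) c,
  rot90    = function(c) cbind(-c[, 2L], c[, 1L]),
  rot180   = function(c) cbind(-c[, 1L], -c[, 2L]),
  rot270   = function(c) cbind(c[, 2L], -c[, 1L]),
  flip_x   = function(c) cbind(-c[, 1L], c[, 2L]),
  flip_y   = function(c) cbind(c[, 1L], -c[, 2L]),
  diag     = function(c) cbind(c[, 2L], c[, 1L]),
  antidiag = function(c) cbind(-c[, 2L], -c[, 1L])
)
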