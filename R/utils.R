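# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", globalenv(), ifnotfound = NULL))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

# Matrix shifted by (dy, dx) with edge replication (out-of-range rows/cols
# clamped to the border).
shift_replicate <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Central differences with replicated edges; returns d/dx (columns) and
# d/dy (rows) of a matrix field. Pixel spacing 1.
grad_central <- function(m) {
  gx <- (shift_replicate(m, 0L, 1L) - shift_replicate(m, 0L, -1L)) / 2
  gy <- (shift_replicate(m, 1L, 0L) - shift_replicate(m, -1L, 0L)) / 2
  list(gx = gx, gy = gy)
}

as_contour_tbl <- function(x, y, closed = TRUE) {
  tibble::tibble(point_index = seq_along(x) - 1L, x = as.numeric(x),
                 y = as.numeric(y)) |>
    structure(closed = closed)
}

contour_points <- function(contour) {
  cbind(contour$x, contour$y)
}
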