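# Contour/mask agreement metrics and the mask <-> contour plumbing.

# Label 4-connected components by iterative min-propagation (masks here are
# compact blobs, so few sweeps are needed).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nb <- pmin(shift_replicate(lab_or_inf(lab), 0L, 1L),
               shift_replicate(lab_or_inf(lab), 0L, -1L),
               shift_replicate(lab_or_inf(lab), 1L, 0L),
               shift_replicate(lab_or_inf(lab), -1L, 0L),
               lab_or_inf(lab))
    new <- lab
    new[mask] <- nb[mask]
    if (identical(new, lab)) break
    lab <- new
  }
  lab[!mask] <- 0L
  lab
}
lab_or_inf <- function(lab) {
  lab[lab == 0L] <- .Machine$integer.max
  lab
}

largest_component <- function(mask) {
  lab <- label_components(mask)
  tab <- tabulate(lab[lab > 0])
  mask & (lab == which.max(tab))
}

#' Extract the boundary contour of a binary mask
#'
#' Traces the 0.5 iso-level boundary of the largest 4-connected foreground
#' component as a closed polygon along pixel edges (vertices at half-integer
#' pixel coordinates), oriented counter-clockwise (positive shoelace area in
#' the stored x/y frame).
#'
#' @param mask logical or 0/1 matrix with at least one foreground pixel.
#' @return A contour tibble with columns `point_index`, `x`, `y`.
#' @export
mask_to_contour <- function(mask) {
  mask <- mask != 0
  if (!any(mask)) abort("empty mask: no contour to extract")
  mask <- largest_component(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask, arr.ind = TRUE)
  r <- fg[, 1]; cc <- fg[, 2]
  bg_at <- function(dr, dc) {
    rr <- r + dr; ccc <- cc + dc
    out <- rr < 1 | rr > nr | ccc < 1 | ccc > nc
    inb <- !out
    out[inb] <- !mask[cbind(rr[inb], ccc[inb])]
    out
  }
  # directed boundary edges (x = col - 1, y = row - 1); each fg pixel
  # contributes its exposed sides, chained head-to-tail into loops
  seg <- list()
  add <- function(keep, x1, y1, x2, y2) {
    if (any(keep)) seg[[length(seg) + 1L]] <<- cbind(x1[keep], y1[keep],
                                                     x2[keep], y2[keep])
  }
  x <- cc - 1; y <- r - 1
  add(bg_at(-1L, 0L), x - 0.5, y - 0.5, x + 0.5, y - 0.5)  # top, +x
  add(bg_at(0L, 1L), x + 0.5, y - 0.5, x + 0.5, y + 0.5)   # right, +y
  add(bg_at(1L, 0L), x + 0.5, y + 0.5, x - 0.5, y + 0.5)   # bottom, -x
  add(bg_at(0L, -1L), x - 0.5, y + 0.5, x - 0.5, y - 0.5)  # left, -y
  seg <- do.call(rbind, seg)
  key <- function(x, y) paste(round(2 * x), round(2 * y))
  from <- key(seg[, 1], seg[, 2])
  lookup <- split(seq_len(nrow(seg)), from)
  used <- rep(FALSE, nrow(seg))
  loops <- list()
  for (s0 in seq_len(nrow(seg))) {
    if (used[s0]) next
    path_x <- seg[s0, 1]; path_y <- seg[s0, 2]
    cur <- s0
    repeat {
      used[cur] <- TRUE
      path_x <- c(path_x, seg[cur, 3]); path_y <- c(path_y, seg[cur, 4])
      nxt <- lookup[[key(seg[cur, 3], seg[cur, 4])]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0L) break
      cur <- nxt[1L]
    }
    loops[[length(loops) + 1L]] <- cbind(path_x, path_y)
  }
  perim <- vapply(loops, nrow, 1L)
  loop <- loops[[which.max(perim)]]
  loop <- loop[-nrow(loop), , drop = FALSE]  # drop repeated closing vertex
  if (polygon_area(loop[, 1], loop[, 2]) < 0) loop <- loop[rev(seq_len(nrow(loop))), ]
  as_contour_tbl(loop[, 1], loop[, 2])
}

#' Resample a polyline/polygon to a maximum point spacing
#'
#' Subdivides every segment so consecutive points are at most `spacing`
#' apart; original vertices are always retained.
#'
#' @param pts two-column matrix or contour tibble of `(x, y)` points.
#' @param spacing maximum spacing between consecutive output points.
#' @param closed treat the input as a closed polygon.
#' @return A two-column matrix of resampled points.
#' @export
resample_polyline <- function(pts, spacing = 1, closed = TRUE) {
  if (is.data.frame(pts)) pts <- contour_points(pts)
  n <- nrow(pts)
  idx <- if (closed) c(seq_len(n), 1L) else seq_len(n)
  out <- list()
  for (k in seq_len(length(idx) - 1L)) {
    p <- pts[idx[k], ]; q <- pts[idx[k + 1L], ]
    len <- sqrt(sum((q - p)^2))
    m <- max(1L, ceiling(len / spacing))
    t0 <- (seq_len(m) - 1L) / m
    out[[k]] <- cbind(p[1] + t0 * (q[1] - p[1]), p[2] + t0 * (q[2] - p[2]))
  }
  res <- do.call(rbind, out)
  if (!closed) res <- rbind(res, pts[n, , drop = FALSE])
  unname(res)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 when both masks are empty (reported
#' with a message).
#'
#' @param a,b logical or 0/1 matrices of the same shape.
#' @return A number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) abort("mask shapes differ")
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    inform("both masks empty: Dice defined as 1")
    return(1)
  }
  2 * sum(a & b) / denom
}

pairwise_min_dists <- function(A, B) {
  # for each row of A, the distance to the nearest row of B (chunked)
  min_dist_to_points(A[, 1], A[, 2], B[, 1], B[, 2])
}

#' Mean sum of squared nearest-point distances between contours
#'
#' Symmetric form on the contour vertices as given:
#' `1/2 [ mean_p min_q ||p - q||^2 + mean_q min_p ||p - q||^2 ]`.
#'
#' @param a,b contour tibbles or two-column point matrices.
#' @return A non-negative number (squared pixels).
#' @export
mssd <- function(a, b) {
  A <- if (is.data.frame(a)) contour_points(a) else as.matrix(a)
  B <- if (is.data.frame(b)) contour_points(b) else as.matrix(b)
  if (nrow(A) == 0L || nrow(B) == 0L) abort("empty contour")
  (mean(pairwise_min_dists(A, B)^2) + mean(pairwise_min_dists(B, A)^2)) / 2
}

#' Hausdorff distance between contours
#'
#' `max(directed(a, b), directed(b, a))` with
#' `directed(a, b) = max_p min_q ||p - q||` over contour points. By default
#' both contours are resampled to at most 1 px spacing (vertices retained)
#' so vertex density does not bias the result.
#'
#' @param a,b contour tibbles or two-column point matrices.
#' @param resample resample both contours to <= 1 px spacing first.
#' @return A non-negative number (pixels).
#' @export
hausdorff <- function(a, b, resample = TRUE) {
  A <- if (is.data.frame(a)) contour_points(a) else as.matrix(a)
  B <- if (is.data.frame(b)) contour_points(b) else as.matrix(b)
  if (nrow(A) == 0L || nrow(B) == 0L) abort("empty contour")
  if (resample && nrow(A) >= 3L) A <- resample_polyline(A, 1)
  if (resample && nrow(B) >= 3L) B <- resample_polyline(B, 1)
  max(max(pairwise_min_dists(A, B)), max(pairwise_min_dists(B, A)))
}

#' Rasterize a closed contour to a binary mask
#'
#' Pixel centers (0-based `x = col`, `y = row`) inside the polygon become
#' foreground.
#'
#' @param contour contour tibble or two-column point matrix.
#' @param shape `c(rows, cols)` of the output mask.
#' @return A logical matrix.
#' @export
contour_to_mask <- function(contour, shape) {
  P <- if (is.data.frame(contour)) contour_points(contour) else as.matrix(contour)
  nr <- shape[1]; nc <- shape[2]
  px <- rep(seq_len(nc) - 1, each = nr)
  py <- rep(seq_len(nr) - 1, times = nc)
  matrix(points_in_polygon(px, py, P[, 1], P[, 2]), nr, nc)
}

#' Per-frame agreement report between two contour series
#'
#' Computes Dice (via rasterization), MSSD and Hausdorff for each common
#' frame of two contour series tibbles (`frame`, `point_index`, `x`, `y`)
#' plus summary rows (min, max, mean).
#'
#' @param pred,truth contour-series tibbles.
#' @param shape raster shape `c(rows, cols)` used for the Dice overlap.
#' @return A tibble with columns `frame`, `dsc`, `mssd`, `hausdorff`;
#'   summary rows carry `frame` values `"min"`, `"max"`, `"mean"`.
#' @export
evaluate_contour_series <- function(pred, truth, shape) {
  frames <- intersect(unique(pred$frame), unique(truth$frame))
  rows <- purrr::map(frames, function(f) {
    cp <- pred[pred$frame == f, ]
    ct <- truth[truth$frame == f, ]
    tibble::tibble(
      frame = as.character(f),
      dsc = dice(contour_to_mask(cp, shape), contour_to_mask(ct, shape)),
      mssd = mssd(cp, ct),
      hausdorff = hausdorff(cp, ct)
    )
  })
  per <- dplyr::bind_rows(rows)
  summ <- tibble::tibble(
    frame = c("min", "max", "mean"),
    dsc = c(min(per$dsc), max(per$dsc), mean(per$dsc)),
    mssd = c(min(per$mssd), max(per$mssd), mean(per$mssd)),
    hausdorff = c(min(per$hausdorff), max(per$hausdorff), mean(per$hausdorff))
  )
  dplyr::bind_rows(per, summ)
}
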