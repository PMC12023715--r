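# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Pixel coordinates (row, col), 1-based, of a disc of given area centred at
# (cy, cx) within an H x W frame. area is the target footprint in px^2; the
# rendered pixel count differs by at most a one-pixel discretization ring.
#' @keywords internal
#' @noRd
disc_pixels <- function(cy, cx, area, h, w) {
  r <- sqrt(area / pi)
  rows <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  grid <- expand.grid(row = rows, col = cols)
  keep <- (grid$row - cy)^2 + (grid$col - cx)^2 <= r^2
  as.matrix(grid[keep, , drop = FALSE])
}

# Logical H x W mask from a (row, col) pixel matrix.
#' @keywords internal
#' @noRd
pixels_to_mask <- function(pixels, h, w) {
  m <- matrix(FALSE, h, w)
  m[pixels[, 1L] + (pixels[, 2L] - 1L) * h] <- TRUE
  m
}

# Circular binary kernel of pixel radius r (pixels with centre distance <= r).
#' @keywords internal
#' @noRd
circular_kernel <- function(r) {
  r <- as.integer(r)
  sz <- 2L * r + 1L
  d2 <- outer((-r):r, (-r):r, function(a, b) a^2 + b^2)
  matrix(as.numeric(d2 <= r^2), sz, sz)
}

# 2D convolution preserving matrix class (EBImage::filter2 returns an Image).
#' @keywords internal
#' @noRd
convolve2 <- function(img, kernel, boundary = "replicate") {
  out <- EBImage::filter2(img, kernel, boundary = boundary)
  matrix(as.numeric(out), nrow(img), ncol(img))
}

# 8-connected component labelling of a logical matrix, ImageJ-style.
# Row runs are merged with union-find; returns an integer label matrix
# (0 = background). EBImage::bwlabel is 4-connected, hence this routine.
#' @keywords internal
#' @noRd
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  # runs along columns of each row: work row-wise for (row, col) convention
  runs <- list(); nrun <- 0L
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  for (i in seq_len(h)) {
    x <- mask[i, ]
    if (!any(x)) next
    d <- diff(c(FALSE, x, FALSE))
    starts <- which(d == 1L); ends <- which(d == -1L) - 1L
    run_row <- c(run_row, rep(i, length(starts)))
    run_s <- c(run_s, starts); run_e <- c(run_e, ends)
  }
  n <- length(run_row)
  if (n == 0L) return(labels)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  # merge runs in adjacent rows whose column spans touch within +/-1 (8-conn)
  for (a in seq_len(n)) {
    nbr <- which(run_row == run_row[a] + 1L &
                 run_s <= run_e[a] + 1L & run_e >= run_s[a] - 1L)
    for (b in nbr) union_(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))
  for (a in seq_len(n)) labels[run_row[a], run_s[a]:run_e[a]] <- ids[a]
  labels
}

# Linear indices into an H x W x T array for a (row, col) pixel matrix at all T.
#' @keywords internal
#' @noRd
pixel_frame_index <- function(pixels, h, w, t) {
  pix <- pixels[, 1L] + (pixels[, 2L] - 1L) * h
  outer(pix, (seq_len(t) - 1L) * h * w, "+")
}
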