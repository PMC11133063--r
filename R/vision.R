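# Low-level image operations used by the visual-odometry and rendering code.
# Images are grayscale matrices in [0, 1], height x width (row = y, col = x);
# pixel centers are at integer coordinates with (1, 1) top-left.

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

conv_sep <- function(img, kx, ky = kx) {
  .conv_sep_cpp(img, as.numeric(kx), as.numeric(ky))
}

#' Sample an image bilinearly at continuous positions
#'
#' @param img grayscale matrix (height x width).
#' @param x,y pixel coordinates ((1, 1) = center of the top-left pixel).
#' @param fill value returned outside the image.
#' @return numeric vector of sampled values.
#' @export
bilinear_sample <- function(img, x, y, fill = 0) {
  .bilinear_sample_cpp(img, as.numeric(x), as.numeric(y), fill)
}

#' Detect Harris corners with subpixel refinement
#'
#' Standard Harris response (k = 0.04) on Gaussian-smoothed gradient
#' products, 3x3 non-maximum suppression, response threshold relative to the
#' strongest corner, and quadratic subpixel refinement of each maximum.
#'
#' Corners are selected per cell of a spatial grid (strongest first within
#' each cell) so that weakly textured regions still contribute
#' correspondences - without this, a single strongly textured surface can
#' monopolize the budget and starve the motion estimate of parallax cues.
#'
#' @param img grayscale matrix.
#' @param max_corners keypoint budget, spread over the grid cells.
#' @param quality minimum response as a fraction of the maximum response.
#' @param border margin in pixels kept free of detections.
#' @param grid `c(nx, ny)` bucketing grid for spatially balanced selection.
#' @return data.frame with subpixel `x`, `y` and `response`, strongest
#'   first within each grid cell.
#' @export
harris_corners <- function(img, max_corners = 1000, quality = 0.005,
                           border = 10, grid = c(8, 6)) {
  d <- c(-0.5, 0, 0.5)
  ident <- 1
  ix <- conv_sep(img, d, ident)
  iy <- conv_sep(img, ident, d)
  g <- gaussian_kernel(1.2)
  sxx <- conv_sep(ix * ix, g)
  syy <- conv_sep(iy * iy, g)
  sxy <- conv_sep(ix * iy, g)
  resp <- (sxx * syy - sxy^2) - 0.04 * (sxx + syy)^2
  h <- nrow(img); w <- ncol(img)
  thr <- max(quality * max(resp), 0)
  lin <- .local_max_cpp(resp, thr, as.integer(border))
  if (length(lin) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  ys <- ((lin - 1) %% h) + 1
  xs <- ((lin - 1) %/% h) + 1
  rv <- resp[lin]
  # per-cell top-q selection
  cell <- pmin((xs - 1) %/% ceiling(w / grid[1]), grid[1] - 1) * grid[2] +
    pmin((ys - 1) %/% ceiling(h / grid[2]), grid[2] - 1)
  q <- max(1L, ceiling(max_corners / (grid[1] * grid[2])))
  ord <- order(cell, -rv)
  rank_in_cell <- sequence(rle(cell[ord])$lengths)
  keep <- ord[rank_in_cell <= q]
  ys <- ys[keep]; xs <- xs[keep]; rv <- rv[keep]
  # quadratic subpixel refinement on the response surface
  rxm <- resp[cbind(ys, xs - 1)]; rxp <- resp[cbind(ys, xs + 1)]
  rym <- resp[cbind(ys - 1, xs)]; ryp <- resp[cbind(ys + 1, xs)]
  denx <- rxm - 2 * rv + rxp
  deny <- rym - 2 * rv + ryp
  ox <- ifelse(abs(denx) > 1e-12, 0.5 * (rxm - rxp) / denx, 0)
  oy <- ifelse(abs(deny) > 1e-12, 0.5 * (rym - ryp) / deny, 0)
  ox <- pmax(-0.5, pmin(0.5, ox))
  oy <- pmax(-0.5, pmin(0.5, oy))
  data.frame(x = xs + ox, y = ys + oy, response = rv)
}

# Extract normalized square patch descriptors around integer corner
# locations. Returns a list with the descriptor matrix (n x patch^2, rows
# zero-mean unit-norm) and the kept corner rows (corners too close to the
# border are dropped upstream by the harris border margin).
patch_descriptors <- function(img, corners, half = 5) {
  n <- nrow(corners)
  k <- 2 * half + 1
  if (n == 0)
    return(list(desc = matrix(0, 0, k * k), corners = corners))
  h <- nrow(img)
  xi <- round(corners$x); yi <- round(corners$y)
  offs <- as.matrix(expand.grid(dy = -half:half, dx = -half:half))
  # linear indices: (x-1)*h + y for every corner x offset combination
  lin <- outer(yi, offs[, "dy"], `+`) + (outer(xi, offs[, "dx"], `+`) - 1) * h
  desc <- matrix(img[lin], n, k * k)
  desc <- desc - rowMeans(desc)
  nrm <- sqrt(rowSums(desc^2))
  nrm[nrm < 1e-12] <- 1
  list(desc = desc / nrm, corners = corners)
}

# Match descriptors between two frames: mutual nearest neighbour by ZNCC
# score with a displacement gate and minimum-score threshold, then refine
# each match displacement to subpixel accuracy by quadratic interpolation of
# the local ZNCC surface in the second frame.
match_keypoints <- function(img_a, kp_a, img_b, kp_b,
                            max_disp = 80, min_score = 0.6, half = 5,
                            desc_a = NULL, desc_b = NULL) {
  da <- desc_a %||% patch_descriptors(img_a, kp_a, half)
  db <- desc_b %||% patch_descriptors(img_b, kp_b, half)
  na <- nrow(da$corners); nb <- nrow(db$corners)
  empty <- data.frame(xa = numeric(0), ya = numeric(0),
                      xb = numeric(0), yb = numeric(0), score = numeric(0))
  if (na == 0 || nb == 0) return(empty)
  mm <- .match_desc_cpp(da$desc, da$corners$x, da$corners$y,
                        db$desc, db$corners$x, db$corners$y,
                        max_disp, min_score)
  ia <- which(mm$match > 0)
  if (length(ia) == 0) return(empty)
  ib <- mm$match[ia]
  # positions in frame a are the integer template centers so that the
  # ZNCC-refined position in frame b measures the pair displacement directly
  xa <- round(da$corners$x[ia]); ya <- round(da$corners$y[ia])
  xb0 <- as.integer(round(db$corners$x[ib]))
  yb0 <- as.integer(round(db$corners$y[ib]))
  ref <- .refine_match_cpp(img_b, da$desc[ia, , drop = FALSE], xb0, yb0,
                           as.integer(half))
  data.frame(xa = xa, ya = ya, xb = ref$xb, yb = ref$yb,
             score = mm$score[ia])
}
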