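# Low-level raster helpers shared across modules.
#
# Coordinate convention (used everywhere in the package): points are (x, y),
# 0-based, origin at the top-left pixel centre; x runs along columns, y along
# rows, so point (x, y) addresses matrix element [y + 1, x + 1]. Physical
# position in micrometres is (x, y) * pixel_size_um.

#' Convert a foreground pixel count to physical area in mm^2
#'
#' @param mask logical or 0/1 matrix.
#' @param pixel_size_um pixel edge length in micrometres.
#' @return area in mm^2: `sum(mask) * (pixel_size_um / 1000)^2`.
#' @export
mask_area_mm2 <- function(mask, pixel_size_um) {
  stopifnot(pixel_size_um > 0)
  sum(mask != 0) * (pixel_size_um / 1000)^2
}

#' Label connected components of a binary mask
#'
#' 8-connectivity is obtained by labelling 4-connected components and then
#' merging labels that touch diagonally (union-find over the label graph).
#'
#' @param mask logical/0-1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels, 0 = background, 1..n = components.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  if (connectivity == 4 || max(lab) <= 1L) {
    return(lab)
  }
  nl <- max(lab)
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: down-right and down-left
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  ok <- a > 0 & b > 0 & a != b
  if (any(ok)) apply(unique(cbind(a[ok], b[ok])), 1, function(p) union2(p[1], p[2]))
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  ok <- a > 0 & b > 0 & a != b
  if (any(ok)) apply(unique(cbind(a[ok], b[ok])), 1, function(p) union2(p[1], p[2]))
  roots <- vapply(seq_len(nl), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Downsample a matrix by integer block averaging
#'
#' Trailing rows/columns that do not fill a complete block are dropped.
#' @param mat numeric matrix.
#' @param factor integer >= 1.
#' @export
block_average <- function(mat, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1L) return(mat)
  nr <- (nrow(mat) %/% factor) * factor
  nc <- (ncol(mat) %/% factor) * factor
  m <- mat[seq_len(nr), seq_len(nc), drop = FALSE]
  # average over factor x factor blocks
  m <- rowsum(m, rep(seq_len(nr %/% factor), each = factor)) / factor
  m <- t(rowsum(t(m), rep(seq_len(nc %/% factor), each = factor)) / factor)
  m
}

#' Sample a matrix at fractional (x, y) positions
#'
#' @param mat numeric matrix.
#' @param x,y 0-based coordinates (vectors of equal length).
#' @param method "bilinear" or "nearest".
#' @param background value returned outside the matrix domain.
#' @return numeric vector of sampled values.
#' @export
sample_raster <- function(mat, x, y, method = c("bilinear", "nearest"),
                          background = 0) {
  method <- match.arg(method)
  nr <- nrow(mat); nc <- ncol(mat)
  out <- rep(as.numeric(background), length(x))
  if (method == "nearest") {
    xi <- round(x); yi <- round(y)
    ok <- xi >= 0 & xi <= nc - 1 & yi >= 0 & yi <= nr - 1
    out[ok] <- mat[cbind(yi[ok] + 1, xi[ok] + 1)]
    return(out)
  }
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= -1 & x0 <= nc - 1 & y0 >= -1 & y0 <= nr - 1
  # clamp corner indices so edge pixels extrapolate their border value
  cl <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  gx0 <- cl(x0, 0, nc - 1); gx1 <- cl(x0 + 1, 0, nc - 1)
  gy0 <- cl(y0, 0, nr - 1); gy1 <- cl(y0 + 1, 0, nr - 1)
  v00 <- mat[cbind(gy0 + 1, gx0 + 1)]
  v01 <- mat[cbind(gy0 + 1, gx1 + 1)]
  v10 <- mat[cbind(gy1 + 1, gx0 + 1)]
  v11 <- mat[cbind(gy1 + 1, gx1 + 1)]
  val <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  out[ok] <- val[ok]
  out
}

# Add `amount` to `canvas` on the disk of radius r_px centred at (cx, cy)
# (0-based). Returns the modified canvas.
add_disk <- function(canvas, cx, cy, r_px, amount) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  x0 <- max(0, floor(cx - r_px)); x1 <- min(nc - 1, ceiling(cx + r_px))
  y0 <- max(0, floor(cy - r_px)); y1 <- min(nr - 1, ceiling(cy + r_px))
  if (x0 > x1 || y0 > y1) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  dx2 <- (xs - cx)^2
  dy2 <- (ys - cy)^2
  inside <- outer(dy2, dx2, "+") <= r_px^2
  sub <- canvas[ys + 1, xs + 1, drop = FALSE]
  sub[inside] <- sub[inside] + amount
  canvas[ys + 1, xs + 1] <- sub
  canvas
}

# Add `amount` to pixels within width_px/2 of the segment (x0,y0)-(x1,y1).
add_segment <- function(canvas, x0, y0, x1, y1, width_px, amount) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  hw <- width_px / 2
  bx0 <- max(0, floor(min(x0, x1) - hw)); bx1 <- min(nc - 1, ceiling(max(x0, x1) + hw))
  by0 <- max(0, floor(min(y0, y1) - hw)); by1 <- min(nr - 1, ceiling(max(y0, y1) + hw))
  if (bx0 > bx1 || by0 > by1) return(canvas)
  xs <- bx0:bx1; ys <- by0:by1
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / len2))
  d2 <- (px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2
  inside <- d2 <= hw^2
  sub <- canvas[ys + 1, xs + 1, drop = FALSE]
  sub[inside] <- sub[inside] + amount
  canvas[ys + 1, xs + 1] <- sub
  canvas
}

# Add `amount` inside a (possibly rotated) filled ellipse; a_px, b_px are
# semi-axes along the rotated x/y axes, theta in radians.
add_ellipse <- function(canvas, cx, cy, a_px, b_px, theta, amount,
                       assign = FALSE) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  r <- max(a_px, b_px)
  x0 <- max(0, floor(cx - r)); x1 <- min(nc - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(nr - 1, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(canvas)
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs, each = length(ys)) - cx
  py <- rep(ys, times = length(xs)) - cy
  u <- px * cos(theta) + py * sin(theta)
  v <- -px * sin(theta) + py * cos(theta)
  inside <- (u / a_px)^2 + (v / b_px)^2 <= 1
  sub <- canvas[ys + 1, xs + 1, drop = FALSE]
  idx <- matrix(inside, length(ys), length(xs))
  if (assign) sub[idx] <- amount else sub[idx] <- sub[idx] + amount
  canvas[ys + 1, xs + 1] <- sub
  canvas
}

# Smooth Gaussian random field with approximately unit SD, for background
# texture. Deterministic under the caller's RNG state.
smooth_noise_field <- function(nrow, ncol, sigma_px) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  z <- as.matrix(EBImage::gblur(z, sigma = sigma_px))
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  z
}

#' Otsu threshold of a numeric sample
#'
#' Maximises between-class variance over a fixed-bin histogram of the values.
#'
#' @param values numeric vector (non-finite values dropped).
#' @param n_bins histogram resolution.
#' @return threshold on the scale of `values`.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("no finite values for Otsu threshold")
  r <- range(v)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(n_bins, 1L + as.integer((v - r[1]) / diff(r) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  mids[which.max(sigma_b)]
}

#' Skeletonize a binary object by Zhang-Suen thinning
#'
#' Iterative two-subiteration thinning to a 1-pixel-wide skeleton,
#' implemented with whole-matrix shifts.
#'
#' @param mask logical/0-1 matrix (one object or several; thinning is local).
#' @return logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(m == 1L)
  # pad to avoid border handling
  p <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  nr <- nrow(p); nc <- ncol(p)
  shift <- function(x, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north
      p2 <- shift(p, 1, 0);  p3 <- shift(p, 1, -1)
      p4 <- shift(p, 0, -1); p5 <- shift(p, -1, -1)
      p6 <- shift(p, -1, 0); p7 <- shift(p, -1, 1)
      p8 <- shift(p, 0, 1);  p9 <- shift(p, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- p == 1L & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- p == 1L & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        p[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1), drop = FALSE] == 1L
}

# Reduce a thinned skeleton to a minimal 8-connected chain: sequentially
# remove non-endpoint pixels whose on-neighbours remain mutually 8-connected
# without them (8-simple points). Thinning leaves staircase pixels that turn
# one diagonal step into two orthogonal ones; without this reduction the
# (1, sqrt 2) step weights overestimate oblique lines by up to ~18%.
prune_staircase <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  off <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, , drop = FALSE]
  neighbours_connected <- function(on) {
    k <- nrow(on)
    if (k <= 1) return(TRUE)
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      if (max(abs(on[a, ] - on[b, ])) == 1) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[rb] <- ra
      }
    }
    length(unique(vapply(seq_len(k), find, integer(1)))) == 1
  }
  repeat {
    changed <- FALSE
    idx <- which(s == 1L, arr.ind = TRUE)
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; c <- idx[i, 2]
      if (s[r, c] == 0L) next
      nb <- off + matrix(c(r, c), nrow(off), 2, byrow = TRUE)
      ok <- nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc
      nb <- nb[ok, , drop = FALSE]
      on <- nb[s[nb] == 1L, , drop = FALSE]
      if (nrow(on) < 2) next            # endpoints stay
      if (neighbours_connected(on)) {
        s[r, c] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  s
}

#' Path length of a skeleton in pixel units
#'
#' Staircase corners left by thinning are pruned to a minimal 8-connected
#' chain, then 4-neighbour adjacencies count weight 1 and diagonal
#' adjacencies weight sqrt(2); a diagonal step is skipped when the two pixels
#' are already connected through a shared orthogonal neighbour, so corners
#' are not double-counted.
#'
#' @param skel logical matrix (output of [skeletonize()]).
#' @return length in pixels.
#' @export
skeleton_length_px <- function(skel) {
  s <- matrix(as.integer(skel != 0), nrow(skel), ncol(skel))
  if (sum(s) <= 1) return(0)
  s <- prune_staircase(s)
  if (sum(s) <= 1) return(0)
  nr <- nrow(s); nc <- ncol(s)
  n_orth <- sum(s[-nr, ] & s[-1, ]) + sum(s[, -nc] & s[, -1])
  # diagonal pairs not bridged by an orthogonal common neighbour
  dr_pair <- s[-nr, -nc] & s[-1, -1]
  dr_bridge <- s[-nr, -1] | s[-1, -nc]
  dl_pair <- s[-nr, -1] & s[-1, -nc]
  dl_bridge <- s[-nr, -nc] | s[-1, -1]
  n_diag <- sum(dr_pair & !dr_bridge) + sum(dl_pair & !dl_bridge)
  n_orth + sqrt(2) * n_diag
}

# Circular moving-average smoothing of a closed contour (n x 2 points).
smooth_contour <- function(pts, k = 5) {
  n <- nrow(pts)
  if (n <= k) return(pts)
  sm <- vapply(1:2, function(j) {
    v <- c(pts[, j], pts[, j], pts[, j])
    as.numeric(stats::filter(v, rep(1 / k, k))[(n + 1):(2 * n)])
  }, numeric(n))
  sm
}

# Closed-polygon length through an ordered set of contour points (n x 2).
polygon_perimeter <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1), , drop = FALSE])^2))
  sum(d)
}

# Solidity of a pixel set: area / convex-hull area. rows/cols are pixel
# indices (any base); pixel squares are accounted for by a half-pixel pad.
pixel_solidity <- function(rows, cols) {
  n <- length(rows)
  if (n <= 2) return(1)
  pts <- cbind(cols, rows)
  # expand each pixel centre to its 4 corners so the hull covers pixel area
  corners <- rbind(pts + rep(c(-0.5, -0.5), each = n),
                   pts + rep(c(0.5, -0.5), each = n),
                   pts + rep(c(-0.5, 0.5), each = n),
                   pts + rep(c(0.5, 0.5), each = n))
  h <- grDevices::chull(corners)
  hp <- corners[h, , drop = FALSE]
  x <- hp[, 1]; y <- hp[, 2]
  hull_area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (hull_area <= 0) return(1)
  min(1, n / hull_area)
}
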