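# Planar registration: landmark-based affine / thin-plate-spline fits for
# MRI-to-histology ROI transfer, and intensity-based (mutual information)
# affine registration for co-registering adjacent stained sections.
#
# A transform maps MOVING-grid points to FIXED-grid points, (x, y) 0-based.

#' Affine transform from a 3 x 3 homogeneous matrix
#' @param A 3 x 3 matrix, last row (0, 0, 1); determinant must be nonzero.
#' @return object of class `transform2d`.
#' @export
affine_transform <- function(A) {
  stopifnot(is.matrix(A), all(dim(A) == c(3, 3)))
  if (abs(det(A[1:2, 1:2])) < 1e-12) stop("degenerate affine (determinant ~ 0)")
  structure(list(kind = "affine", A = A), class = "transform2d")
}

#' @export
print.transform2d <- function(x, ...) {
  if (x$kind == "affine") {
    cat("<transform2d> affine\n")
    print(signif(x$A, 6))
  } else {
    cat(sprintf("<transform2d> thin-plate spline, %d control points (lambda = %g)\n",
                nrow(x$fwd$ctrl), x$lambda))
  }
  invisible(x)
}

# Thin-plate spline radial basis U(r) = r^2 log(r); U(0) = 0.
tps_u <- function(r2) {
  out <- numeric(length(r2))
  pos <- r2 > 0
  out[pos] <- 0.5 * r2[pos] * log(r2[pos])  # r^2 log r = r^2 * log(r^2)/2
  out
}

# Fit one TPS mapping src (n x 2) -> dst (n x 2). Control-point coordinates
# are normalised (centred, unit RMS radius) before solving, which keeps the
# system well conditioned on pixel-scale grids.
tps_fit_one <- function(src, dst, lambda = 0) {
  n <- nrow(src)
  if (anyDuplicated(src) > 0) stop("duplicate control points for TPS")
  center <- colMeans(src)
  scale <- sqrt(mean((src[, 1] - center[1])^2 + (src[, 2] - center[2])^2))
  if (scale <= 0) stop("degenerate control points for TPS")
  s <- sweep(src, 2, center) / scale
  d2 <- as.matrix(stats::dist(s))^2
  K <- tps_u(d2)
  dim(K) <- c(n, n)
  P <- cbind(1, s)
  L <- rbind(cbind(K + lambda * diag(n), P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- rbind(dst, matrix(0, 3, 2))
  coef <- tryCatch(solve(L, rhs),
                   error = function(e) stop("TPS system is singular: ",
                                            conditionMessage(e)))
  list(ctrl = src, center = center, scale = scale, coef = coef)
}

tps_eval_one <- function(model, pts) {
  n <- nrow(model$ctrl)
  s <- sweep(matrix(as.numeric(pts), ncol = 2), 2, model$center) / model$scale
  ctrl_s <- sweep(model$ctrl, 2, model$center) / model$scale
  d2 <- outer(s[, 1], ctrl_s[, 1], "-")^2 + outer(s[, 2], ctrl_s[, 2], "-")^2
  U <- tps_u(d2)
  dim(U) <- c(nrow(s), n)
  w <- model$coef[seq_len(n), , drop = FALSE]
  a <- model$coef[n + 1:3, , drop = FALSE]
  U %*% w + cbind(1, s) %*% a
}

#' Apply a transform to points
#' @param transform a `transform2d`.
#' @param pts n x 2 matrix of (x, y) points on the moving grid.
#' @param inverse map fixed-grid points back to the moving grid instead.
#' @return n x 2 matrix of mapped points.
#' @export
transform_points <- function(transform, pts, inverse = FALSE) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (transform$kind == "affine") {
    A <- if (inverse) solve(transform$A) else transform$A
    out <- cbind(pts, 1) %*% t(A)
    return(out[, 1:2, drop = FALSE])
  }
  model <- if (inverse) transform$bwd else transform$fwd
  n <- nrow(pts)
  if (n <= 50000L) return(unname(tps_eval_one(model, pts)))
  # chunk large grids to bound the n x n_ctrl basis matrix
  out <- matrix(0, n, 2)
  starts <- seq(1L, n, by = 50000L)
  for (s in starts) {
    e <- min(n, s + 50000L - 1L)
    out[s:e, ] <- tps_eval_one(model, pts[s:e, , drop = FALSE])
  }
  out
}

#' Invert a transform
#'
#' Affine transforms invert exactly; a TPS swaps its forward and backward
#' interpolants (each fitted on the landmark pairs, so the composition is
#' identity at the landmarks and approximate elsewhere).
#' @param transform a `transform2d`.
#' @export
invert_transform <- function(transform) {
  if (transform$kind == "affine") return(affine_transform(solve(transform$A)))
  structure(list(kind = "tps", fwd = transform$bwd, bwd = transform$fwd,
                 lambda = transform$lambda), class = "transform2d")
}

registration_result <- function(transform, rmse_px, method, converged,
                                n_landmarks = NA_integer_,
                                similarity = NA_real_) {
  structure(list(transform = transform, rmse_px = rmse_px, method = method,
                 converged = converged, n_landmarks = n_landmarks,
                 similarity = similarity),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> method=%s, %s=%.4g, converged=%s\n",
              x$method,
              if (x$method == "intensity") "similarity" else "rmse_px",
              if (x$method == "intensity") x$similarity else x$rmse_px,
              x$converged))
  invisible(x)
}

#' Fit a landmark transform (affine least squares or exact TPS)
#'
#' The operating standard is at least 10 landmark pairs; fewer (but >= 3 for
#' affine, >= 4 non-collinear for TPS) produce a warning, not an error.
#'
#' @param landmarks data.frame with columns `x_moving`, `y_moving`,
#'   `x_fixed`, `y_fixed` (see [read_landmarks()]).
#' @param kind `"affine"` (least-squares fit) or `"tps"` (exact interpolant,
#'   bending-energy regulariser `lambda`).
#' @param lambda TPS regularisation (0 = exact interpolation).
#' @param method_tag recorded registration method (`"landmark"`, or
#'   `"manual_fallback"` when the landmarks replace a failed automated run).
#' @return a `registration_result` whose transform maps moving to fixed.
#' @export
fit_landmark_transform <- function(landmarks, kind = c("affine", "tps"),
                                   lambda = 0, method_tag = "landmark") {
  kind <- match.arg(kind)
  mov <- as.matrix(landmarks[, c("x_moving", "y_moving")])
  fix <- as.matrix(landmarks[, c("x_fixed", "y_fixed")])
  n <- nrow(mov)
  if (n < 3) stop("need at least 3 landmark pairs")
  if (anyDuplicated(fix) > 0 && kind == "tps")
    stop("duplicate fixed points for TPS")
  if (n < 10)
    warning(sprintf("only %d landmark pairs; the operating standard is >= 10", n))
  if (kind == "affine") {
    X <- cbind(mov, 1)
    if (qr(X)$rank < 3) stop("collinear landmarks: affine fit is degenerate")
    B <- qr.solve(X, fix)               # 3 x 2
    A <- unname(rbind(t(B), c(0, 0, 1)))
    tf <- affine_transform(A)
  } else {
    fwd <- tps_fit_one(mov, fix, lambda)
    bwd <- tps_fit_one(fix, mov, lambda)
    tf <- structure(list(kind = "tps", fwd = fwd, bwd = bwd, lambda = lambda),
                    class = "transform2d")
  }
  pred <- transform_points(tf, mov)
  # RMS over residual components (2n of them), so sigma-scaled noise gives
  # rmse ~ sigma * sqrt(1 - p / (2n)) for a p-parameter fit
  rmse <- sqrt(mean((pred - fix)^2))
  registration_result(tf, rmse, method_tag, converged = TRUE, n_landmarks = n)
}

#' Warp an image or mask onto an output grid
#'
#' Inverse-mapping resampler: each output (fixed-grid) pixel is pulled from
#' the moving image through the transform's inverse. Masks must use
#' nearest-neighbour interpolation so the output stays strictly binary.
#'
#' @param image numeric matrix, `h x w x 3` array, or logical mask (moving grid).
#' @param transform `transform2d` mapping moving to fixed coordinates.
#' @param output_dim `c(rows, cols)` of the fixed grid.
#' @param interpolation `"bilinear"` (images) or `"nearest"` (masks/labels).
#' @param background fill value outside the moving domain.
#' @return warped raster on the output grid (logical in, logical out).
#' @export
warp_image <- function(image, transform, output_dim,
                       interpolation = c("bilinear", "nearest"),
                       background = 0) {
  interpolation <- match.arg(interpolation)
  was_logical <- is.logical(image)
  nr <- output_dim[1]; nc <- output_dim[2]
  gx <- rep(0:(nc - 1), each = nr)
  gy <- rep(0:(nr - 1), times = nc)
  src <- transform_points(transform, cbind(gx, gy), inverse = TRUE)
  warp1 <- function(mat) {
    v <- sample_raster(mat, src[, 1], src[, 2], method = interpolation,
                       background = background)
    matrix(v, nr, nc)
  }
  if (length(dim(image)) == 3) {
    out <- simplify2array(lapply(1:3, function(k) warp1(image[, , k])))
  } else {
    out <- warp1(matrix(as.numeric(image), nrow(image), ncol(image)))
    if (was_logical) out <- out != 0
  }
  out
}

# --- intensity-based registration -------------------------------------------

# Affine matrix from parameters about image centres:
# p_fixed = R(rot) %*% diag(exp(ls)) %*% (p_mov - c_mov) + c_fix + t
params_to_affine <- function(theta, c_mov, c_fix) {
  tx <- theta[1]; ty <- theta[2]; rot <- theta[3]
  sx <- exp(theta[4]); sy <- exp(theta[5])
  R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2, byrow = TRUE)
  M <- R %*% diag(c(sx, sy))
  off <- c_fix + c(tx, ty) - M %*% c_mov
  rbind(cbind(M, off), c(0, 0, 1))
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Similarity between fixed image and moving image warped by theta.
# Returns list(sim, overlap_frac, nmi).
affine_similarity <- function(theta, moving, fixed, c_mov, c_fix,
                              metric = "mi", n_bins = 32, stride = 1L) {
  A <- tryCatch(params_to_affine(theta, c_mov, c_fix), error = function(e) NULL)
  if (is.null(A) || abs(det(A[1:2, 1:2])) < 1e-9)
    return(list(sim = -Inf, overlap = 0, nmi = 0))
  nr <- nrow(fixed); nc <- ncol(fixed)
  ys <- seq(0, nr - 1, by = stride); xs <- seq(0, nc - 1, by = stride)
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  Ainv <- solve(A)
  src <- cbind(gx, gy, 1) %*% t(Ainv)
  mv <- sample_raster(moving, src[, 1], src[, 2], method = "bilinear",
                      background = NA)
  fv <- fixed[cbind(gy + 1, gx + 1)]
  ok <- !is.na(mv)
  overlap <- mean(ok)
  if (overlap < 1e-3) return(list(sim = -1e3, overlap = overlap, nmi = 0))
  mv <- mv[ok]; fv <- fv[ok]
  if (metric == "ncc") {
    if (stats::sd(mv) == 0 || stats::sd(fv) == 0)
      return(list(sim = 0, overlap = overlap, nmi = 0))
    cc <- stats::cor(mv, fv)
    return(list(sim = cc, overlap = overlap, nmi = abs(cc)))
  }
  qz <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(1L, length(v)))
    pmin(n_bins, 1L + as.integer((v - r[1]) / diff(r) * n_bins))
  }
  bi <- qz(mv); bj <- qz(fv)
  joint <- tabulate(bi + n_bins * (bj - 1L), nbins = n_bins * n_bins)
  pj <- joint / sum(joint)
  hx <- entropy_nats(rowSums(matrix(pj, n_bins)))
  hy <- entropy_nats(colSums(matrix(pj, n_bins)))
  hxy <- entropy_nats(pj)
  mi <- hx + hy - hxy
  nmi <- if (min(hx, hy) > 0) mi / min(hx, hy) else 0
  list(sim = mi, overlap = overlap, nmi = nmi)
}

#' Intensity-based affine registration (multiresolution)
#'
#' Optimises a 5-parameter affine (translation, rotation, per-axis log scale)
#' maximising mutual information (default) or normalised correlation between
#' single-channel images, over a 3-level coarse-to-fine pyramid with a
#' translation grid search at the coarsest level. Intended for co-registering
#' hematoxylin concentration maps of adjacent sections.
#'
#' `converged` is `FALSE` when the final similarity is degenerate: the MI
#' gain over the initial transform is below `gain_min` *and* the normalised
#' MI (MI / min marginal entropy) is below `nmi_min`. Non-converged results
#' signal that a manual landmark fallback is needed.
#'
#' @param moving,fixed single-channel numeric matrices.
#' @param init optional initial `transform2d` (affine).
#' @param config list of options: `metric` ("mi" or "ncc"), `n_bins`,
#'   `levels` (downsampling factors, coarse to fine), `maxit` per level,
#'   `gain_min`, `nmi_min`, `min_overlap`.
#' @return a `registration_result` (method `"intensity"`; `similarity` and
#'   `rmse_px` hold the final similarity value).
#' @export
register_intensity <- function(moving, fixed, init = NULL, config = list()) {
  cfg <- utils::modifyList(list(metric = "mi", n_bins = 32,
                                levels = c(4, 2, 1), maxit = 120,
                                gain_min = 0.05, nmi_min = 0.25,
                                min_overlap = 0.25), config)
  if (length(dim(moving)) != 2 || length(dim(fixed)) != 2)
    stop("register_intensity expects single-channel matrices")
  c_mov_full <- c((ncol(moving) - 1) / 2, (nrow(moving) - 1) / 2)
  c_fix_full <- c((ncol(fixed) - 1) / 2, (nrow(fixed) - 1) / 2)
  theta <- c(0, 0, 0, 0, 0)
  if (!is.null(init)) {
    stopifnot(init$kind == "affine")
    M <- init$A[1:2, 1:2]
    sx <- sqrt(sum(M[, 1]^2)); sy <- sqrt(sum(M[, 2]^2))
    rot <- atan2(M[2, 1], M[1, 1])
    tr <- transform_points(init, matrix(c_mov_full, 1)) - matrix(c_fix_full, 1)
    theta <- c(tr[1], tr[2], rot, log(sx), log(sy))
  }
  init_eval <- affine_similarity(theta, moving, fixed, c_mov_full, c_fix_full,
                                 cfg$metric, cfg$n_bins)
  if (!is.finite(init_eval$sim) && init_eval$overlap < cfg$min_overlap)
    stop("empty overlap between images at the initial transform")
  levels <- sort(unique(pmax(1, as.integer(cfg$levels))), decreasing = TRUE)
  for (li in seq_along(levels)) {
    f <- levels[li]
    mv <- block_average(moving, f); fx <- block_average(fixed, f)
    c_mov <- c((ncol(mv) - 1) / 2, (nrow(mv) - 1) / 2)
    c_fix <- c((ncol(fx) - 1) / 2, (nrow(fx) - 1) / 2)
    th <- c(theta[1] / f, theta[2] / f, theta[3:5])
    obj <- function(p) {
      ev <- affine_similarity(p, mv, fx, c_mov, c_fix, cfg$metric, cfg$n_bins)
      if (ev$overlap < cfg$min_overlap)
        return(1e3 + (cfg$min_overlap - ev$overlap) * 1e3)
      -ev$sim
    }
    if (li == 1) {
      # translation grid search for a robust basin at the coarsest level
      span_x <- max(2, round(ncol(fx) * 0.3))
      span_y <- max(2, round(nrow(fx) * 0.3))
      txs <- seq(-span_x, span_x, by = max(1, round(span_x / 6)))
      tys <- seq(-span_y, span_y, by = max(1, round(span_y / 6)))
      best <- obj(th); best_th <- th
      for (tx in txs) for (ty in tys) {
        cand <- th; cand[1] <- cand[1] + tx; cand[2] <- cand[2] + ty
        v <- obj(cand)
        if (v < best) { best <- v; best_th <- cand }
      }
      th <- best_th
    }
    opt <- stats::optim(th, obj, method = "Nelder-Mead",
                        control = list(maxit = cfg$maxit,
                                       parscale = c(2, 2, 0.05, 0.05, 0.05)))
    th <- opt$par
    theta <- c(th[1] * f, th[2] * f, th[3:5])
  }
  final <- affine_similarity(theta, moving, fixed, c_mov_full, c_fix_full,
                             cfg$metric, cfg$n_bins)
  if (!is.finite(final$sim)) stop("non-finite similarity at final transform")
  gain <- final$sim - init_eval$sim
  converged <- if (cfg$metric == "mi") {
    (is.finite(gain) && gain >= cfg$gain_min) || final$nmi >= cfg$nmi_min
  } else {
    final$nmi >= cfg$nmi_min
  }
  tf <- affine_transform(params_to_affine(theta, c_mov_full, c_fix_full))
  registration_result(tf, rmse_px = final$sim, method = "intensity",
                      converged = converged, similarity = final$sim)
}

#' Transfer MRI-drawn ROIs onto the histology grid
#'
#' Nearest-neighbour warp of each ROI mask through the MRI-to-histology
#' transform; disjointness is re-checked and ROIs that land empty are
#' flagged (all-empty is an error).
#'
#' @param rois [roi_set()] on the transform's moving (MRI) grid.
#' @param transform `transform2d` mapping MRI to histology coordinates.
#' @param histology_dim `c(rows, cols)` of the histology grid.
#' @param pixel_size_um histology pixel size in micrometres.
#' @return a [roi_set()] on the histology grid.
#' @export
transfer_rois <- function(rois, transform, histology_dim, pixel_size_um) {
  warped <- lapply(rois$masks, function(m)
    warp_image(m, transform, histology_dim, interpolation = "nearest"))
  empty <- vapply(warped, function(m) !any(m), logical(1))
  if (all(empty)) stop("all ROIs are empty after transfer")
  if (any(empty))
    warning("ROI(s) empty after transfer: ",
            paste(names(warped)[empty], collapse = ", "))
  roi_set(warped, grid = "HISTOLOGY", pixel_size_um = pixel_size_um)
}

#' Serialise a transform to JSON
#' @param transform a `transform2d`.
#' @param path output file.
#' @export
write_transform <- function(transform, path) {
  pack <- function(m) list(ctrl = m$ctrl, center = m$center,
                           scale = m$scale, coef = m$coef)
  obj <- if (transform$kind == "affine") {
    list(kind = "affine", A = transform$A)
  } else {
    list(kind = "tps", lambda = transform$lambda,
         fwd = pack(transform$fwd), bwd = pack(transform$bwd))
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a transform serialised by [write_transform()]
#' @param path JSON file.
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$kind == "affine") return(affine_transform(as.matrix(obj$A)))
  unpack <- function(m) list(ctrl = as.matrix(m$ctrl),
                             center = as.numeric(m$center),
                             scale = as.numeric(m$scale),
                             coef = as.matrix(m$coef))
  structure(list(kind = "tps", lambda = obj$lambda,
                 fwd = unpack(obj$fwd), bwd = unpack(obj$bwd)),
            class = "transform2d")
}
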