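# Optical-density colour deconvolution for H-DAB brightfield stains.
#
# Beer-Lambert: transmitted intensity I = I0 * 10^(-OD), with OD linear in
# chromogen concentration. A pixel's 3-vector of channel ODs is modelled as
# M %*% c, where the columns of M are unit-norm stain OD vectors and c the
# per-stain concentrations; deconvolution inverts this linear system.

#' Construct a stain-vector basis
#'
#' @param m 3 x 3 matrix whose columns are stain OD vectors; columns are
#'   normalised to unit Euclidean norm.
#' @param stain_names names for the three columns.
#' @return object of class `stain_vectors`.
#' @export
stain_vectors <- function(m, stain_names = c("hematoxylin", "dab", "residual")) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  nrm <- sqrt(colSums(m^2))
  if (any(nrm == 0)) stop("zero stain vector")
  m <- sweep(m, 2, nrm, "/")
  if (abs(det(m)) < 1e-8) stop("stain matrix is singular")
  colnames(m) <- stain_names
  structure(list(matrix = m, stain_names = stain_names), class = "stain_vectors")
}

#' Standard hematoxylin / DAB stain basis
#'
#' The widely used published H-DAB optical-density basis; the residual vector
#' is the normalised cross product of the hematoxylin and DAB vectors, so the
#' basis is complete and invertible. The same basis is applied to both DAB
#' immunostains (IBA1, GFAP), which share the brown chromogen and
#' hematoxylin counterstain.
#'
#' @return a [stain_vectors()] object.
#' @export
default_hdab_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  stain_vectors(cbind(h, d, r))
}

#' Estimate per-channel background intensity I0
#'
#' 99th percentile per channel within a tissue-free margin of the slide
#' (background calibration for the OD transform).
#'
#' @param image [stain_image()] (RGB).
#' @param margin_px margin width sampled along all four edges.
#' @return numeric length-3 vector in (0, 255\].
#' @export
estimate_background_i0 <- function(image, margin_px = 16) {
  px <- image$pixels
  stopifnot(length(dim(px)) == 3)
  nr <- dim(px)[1]; nc <- dim(px)[2]
  m <- min(margin_px, floor(min(nr, nc) / 2))
  sel <- matrix(FALSE, nr, nc)
  sel[c(seq_len(m), nr - seq_len(m) + 1), ] <- TRUE
  sel[, c(seq_len(m), nc - seq_len(m) + 1)] <- TRUE
  vapply(1:3, function(k) {
    v <- px[, , k][sel]
    max(1, stats::quantile(v, 0.99, names = FALSE))
  }, numeric(1))
}

#' RGB image to optical density
#'
#' `OD_c = -log10(max(I_c, 1) / I0_c)` per channel; intensities are floored
#' at 1 grey level so OD is finite.
#'
#' @param image [stain_image()] (RGB) or `h x w x 3` array in \[0, 255\].
#' @param I0 per-channel background intensity in (0, 255\] (scalar recycled).
#' @return `h x w x 3` array of optical densities.
#' @export
rgb_to_od <- function(image, I0 = c(255, 255, 255)) {
  px <- if (inherits(image, "stain_image")) image$pixels else image
  if (length(dim(px)) != 3 || dim(px)[3] != 3) stop("non-RGB input")
  I0 <- rep_len(I0, 3)
  if (any(!is.finite(I0)) || any(I0 <= 0) || any(I0 > 255))
    stop("I0 must lie in (0, 255]")
  od <- px
  for (k in 1:3) od[, , k] <- -log10(pmax(px[, , k], 1) / I0[k])
  od
}

#' Optical density back to RGB
#'
#' Inverse of [rgb_to_od()]: `I = I0 * 10^(-OD)`, rounded and clipped to
#' \[0, 255\].
#' @param od `h x w x 3` OD array.
#' @inheritParams rgb_to_od
#' @return 8-bit RGB array.
#' @export
od_to_rgb <- function(od, I0 = c(255, 255, 255)) {
  I0 <- rep_len(I0, 3)
  out <- od
  for (k in 1:3) out[, , k] <- pmin(255, pmax(0, round(I0[k] * 10^(-od[, , k]))))
  out
}

#' Unmix an OD raster into per-stain concentration maps
#'
#' Solves `M c = OD` per pixel. Negative concentrations (noise outside the
#' stain simplex) are clipped to zero; the clipped fraction of total mass is
#' reported as a QC metric.
#'
#' @param od `h x w x 3` OD array (see [rgb_to_od()]).
#' @param vectors a [stain_vectors()]; default [default_hdab_vectors()].
#' @param pixel_size_um carried through for downstream physical measures.
#' @return object of class `concentration_maps`: list with `maps` (named list
#'   of matrices), `clipped_fraction`, `pixel_size_um`.
#' @export
deconvolve <- function(od, vectors = default_hdab_vectors(),
                       pixel_size_um = NA_real_) {
  stopifnot(inherits(vectors, "stain_vectors"))
  if (length(dim(od)) != 3 || dim(od)[3] != 3) stop("OD raster must be h x w x 3")
  d <- dim(od)
  flat <- rbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  conc <- solve(vectors$matrix, flat)
  neg <- conc < 0
  total <- sum(abs(conc))
  clipped <- if (total > 0) sum(abs(conc[neg])) / total else 0
  conc[neg] <- 0
  maps <- lapply(1:3, function(k) matrix(conc[k, ], d[1], d[2]))
  names(maps) <- vectors$stain_names
  structure(list(maps = maps, clipped_fraction = clipped,
                 pixel_size_um = pixel_size_um),
            class = "concentration_maps")
}

#' @export
print.concentration_maps <- function(x, ...) {
  cat(sprintf("<concentration_maps> %s; %d x %d px; clipped mass %.3g%%\n",
              paste(names(x$maps), collapse = ", "),
              nrow(x$maps[[1]]), ncol(x$maps[[1]]),
              100 * x$clipped_fraction))
  invisible(x)
}

#' Full RGB-to-concentration convenience wrapper
#'
#' @inheritParams deconvolve
#' @param image [stain_image()] (RGB).
#' @param I0 background intensity; default is the 8-bit white point. Pass
#'   `"margin"` to estimate it with [estimate_background_i0()] (requires a
#'   tissue-free slide margin).
#' @export
separate_stains <- function(image, vectors = default_hdab_vectors(),
                            I0 = c(255, 255, 255)) {
  if (identical(I0, "margin") || is.null(I0)) I0 <- estimate_background_i0(image)
  deconvolve(rgb_to_od(image, I0), vectors,
             pixel_size_um = image$pixel_size_um)
}
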