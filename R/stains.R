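## Color deconvolution of H-DAB brightfield images in optical-density space.
## Stains mix additively in OD (Beer-Lambert), so an invertible 3x3 basis of
## unit OD vectors separates hematoxylin, DAB and a residual channel.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("stain vector has zero length")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Construct a stain optical-density basis
#'
#' Builds the 3x3 matrix whose columns are unit-length optical-density
#' vectors for hematoxylin, DAB and a residual channel. The residual
#' defaults to the unit cross product of the two dye vectors, which makes
#' the matrix invertible whenever the dyes are not collinear.
#'
#' @param hematoxylin,dab Length-3 nonnegative OD vectors (any scale; they
#'   are normalized to unit Euclidean length). Defaults are the published
#'   H-DAB pair from the color-deconvolution literature.
#' @param residual Optional length-3 vector for the third channel; by
#'   default the unit cross product of `hematoxylin` and `dab`.
#' @return A `stain_basis`: a 3x3 numeric matrix with columns
#'   `hema`, `dab`, `residual`, rows R, G, B.
#' @examples
#' b <- stain_basis()
#' colSums(b^2)  # all 1
#' @export
stain_basis <- function(hematoxylin = c(0.650, 0.704, 0.286),
                        dab = c(0.269, 0.568, 0.778),
                        residual = NULL) {
  if (length(hematoxylin) != 3L || length(dab) != 3L)
    stop("stain vectors must have length 3")
  if (any(hematoxylin < 0) || any(dab < 0))
    stop("dye OD vectors must be componentwise nonnegative")
  h <- .unit(hematoxylin)
  d <- .unit(dab)
  r <- if (is.null(residual)) .cross3(h, d) else residual
  r <- .unit(r)
  m <- cbind(hema = h, dab = d, residual = r)
  rownames(m) <- c("R", "G", "B")
  if (kappa(m, exact = TRUE) > 1e6)
    stop("stain matrix is singular or ill-conditioned (condition number > 1e6)")
  class(m) <- c("stain_basis", "matrix", "array")
  m
}

.check_basis <- function(basis) {
  if (!is.matrix(basis) || any(dim(basis) != c(3L, 3L)))
    stop("`basis` must be a 3x3 stain matrix; see stain_basis()")
  if (any(abs(sqrt(colSums(basis^2)) - 1) > 1e-9))
    stop("stain basis columns must have unit Euclidean norm")
  if (kappa(unclass(basis), exact = TRUE) > 1e6)
    stop("stain basis is singular or ill-conditioned")
  invisible(basis)
}

.check_rgb <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("expected an RGB array of dimension height x width x 3")
  invisible(rgb)
}

#' Convert an 8-bit RGB image to raw optical density
#'
#' Per channel, OD = -log10(max(I, 1) / 255). The floor of one intensity
#' level keeps the OD finite, capping it at log10(255) ~ 2.4065.
#'
#' @param rgb Numeric array `h x w x 3` with values in \[0, 255\].
#' @return Array of the same shape with per-channel OD values.
#' @export
rgb_to_od <- function(rgb) {
  .check_rgb(rgb)
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("RGB values must lie in [0, 255]")
  -log10(pmax(rgb, 1) / 255)
}

#' Unmix raw optical density into per-stain concentrations
#'
#' Solves `basis %*% c = od` per pixel by the basis inverse and clips
#' negative concentrations to zero.
#'
#' @param od Raw OD array `h x w x 3` (from [rgb_to_od()]).
#' @param basis A [stain_basis()].
#' @param clip Clip negative concentrations to 0 (default `TRUE`).
#' @return Array `h x w x 3`, channel order (hema, dab, residual).
#' @export
unmix <- function(od, basis = stain_basis(), clip = TRUE) {
  .check_rgb(od)
  .check_basis(basis)
  d <- dim(od)
  conc <- matrix(od, ncol = 3L) %*% t(solve(unclass(basis)))
  if (clip) conc[conc < 0] <- 0
  array(conc, dim = d, dimnames = list(NULL, NULL, c("hema", "dab", "residual")))
}

#' Compose an RGB image from stain concentrations
#'
#' Forward Beer-Lambert model, the exact inverse of [unmix()]:
#' `I = 255 * 10^-(basis %*% c)`, optionally rounded to 8-bit levels.
#'
#' @param conc Concentration array `h x w x 3` (hema, dab, residual), OD units.
#' @param basis A [stain_basis()].
#' @param quantize Round to integer intensity levels and clip to
#'   \[0, 255\] (default `TRUE`).
#' @return RGB array `h x w x 3` in \[0, 255\].
#' @export
compose_rgb <- function(conc, basis = stain_basis(), quantize = TRUE) {
  .check_rgb(conc)
  .check_basis(basis)
  d <- dim(conc)
  od <- matrix(conc, ncol = 3L) %*% t(unclass(basis))
  i <- 255 * 10^(-od)
  if (quantize) i <- pmin(pmax(round(i), 0), 255)
  array(i, dim = d)
}

#' Read an 8-bit RGB image (PNG or TIFF)
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return RGB array `h x w x 3`, values in \[0, 255\].
#' @export
read_rgb <- function(path) {
  x <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  .check_rgb(x)
  round(x * 255)
}

#' Write an 8-bit RGB image
#'
#' @param rgb RGB array `h x w x 3`, values in \[0, 255\].
#' @param path Output path; format chosen by extension (`.png` or `.tif`).
#' @export
write_rgb <- function(rgb, path) {
  .check_rgb(rgb)
  x <- pmin(pmax(rgb, 0), 255) / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(x, target = path)
  } else {
    tiff::writeTIFF(x, where = path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Write / read a nucleus label map as 16-bit single-channel TIFF
#'
#' @param labels Integer matrix of labels (0 = background, < 65536).
#' @param path TIFF path.
#' @return `read_label_map` returns the integer label matrix.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535L) stop("label map exceeds 16-bit range")
  tiff::writeTIFF(labels / 65535, where = path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  x <- tiff::readTIFF(path)
  matrix(as.integer(round(x * 65535)), nrow = nrow(x))
}
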