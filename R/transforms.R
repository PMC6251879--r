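#' Laplacian-of-Gaussian convolution kernel
#'
#' The fixed 5 x 5 integer kernel used by [local_curvature()]. It combines a
#' Gaussian smoothing step with a Laplace (second-derivative) operator, so its
#' response is maximal for blob-shaped intensity maxima of roughly the kernel's
#' own scale. The centre coefficient is 32 and the kernel is symmetric under
#' horizontal/vertical flips and transposition.
#'
#' @return A 5 x 5 numeric matrix.
#' @export
#' @examples
#' lc_kernel()[3, 3]  # 32
lc_kernel <- function() {
  matrix(c(
    -2, -4, -4, -4, -2,
    -4,  0, 10,  0, -4,
    -4, 10, 32, 10, -4,
    -4,  0, 10,  0, -4,
    -2, -4, -4, -4, -2
  ), nrow = 5, ncol = 5, byrow = TRUE)
}

as_image_matrix <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  storage.mode(image) <- "double"
  image
}

#' White top-hat transform
#'
#' Subtracts the grey-scale opening of the image (erosion followed by dilation
#' with a flat disc) from the image itself. Smooth background survives the
#' opening and cancels out; peaks narrower than the disc do not, so small
#' bright spots are isolated from slowly varying background. The disc contains
#' every pixel within Euclidean distance `diameter / 2` of its centre and is
#' clipped at the image borders.
#'
#' @param image Numeric matrix (grey values).
#' @param diameter Disc diameter in pixels; must be >= 3. The default of 10
#'   pixels is chosen to exceed the diameter of a small focus.
#' @return Numeric matrix of the same size, non-negative everywhere.
#' @export
#' @examples
#' img <- matrix(5, 20, 20); img[10, 10] <- 50
#' th <- top_hat(img)
#' th[10, 10]  # 45: the flat background is removed
top_hat <- function(image, diameter = 10) {
  image <- as_image_matrix(image)
  if (diameter < 3) abort("`diameter` must be at least 3 pixels.")
  opened <- cpp_morph_disc(cpp_morph_disc(image, diameter, TRUE), diameter, FALSE)
  image - opened
}

#' Local-curvature (LoG) transform
#'
#' Correlates the image with the fixed 5 x 5 Laplacian-of-Gaussian kernel of
#' [lc_kernel()] (the kernel is symmetric, so correlation and convolution
#' coincide). Output values are signed and kept at full floating-point
#' precision; borders use half-sample reflect padding.
#'
#' @param image Numeric matrix, at least 5 x 5.
#' @return Numeric matrix of the same size.
#' @export
local_curvature <- function(image) {
  image <- as_image_matrix(image)
  if (nrow(image) < 5 || ncol(image) < 5) abort("`image` must be at least 5 x 5.")
  cpp_conv2_reflect(image, lc_kernel())
}

#' Sobel gradient magnitude
#'
#' Per-pixel Euclidean magnitude of the two orthogonal 3 x 3 Sobel responses,
#' with reflect padding at the borders. Used to rank z-planes by edge content
#' when selecting the sharpest plane of a marker stack.
#'
#' @param image Numeric matrix, at least 3 x 3.
#' @return Numeric matrix of the same size, non-negative.
#' @export
sobel_magnitude <- function(image) {
  image <- as_image_matrix(image)
  if (nrow(image) < 3 || ncol(image) < 3) abort("`image` must be at least 3 x 3.")
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- cpp_conv2_reflect(image, kx)
  gy <- cpp_conv2_reflect(image, t(kx))
  sqrt(gx^2 + gy^2)
}
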