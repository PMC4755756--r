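#' Crystallographic unit cell
#'
#' Constructs a unit cell from edge lengths (Angstrom) and angles (degrees).
#' All internal coordinates in the package are Cartesian Angstrom; fractional
#' coordinates appear only at file boundaries and for grid indexing.
#'
#' @param a,b,c cell edge lengths in Angstrom, all > 0.
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return an object of class `unit_cell` with fields `a,b,c,alpha,beta,gamma`,
#'   the orthogonalization matrix `ortho` (fractional -> Cartesian), its
#'   inverse `frac`, and the cell `volume` in cubic Angstrom.
#' @examples
#' cl <- unit_cell(72, 51.2, 112 / 3)
#' orthogonalize(c(0.5, 0.5, 0.5), cl)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c)
  ang <- c(alpha, beta, gamma)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stopf("invalid cell: lengths must be positive and finite")
  }
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180)) {
    stopf("invalid cell: angles must lie strictly between 0 and 180 degrees")
  }
  ca <- cospi(alpha / 180); cb <- cospi(beta / 180); cg <- cospi(gamma / 180)
  sg <- sinpi(gamma / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 1e-12) {
    stopf("invalid cell: angle combination gives non-positive cell volume")
  }
  v <- sqrt(v2)
  ortho <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      c * v / sg
  ), nrow = 3, byrow = TRUE)
  structure(list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    ortho = ortho, frac = solve(ortho), volume = a * b * c * v
  ), class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Fractional to Cartesian coordinates
#'
#' Standard crystallographic orthogonalization (a along x, b in the xy
#' plane). `fractionalize()` is its exact inverse.
#'
#' @param frac numeric vector of length 3 or an n x 3 matrix of fractional
#'   coordinates.
#' @param cell a [unit_cell].
#' @return Cartesian coordinates in Angstrom, same shape as the input.
#' @export
orthogonalize <- function(frac, cell) {
  stopifnot(inherits(cell, "unit_cell"))
  if (is.matrix(frac)) {
    if (any(!is.finite(frac))) stopf("non-finite fractional coordinates")
    t(cell$ortho %*% t(frac))
  } else {
    if (any(!is.finite(frac))) stopf("non-finite fractional coordinates")
    drop(cell$ortho %*% frac)
  }
}

#' @rdname orthogonalize
#' @param cart Cartesian coordinates (Angstrom), vector of length 3 or n x 3
#'   matrix.
#' @export
fractionalize <- function(cart, cell) {
  stopifnot(inherits(cell, "unit_cell"))
  if (is.matrix(cart)) t(cell$frac %*% t(cart)) else drop(cell$frac %*% cart)
}
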