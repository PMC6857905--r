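#' O'Sullivan penalized B-spline basis with mixed-model representation
#'
#' Builds a cubic B-spline basis on the coral-cover axis with interior knots
#' at quantiles of the observed covers and boundary knots pinned at the
#' domain edges (0 and 100 by default, so fitted curves can be evaluated
#' anywhere on the cover scale). The roughness penalty is the integrated
#' squared second derivative, computed exactly by Simpson's rule (the
#' integrand is piecewise quadratic for cubic splines). A spectral
#' decomposition of the penalty splits the basis into an unpenalized null
#' space (absorbed by the model's intercept and linear term) and a
#' penalized part `Z` whose coefficients act as i.i.d. random effects --
#' the standard mixed-model representation of a penalized spline.
#'
#' @param x numeric vector of covers (percent) used to place interior knots.
#' @param n_knots number of interior knots (>= 3).
#' @param boundary domain endpoints, default `c(0, 100)`.
#' @return List of class `"osullivan_basis"`: `Z` (design for the penalized
#'   part at `x`), `B` (raw B-spline design), `knots` (full knot sequence),
#'   `transform` (matrix mapping B-spline columns to `Z` columns), and
#'   `predict(newx)` evaluating `Z` rows at new covers.
#' @examples
#' b <- build_spline_basis(runif(50, 5, 60), n_knots = 8)
#' dim(b$Z)
#' @export
build_spline_basis <- function(x, n_knots = 20, boundary = c(0, 100)) {
  stopifnot(n_knots >= 3, length(boundary) == 2, boundary[1] < boundary[2])
  if (any(x < boundary[1] | x > boundary[2])) {
    stop("cover values outside the domain [", boundary[1], ", ",
         boundary[2], "]", call. = FALSE)
  }
  ux <- unique(x)
  if (length(ux) <= n_knots) {
    stop("need more distinct cover values (", length(ux), ") than interior ",
         "knots (", n_knots, "); reduce n_knots", call. = FALSE)
  }
  interior <- unique(stats::quantile(ux, seq(0, 1, length.out = n_knots + 2)
                                     [-c(1, n_knots + 2)], names = FALSE))
  knots <- c(rep(boundary[1], 4), interior, rep(boundary[2], 4))

  design <- function(v, derivs = 0L) {
    splines::splineDesign(knots, v, ord = 4L,
                          derivs = rep(derivs, length(v)))
  }

  # exact integral of B''_k B''_l: Simpson per inter-knot interval
  breaks <- unique(knots)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  h <- diff(breaks)
  pts <- c(breaks[-length(breaks)], mids, breaks[-1])
  w <- c(h / 6, 4 * h / 6, h / 6)
  B2 <- design(pts, derivs = 2L)
  omega <- crossprod(B2, B2 * w)

  eg <- eigen(omega, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  U <- eg$vectors[, pos, drop = FALSE]
  transform <- U %*% diag(1 / sqrt(eg$values[pos]), sum(pos))

  B <- design(x)
  structure(list(
    Z = B %*% transform,
    B = B,
    knots = knots,
    transform = transform,
    boundary = boundary,
    predict = function(newx) {
      if (any(newx < boundary[1] | newx > boundary[2])) {
        stop("prediction covers outside the basis domain", call. = FALSE)
      }
      design(newx) %*% transform
    }
  ), class = "osullivan_basis")
}
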