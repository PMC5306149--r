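# O'Sullivan penalized splines and their mixed-model form.
#
# Each smoother f(day) is a cubic B-spline expansion penalized by the
# integrated squared second derivative, Omega[j,k] = int B''_j B''_k dt.
# The penalty has a two-dimensional null space (constants and straight
# lines), so the smoother splits exactly into an unpenalized linear part
# and q = K - 2 penalized deviations Z u with u ~ N(0, sigma^2 I) --
# the variance-component form the Bernoulli GAMM samples over.

#' Place interior knots at sample quantiles
#'
#' Interior knots go at equally spaced quantiles (levels k/(n_knots+1))
#' of the distinct observed values, so knot positions adapt to each
#' species' sampling days while the knot count stays fixed.
#'
#' @param x Numeric values (e.g. observed days).
#' @param n_knots Number of interior knots (>= 1).
#' @return Strictly increasing numeric vector of length \code{n_knots}.
#' @export
place_knots <- function(x, n_knots) {
  stopifnot(n_knots >= 1)
  ux <- sort(unique(x[is.finite(x)]))
  if (length(ux) < max(n_knots, 2))
    sg_error("seasongamm_degenerate_error",
             sprintf("need at least %d distinct values to place %d knots, got %d",
                     max(n_knots, 2), n_knots, length(ux)))
  probs <- seq_len(n_knots) / (n_knots + 1)
  k <- quantile(ux, probs = probs, names = FALSE, type = 7)
  if (any(diff(k) <= 0))
    sg_error("seasongamm_degenerate_error",
             "quantile knots are not strictly increasing; too few distinct values")
  k
}

full_knot_vector <- function(knots, boundary, degree) {
  c(rep(boundary[1], degree + 1), knots, rep(boundary[2], degree + 1))
}

#' Evaluate the B-spline design matrix
#'
#' Standard (Cox--de Boor) B-spline basis of the given degree on the
#' boundary interval with the supplied interior knots; rows form a
#' partition of unity.
#'
#' @param x Evaluation points inside \code{[boundary[1], boundary[2]]}.
#' @param knots Interior knots, strictly increasing, inside the boundary.
#' @param boundary Length-2 numeric, the boundary knots.
#' @param degree Spline degree (default cubic).
#' @return n x K design matrix, K = length(knots) + degree + 1.
#' @export
bspline_design <- function(x, knots, boundary, degree = 3) {
  if (any(x < boundary[1] | x > boundary[2]))
    sg_error("seasongamm_range_error",
             sprintf("evaluation points outside [%g, %g]", boundary[1], boundary[2]))
  splines::splineDesign(full_knot_vector(knots, boundary, degree), x,
                        ord = degree + 1, outer.ok = FALSE)
}

#' O'Sullivan roughness penalty matrix
#'
#' \eqn{\Omega_{jk} = \int B''_j(t)\,B''_k(t)\,dt} over the boundary
#' interval, computed exactly by composite Simpson quadrature on each
#' inter-knot interval (the integrand is piecewise quadratic for cubic
#' splines, which Simpson integrates exactly).
#'
#' @inheritParams bspline_design
#' @return Symmetric positive semidefinite K x K matrix of rank K - 2;
#'   its null space is spanned by coefficient vectors reproducing
#'   constants and straight lines.
#' @export
penalty_matrix <- function(knots, boundary, degree = 3) {
  allk <- full_knot_vector(knots, boundary, degree)
  breaks <- sort(unique(allk))
  a <- breaks[-length(breaks)]
  b <- breaks[-1]
  h <- b - a
  # Simpson nodes (a, midpoint, b) and weights h/6 * (1, 4, 1) per interval
  xg <- as.vector(rbind(a, (a + b) / 2, b))
  wg <- as.vector(rbind(h / 6, 4 * h / 6, h / 6))
  B2 <- splines::splineDesign(allk, xg, ord = degree + 1,
                              derivs = rep(2L, length(xg)), outer.ok = TRUE)
  Omega <- t(B2 * wg) %*% B2
  (Omega + t(Omega)) / 2
}

#' Mixed-model reparameterization of a penalized spline
#'
#' Spectral decomposition of the penalty splits the B-spline coefficient
#' space into the penalty null space (absorbed into an intercept and a
#' centered linear column) and q = K - 2 penalized directions
#' \code{Z = B U_+ diag(d_+)^{-1/2}}, so a ridge fit in (B, Omega) with
#' smoothing parameter lambda equals a mixed-model fit in (X_lin, Z) with
#' deviation variance 1/lambda.
#'
#' @param B B-spline design matrix from [bspline_design()].
#' @param Omega Penalty matrix from [penalty_matrix()] for the same basis.
#' @param x The covariate values behind \code{B}'s rows (for the linear
#'   column).
#' @param null_dim Expected null-space dimension (2: constant + linear).
#' @return A \code{spline_basis}: list with \code{X_lin} (centered linear
#'   column), \code{Z}, the eigenvectors \code{U} and eigenvalues
#'   \code{d} of the penalized subspace, and the centering constant
#'   \code{x_center}.
#' @export
mixed_model_rep <- function(B, Omega, x, null_dim = 2L) {
  eg <- eigen(Omega, symmetric = TRUE)
  d <- eg$values
  tol <- 1e-10 * max(d)
  pos <- d > tol
  if (sum(!pos) != null_dim)
    sg_error("seasongamm_decomposition_error",
             sprintf("penalty null space has dimension %d, expected %d",
                     sum(!pos), null_dim))
  U <- eg$vectors[, pos, drop = FALSE]
  dpos <- d[pos]
  Z <- B %*% U %*% diag(1 / sqrt(dpos), length(dpos))
  if (!all(is.finite(Z)))
    sg_error("seasongamm_decomposition_error", "non-finite entries in Z")
  structure(list(X_lin = x - mean(x), Z = Z, U = U, d = dpos,
                 x_center = mean(x)),
            class = "spline_basis")
}

#' Build a full O'Sullivan basis from data
#'
#' Convenience wrapper: quantile knots, boundary at the data range padded
#' by 1e-3 of the range (avoids edge degeneracy), cubic B-spline design,
#' exact penalty, and the mixed-model reparameterization.
#'
#' @param x Covariate values (days).
#' @param n_knots Interior knot count (default 5, the survey model's
#'   setting).
#' @param degree Spline degree.
#' @return A \code{spline_basis} with additional fields \code{knots},
#'   \code{boundary}, \code{degree}, \code{B}, \code{Omega} and
#'   \code{x_range}.
#' @export
osullivan_basis <- function(x, n_knots = 5, degree = 3) {
  knots <- place_knots(x, n_knots)
  pad <- 1e-3 * diff(range(x))
  boundary <- c(min(x) - pad, max(x) + pad)
  B <- bspline_design(x, knots, boundary, degree)
  Omega <- penalty_matrix(knots, boundary, degree)
  rep_ <- mixed_model_rep(B, Omega, x)
  rep_$knots <- knots
  rep_$boundary <- boundary
  rep_$degree <- degree
  rep_$B <- B
  rep_$Omega <- Omega
  rep_$x_range <- range(x)
  rep_
}

#' Evaluate a fitted spline basis at new points
#'
#' Reconstructs the linear column and penalized design at new covariate
#' values using the training decomposition and centering, for smoother
#' curves on a day grid.
#'
#' @param basis A \code{spline_basis} from [osullivan_basis()].
#' @param xnew New covariate values within the training range.
#' @return List with \code{X_lin} and \code{Z} at \code{xnew}.
#' @export
eval_spline_basis <- function(basis, xnew) {
  if (any(xnew < basis$x_range[1] | xnew > basis$x_range[2]))
    sg_error("seasongamm_extrapolation_error",
             sprintf("evaluation outside fitted day range [%g, %g]",
                     basis$x_range[1], basis$x_range[2]))
  B <- bspline_design(xnew, basis$knots, basis$boundary, basis$degree)
  list(X_lin = xnew - basis$x_center,
       Z = B %*% basis$U %*% diag(1 / sqrt(basis$d), length(basis$d)))
}
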