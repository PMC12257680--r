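#' Smoothing configuration for one series type
#'
#' @param order B-spline order (number of polynomial coefficients per piece):
#'   3 for body weight (quadratic pieces), 4 for fibre diameter (cubic).
#' @param lambda_smooth curvature penalty weight; default 2500.
#' @param n_quantile_knots number of quantile intervals defining the interior
#'   knots from the pooled flock-year positions; default 10.
#' @param extra_knots additional knot positions (body weight uses these in the
#'   sparse pre-weaning region, 0-90 days).
#' @param prediction_step spacing of the prediction grid: 1 mm (FD) or
#'   10 days (BW).
#' @param penalty_derivative derivative order being penalized (2 = curvature).
#' @return object of class `smoothing_config`.
#' @export
smoothing_config <- function(order = 4L, lambda_smooth = 2500,
                             n_quantile_knots = 10L, extra_knots = NULL,
                             prediction_step = 1, penalty_derivative = 2L) {
  stopifnot(order >= 2L, lambda_smooth >= 0, n_quantile_knots >= 1L,
            prediction_step > 0)
  structure(list(order = as.integer(order), lambda_smooth = lambda_smooth,
                 n_quantile_knots = as.integer(n_quantile_knots),
                 extra_knots = extra_knots, prediction_step = prediction_step,
                 penalty_derivative = as.integer(penalty_derivative)),
            class = "smoothing_config")
}

#' Knot vector from pooled group positions
#'
#' Interior knots at empirical quantiles (type 7, linear interpolation) of all
#' observation positions in the flock-year group; boundary knots at the domain
#' ends. `n_quantiles` counts intervals, so 10 quantiles place interior knots
#' at the 10%, 20%, ..., 90% points. Extra knots are merged and deduplicated.
#'
#' @param positions pooled observation positions of the group.
#' @param n_quantiles number of quantile intervals.
#' @param extra_knots optional extra interior knots.
#' @param domain numeric length-2 domain; defaults to the position range.
#' @return sorted knot vector including the two boundary knots.
#' @export
quantile_knots <- function(positions, n_quantiles = 10L, extra_knots = NULL,
                           domain = range(positions)) {
  if (length(unique(positions)) < n_quantiles) {
    stop("need at least ", n_quantiles, " distinct positions to place quantile knots")
  }
  probs <- seq(0, 1, length.out = n_quantiles + 1L)
  interior <- unname(quantile(positions, probs[-c(1L, n_quantiles + 1L)], type = 7))
  knots <- sort(unique(c(domain, interior, extra_knots)))
  knots <- knots[knots >= domain[1] & knots <= domain[2]]
  # collapse knots closer than a relative tolerance
  tol <- diff(domain) * 1e-9
  knots[c(TRUE, diff(knots) > tol)]
}

# Full (boundary-replicated) knot sequence for splineDesign.
augment_knots <- function(knots, order) {
  c(rep(knots[1], order - 1L), knots, rep(knots[length(knots)], order - 1L))
}

#' Exact curvature penalty Gram matrix
#'
#' Integral over the domain of products of `deriv`-th basis derivatives,
#' computed span-by-span with Gauss-Legendre quadrature using enough nodes to
#' be exact for the piecewise-polynomial integrand.
#'
#' @param knots knot vector (with boundary knots, unreplicated).
#' @param order spline order.
#' @param deriv penalized derivative order (default 2).
#' @return symmetric penalty matrix, dimension = number of basis functions.
#' @export
penalty_gram <- function(knots, order, deriv = 2L) {
  aug <- augment_knots(knots, order)
  nb <- length(aug) - order
  R <- matrix(0, nb, nb)
  # integrand degree per span: 2 * (order - 1 - deriv); n-point GL exact to 2n-1
  npt <- max(1L, as.integer(ceiling((2 * (order - 1L - deriv) + 1L) / 2)))
  gl <- gauss_legendre(npt)
  for (k in seq_len(length(knots) - 1L)) {
    a <- knots[k]; b <- knots[k + 1L]
    if (b <= a) next
    x <- (b - a) / 2 * gl$nodes + (a + b) / 2
    w <- (b - a) / 2 * gl$weights
    D <- splines::splineDesign(aug, x, ord = order, derivs = rep(deriv, length(x)),
                               outer.ok = TRUE)
    R <- R + crossprod(D * sqrt(w))
  }
  (R + t(R)) / 2
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem.
gauss_legendre <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
}

#' Fit a penalized B-spline to one animal's records
#'
#' Minimizes the sum of squared residuals plus `lambda` times the integrated
#' squared second derivative, solving the normal equations
#' `(B'B + lambda R) c = B'y` with the exact curvature Gram matrix `R`.
#'
#' @param x,y observation positions and values (positions within the knot
#'   domain; at least `order + 1` observations).
#' @param knots knot vector from [quantile_knots()], clipped to this animal's
#'   domain if necessary.
#' @param config a [smoothing_config()].
#' @return object of class `smooth_curve`: `coefficients`, `knots`, `order`,
#'   `domain`, `lambda`, plus the prediction `grid` and fitted `values`.
#' @export
fit_penalized_spline <- function(x, y, knots, config) {
  stopifnot(length(x) == length(y))
  ord <- config$order
  if (length(x) < ord + 1L) stop("need at least order + 1 observations")
  domain <- range(knots)
  if (any(x < domain[1] - 1e-9 | x > domain[2] + 1e-9)) {
    stop("observations outside the knot domain")
  }
  x <- pmin(pmax(x, domain[1]), domain[2])
  aug <- augment_knots(knots, ord)
  B <- splines::splineDesign(aug, x, ord = ord)
  R <- penalty_gram(knots, ord, config$penalty_derivative)
  M <- crossprod(B) + config$lambda_smooth * R
  rhs <- crossprod(B, y)
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps) * max(diag(ch)))) {
    stop("singular normal equations: a basis function is unsupported by the data ",
         "and the penalty null space cannot determine it (add data or knots, or ",
         "increase lambda)")
  }
  cf <- drop(backsolve(ch, forwardsolve(t(ch), rhs)))
  grid <- seq(domain[1], domain[2], by = config$prediction_step)
  if (grid[length(grid)] < domain[2] - 1e-9) grid <- c(grid, domain[2])
  curve <- structure(list(coefficients = cf, knots = knots, order = ord,
                          domain = domain, lambda = config$lambda_smooth,
                          grid = grid, values = NULL),
                     class = "smooth_curve")
  curve$values <- evaluate_curve(curve, grid)
  curve
}

#' Evaluate a smooth curve (or a derivative) on a grid
#'
#' De Boor evaluation of the fitted B-spline.
#'
#' @param curve a `smooth_curve`.
#' @param grid evaluation points within the curve domain.
#' @param deriv derivative order (0 = the curve itself).
#' @return numeric vector of values.
#' @export
evaluate_curve <- function(curve, grid, deriv = 0L) {
  if (any(grid < curve$domain[1] - 1e-9 | grid > curve$domain[2] + 1e-9)) {
    stop("grid outside curve domain")
  }
  grid <- pmin(pmax(grid, curve$domain[1]), curve$domain[2])
  aug <- augment_knots(curve$knots, curve$order)
  D <- splines::splineDesign(aug, grid, ord = curve$order,
                             derivs = rep(as.integer(deriv), length(grid)))
  drop(D %*% curve$coefficients)
}

#' Standardize raw records within flock-year cells
#'
#' Fibre diameter records are standardized to mean 0, sd 1 (n-1 denominator)
#' within each flock-year; body weight records within each flock-year by
#' recording moment, where recording moments are found by clustering ages:
#' sorted distinct ages are split wherever the gap exceeds `moment_gap` days,
#' so each weighing occasion forms one cell.
#'
#' @param records long `data.frame` with at least `series`, `position`,
#'   `value`, `flock_year`.
#' @param moment_gap age gap (days) separating two body-weight recording
#'   moments; default 7.
#' @param on_small what to do with a cell of fewer than 2 records or zero
#'   spread: `"error"` (default) or `"drop"` (remove those records).
#' @return the records with `value` replaced by its standardized version and a
#'   `std_cell` column naming the standardization cell.
#' @export
standardize_raw <- function(records, moment_gap = 7,
                            on_small = c("error", "drop")) {
  on_small <- match.arg(on_small)
  stopifnot(all(c("series", "position", "value", "flock_year") %in% names(records)))
  cell <- character(nrow(records))
  is_fd <- records$series == "FD"
  cell[is_fd] <- paste0(records$flock_year[is_fd], ":FD")
  if (any(!is_fd)) {
    bw <- which(!is_fd)
    for (fy in unique(records$flock_year[bw])) {
      idx <- bw[records$flock_year[bw] == fy]
      bin <- cluster_moments(records$position[idx], moment_gap)
      cell[idx] <- paste0(fy, ":BW:m", bin)
    }
  }
  out <- records
  bad <- integer(0)
  for (cl in unique(cell)) {
    idx <- which(cell == cl)
    if (length(idx) < 2L) {
      if (on_small == "error") {
        stop("standardization cell '", cl, "' has fewer than 2 records")
      }
      bad <- c(bad, idx)
      next
    }
    s <- sd(records$value[idx])
    if (s == 0) {
      if (on_small == "error") {
        stop("zero within-group standard deviation in cell '", cl, "'")
      }
      bad <- c(bad, idx)
      next
    }
    out$value[idx] <- (records$value[idx] - mean(records$value[idx])) / s
  }
  out$std_cell <- cell
  if (length(bad)) out <- out[-bad, , drop = FALSE]
  out
}

# 1-D clustering of ages into recording moments: split sorted values at gaps
# larger than `gap`; returns the bin index of each input value.
cluster_moments <- function(ages, gap) {
  u <- sort(unique(ages))
  bin_of_u <- cumsum(c(1, diff(u) > gap))
  bin_of_u[match(ages, u)]
}
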