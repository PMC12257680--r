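#' Square-root velocity function (SRVF) transform
#'
#' Maps a curve `f` on grid `t` to `q = sign(f') sqrt(|f'|)`, the
#' representation under which warping acts by an isometry and elastic
#' distances between curves become ordinary L2 distances. The derivative is
#' taken by centered finite differences (one-sided at the ends).
#'
#' @param f curve values.
#' @param t strictly increasing grid, at least 3 points.
#' @return object of class `srvf_curve` with fields `t` and `q`.
#' @export
srvf_transform <- function(f, t) {
  if (length(t) < 3L || any(diff(t) <= 0)) stop("grid must be strictly increasing with >= 3 points")
  g <- fd_gradient(f, t)
  structure(list(t = t, q = sign(g) * sqrt(abs(g))), class = "srvf_curve")
}

#' Optimal warping of one SRVF onto a target
#'
#' Solves `argmin over monotone endpoint-preserving gamma of
#' ||mu - (q o gamma) sqrt(gamma')||^2 + lambda R(gamma)` by dynamic
#' programming on an n x n lattice with segment slopes restricted to
#' `[1/5, 5]`. The roughness penalty is the identity deviation in SRVF space,
#' `R(gamma) = ||sqrt(gamma') - 1||^2`, so large `lambda` forces gamma toward
#' the identity. Curves are internally rescaled to the unit interval.
#'
#' @param q,mu `srvf_curve` objects on a common grid (`q` is warped onto `mu`).
#' @param lambda_align warping penalty, `>= 0`.
#' @return object of class `warp_function`: fields `t` (the original grid) and
#'   `gamma` (warp values on that grid), satisfying `gamma(t1) = t1`,
#'   `gamma(tn) = tn`, non-decreasing.
#' @export
optimal_warp <- function(q, mu, lambda_align = 0) {
  stopifnot(inherits(q, "srvf_curve"), inherits(mu, "srvf_curve"),
            lambda_align >= 0)
  if (length(q$t) != length(mu$t) || max(abs(q$t - mu$t)) > 1e-8 * diff(range(q$t))) {
    stop("q and mu must share one grid")
  }
  t <- q$t
  L <- diff(range(t))
  # DP assumes a uniform unit grid; resample if the grid is non-uniform
  tu <- (t - t[1]) / L
  if (max(abs(diff(tu) - tu[2])) > 1e-8) {
    n <- length(t)
    tt <- seq(0, 1, length.out = n)
    qv <- approx(tu, q$q, tt)$y
    mv <- approx(tu, mu$q, tt)$y
    g <- .dp_warp_cpp(mv, qv, lambda_align)
    gam <- approx(tt, g, tu)$y
  } else {
    gam <- .dp_warp_cpp(mu$q, q$q, lambda_align)
  }
  new_warp_function(t, t[1] + gam * L)
}

new_warp_function <- function(t, gamma) {
  w <- structure(list(t = t, gamma = gamma), class = "warp_function")
  validate_warp(w)
  w
}

#' Check warping-function invariants
#'
#' Endpoint preservation and monotonicity on its grid.
#' @param w a `warp_function`.
#' @return the warp, invisibly; errors if invalid.
#' @export
validate_warp <- function(w) {
  L <- range(w$t)
  tol <- 1e-8 * diff(L)
  if (abs(w$gamma[1] - L[1]) > tol || abs(w$gamma[length(w$gamma)] - L[2]) > tol) {
    stop("warp does not preserve the endpoints")
  }
  if (any(diff(w$gamma) < -tol)) stop("warp is not non-decreasing")
  invisible(w)
}

# SRVF of q composed with gamma: (q o gamma) sqrt(gamma'), gamma on q's grid.
warp_srvf <- function(q, w) {
  gd <- fd_gradient(w$gamma, w$t)
  qg <- approx(q$t, q$q, xout = pmin(pmax(w$gamma, min(q$t)), max(q$t)))$y
  structure(list(t = q$t, q = qg * sqrt(pmax(gd, 0))), class = "srvf_curve")
}

# L2 distance between two SRVFs on their common grid.
srvf_distance <- function(q1, q2) {
  sqrt(trapz(q1$t, (q1$q - q2$q)^2))
}

#' Apply a warping function to curve values
#'
#' Computes the aligned curve `f(gamma(t))` by monotone (linear)
#' interpolation; attained extreme values are preserved up to interpolation
#' error because gamma is an increasing surjection of the domain.
#'
#' @param f curve values on grid `t`.
#' @param t evaluation grid.
#' @param w a `warp_function` on the same grid.
#' @return aligned curve values on `t`.
#' @export
apply_warp <- function(f, t, w) {
  validate_warp(w)
  approx(t, f, xout = pmin(pmax(w$gamma, min(t)), max(t)))$y
}

# Numerical inverse of a warp: swap axes and re-interpolate onto the grid.
invert_warp <- function(w) {
  g <- cummax(w$gamma)                      # enforce monotone before inversion
  keep <- c(TRUE, diff(g) > 0)
  inv <- approx(g[keep], w$t[keep], xout = w$t, rule = 2)$y
  inv[1] <- w$t[1]; inv[length(inv)] <- w$t[length(w$t)]
  new_warp_function(w$t, inv)
}

#' Karcher (Frechet) mean of a set of SRVF curves
#'
#' Iteratively aligns every member to the current mean by [optimal_warp()],
#' updates the mean as the cross-member average of the aligned SRVFs and stops
#' when the alignment objective (sum of squared L2 distances to the mean)
#' changes by less than `tol` (relative) or `max_iter` is reached. The
#' objective is non-increasing across iterations. After convergence the warps
#' are re-centered so their mean is the identity, and the mean is adjusted by
#' the common inverse warp.
#'
#' @param qs list of `srvf_curve` objects on one common grid (>= 2 members).
#' @param lambda_align warping penalty.
#' @param tol relative objective-change tolerance.
#' @param max_iter maximum iterations.
#' @param recenter re-center warps after convergence (default TRUE).
#' @return list: `mean` (`srvf_curve`), `warps` (list of `warp_function`),
#'   `aligned` (list of aligned `srvf_curve`), `objective` (per-iteration
#'   values), `converged` (flag).
#' @export
karcher_mean <- function(qs, lambda_align = 0, tol = 1e-3, max_iter = 30L,
                         recenter = TRUE) {
  if (length(qs) < 2L) stop("need at least 2 curves for a Karcher mean")
  t <- qs[[1]]$t
  for (q in qs) stopifnot(max(abs(q$t - t)) < 1e-8 * diff(range(t)))
  Q <- vapply(qs, function(q) q$q, numeric(length(t)))
  mu <- structure(list(t = t, q = rowMeans(Q)), class = "srvf_curve")
  warps <- NULL
  objective <- numeric(0)
  converged <- FALSE
  mu_prev <- mu
  warps_prev <- NULL
  for (it in seq_len(max_iter)) {
    warps <- lapply(qs, optimal_warp, mu = mu, lambda_align = lambda_align)
    aligned <- mapply(warp_srvf, qs, warps, SIMPLIFY = FALSE)
    obj <- sum(vapply(aligned, srvf_distance, numeric(1), q2 = mu)^2)
    if (it > 1L && obj > objective[length(objective)]) {
      # the DP cost and the reported trapezoid distance use slightly
      # different discretizations; once their mismatch exceeds the true
      # improvement, further iterations cannot help — keep the best iterate
      warps <- warps_prev
      mu <- mu_prev
      converged <- TRUE
      break
    }
    objective <- c(objective, obj)
    warps_prev <- warps
    mu_prev <- mu
    Qa <- vapply(aligned, function(q) q$q, numeric(length(t)))
    mu <- structure(list(t = t, q = rowMeans(Qa)), class = "srvf_curve")
    if (it > 1L && abs(objective[it - 1L] - obj) <=
        tol * max(1e-12, objective[it - 1L])) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Karcher mean did not converge in ", max_iter,
            " iterations; final objective ", signif(objective[length(objective)], 6))
  }
  if (recenter) {
    gbar <- rowMeans(vapply(warps, function(w) w$gamma, numeric(length(t))))
    ginv <- invert_warp(new_warp_function(t, gbar))
    mu <- warp_srvf(mu, ginv)
    # final pass against the re-centered mean so every reported warp is the
    # DP optimum for the mean actually returned (identity stays feasible, so
    # each member's aligned distance cannot exceed its unaligned distance)
    warps <- lapply(qs, optimal_warp, mu = mu, lambda_align = lambda_align)
  }
  aligned <- mapply(warp_srvf, qs, warps, SIMPLIFY = FALSE)
  list(mean = mu, warps = warps, aligned = aligned,
       objective = objective, converged = converged)
}

#' Elastic alignment of one flock-year group
#'
#' Transforms each member curve to its SRVF, computes the group Karcher mean
#' and per-animal optimal warps at each requested alignment penalty, and
#' returns the aligned curves in the original function space together with the
#' group mean curve (the cross-sectional average of the aligned functions,
#' whose deviations therefore average to zero at every grid point).
#'
#' @param curves numeric matrix, grid points x animals, all on `grid`.
#' @param grid common evaluation grid.
#' @param lambda_grid alignment penalties to run (default the sensitivity grid
#'   0, 0.2, 0.4, 0.6).
#' @param ids optional animal ids (defaults to column names).
#' @param flock_year optional group label carried through.
#' @param ... passed to [karcher_mean()].
#' @return object of class `group_alignment`: a list with one entry per
#'   lambda, each holding `aligned` (matrix like `curves`), `warps`,
#'   `mean_curve` (function-space group mean), `mean_srvf`, `distances`
#'   (per-animal aligned elastic distance to the mean), `objective`; plus
#'   attributes `grid`, `ids`, `flock_year`, `lambda_grid`.
#' @export
align_group <- function(curves, grid, lambda_grid = c(0, 0.2, 0.4, 0.6),
                        ids = colnames(curves), flock_year = NULL, ...) {
  curves <- as.matrix(curves)
  if (ncol(curves) < 2L) stop("group too small: need at least 2 curves")
  if (length(lambda_grid) < 1L) stop("lambda grid must be non-empty")
  if (is.null(ids)) ids <- paste0("c", seq_len(ncol(curves)))
  qs <- lapply(seq_len(ncol(curves)), function(j) srvf_transform(curves[, j], grid))
  out <- vector("list", length(lambda_grid))
  names(out) <- paste0("lambda_", lambda_grid)
  for (li in seq_along(lambda_grid)) {
    km <- karcher_mean(qs, lambda_align = lambda_grid[li], ...)
    aligned_f <- vapply(seq_len(ncol(curves)),
                        function(j) apply_warp(curves[, j], grid, km$warps[[j]]),
                        numeric(length(grid)))
    colnames(aligned_f) <- ids
    dists <- vapply(km$aligned, srvf_distance, numeric(1), q2 = km$mean)
    out[[li]] <- list(aligned = aligned_f, warps = km$warps,
                      mean_curve = rowMeans(aligned_f), mean_srvf = km$mean,
                      distances = dists, objective = km$objective,
                      converged = km$converged)
  }
  structure(out, grid = grid, ids = ids, flock_year = flock_year,
            lambda_grid = lambda_grid, class = "group_alignment")
}

#' Plot a group alignment (unaligned, aligned, mean, warps)
#'
#' Four-panel base-graphics display of one lambda's alignment.
#'
#' @param x a `group_alignment`.
#' @param curves the original (unaligned) curve matrix.
#' @param lambda which lambda entry to plot (index or value).
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot_group_alignment <- function(x, curves, lambda = 1L, ...) {
  grid <- attr(x, "grid")
  li <- if (lambda %in% attr(x, "lambda_grid")) match(lambda, attr(x, "lambda_grid")) else lambda
  entry <- x[[li]]
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(grid, curves, type = "l", lty = 1, col = grDevices::grey(0.6),
                    xlab = "position", ylab = "value", main = "unaligned")
  graphics::matplot(grid, entry$aligned, type = "l", lty = 1, col = grDevices::grey(0.6),
                    xlab = "position", ylab = "value", main = "aligned")
  graphics::plot(grid, entry$mean_curve, type = "l", lwd = 2,
                 xlab = "position", ylab = "value", main = "group mean")
  gmat <- vapply(entry$warps, function(w) w$gamma, numeric(length(grid)))
  graphics::matplot(grid, gmat, type = "l", lty = 1, col = grDevices::grey(0.6),
                    xlab = "original position", ylab = "aligned position",
                    main = "warping functions")
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
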