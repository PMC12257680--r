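#' Build a model frame for the animal model
#'
#' Assembles the response, fixed-effect design (birth-rearing type and
#' contemporary group = flock-year x sex by default, reduced to full column
#' rank), and the incidence matrices linking records to additive genetic
#' effects (all pedigree animals) and maternal permanent environmental effects
#' (dam levels; animals with unknown dam receive their own singleton level).
#'
#' @param data `data.frame` with columns `animal`, `value`, and the fixed
#'   effect columns (`brt`, `flock_year`, `sex` as available). Rows with
#'   missing `value` are dropped.
#' @param ped the pedigree holding every phenotyped animal.
#' @param fixed character vector of fixed-effect column names; `"cg"` is
#'   created as flock_year x sex when both exist. Defaults to the available
#'   subset of `c("brt", "cg")`.
#' @param covariate optional numeric covariate column name(s).
#' @param maternal include the maternal permanent environmental effect.
#' @return object of class `model_frame`.
#' @export
model_frame <- function(data, ped, fixed = NULL, covariate = NULL,
                        maternal = TRUE) {
  validate_pedigree(ped)
  stopifnot(all(c("animal", "value") %in% names(data)))
  data <- data[!is.na(data$value), , drop = FALSE]
  n <- nrow(data)
  if (n < 1L) stop("no records with non-missing values")
  if (!all(data$animal %in% ped$animal)) {
    stop("every phenotyped animal must be in the pedigree")
  }
  if (all(c("flock_year", "sex") %in% names(data))) {
    data$cg <- interaction(data$flock_year, data$sex, drop = TRUE)
  }
  if (is.null(fixed)) fixed <- intersect(c("brt", "cg"), names(data))
  terms <- c("1", fixed, covariate)
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]

  q <- nrow(ped)
  Z1 <- Matrix::sparseMatrix(i = seq_len(n), j = match(data$animal, ped$animal),
                             x = 1, dims = c(n, q))
  dam <- ped$dam[match(data$animal, ped$animal)]
  dam_lab <- ifelse(dam == 0L, paste0("solo_", data$animal), paste0("dam_", dam))
  dam_levels <- unique(dam_lab)
  s <- length(dam_levels)
  dam_idx <- match(dam_lab, dam_levels)
  Z2 <- Matrix::sparseMatrix(i = seq_len(n), j = dam_idx, x = 1, dims = c(n, s))
  structure(list(y = as.numeric(data$value), X = X, Z1 = Z1,
                 Z2 = if (maternal) Z2 else NULL,
                 dam_idx = if (maternal) dam_idx else NULL,
                 animal = data$animal, dam_levels = if (maternal) dam_levels else NULL,
                 maternal = maternal, n = n, p = ncol(X), q = q, s = if (maternal) s else 0L),
            class = "model_frame")
}

# Central-difference Hessian of a scalar function.
num_hessian <- function(f, x, h = pmax(abs(x) * 1e-4, 1e-7)) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k); ei[i] <- h[i]; ej[j] <- h[j]
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

# log-determinant of a sparse symmetric PD matrix; +Inf marks non-PD.
sparse_logdet <- function(C) {
  out <- tryCatch(Matrix::determinant(C, logarithm = TRUE)$modulus,
                  error = function(e) Inf)
  as.numeric(out)
}

#' Univariate REML for the single-step animal model
#'
#' Estimates `sigma2_a`, `sigma2_m`, `sigma2_e` of
#' `y = Xb + Z1 a + Z2 m + e`, `var(a) = H sigma2_a`, `var(m) = I sigma2_m`,
#' `var(e) = I sigma2_e`, by maximizing the restricted log-likelihood
#' evaluated through sparse mixed-model equations (one sparse Cholesky per
#' evaluation). Components are bounded below by `eps`. Standard errors come
#' from the inverse numeric observed-information matrix; the heritability
#' `h2 = sigma2_a / (sigma2_a + sigma2_m + sigma2_e)` gets a delta-method SE.
#'
#' @param frame a [model_frame()].
#' @param rel a [blend_and_build_H()] `relationship_set` on the same pedigree.
#' @param start optional starting values `c(sigma2_a, sigma2_m, sigma2_e)`.
#' @param eps lower bound on components.
#' @param control passed to [stats::nlminb()].
#' @return object of class `reml_fit`: `varcomp` (estimates), `se`, `h2`,
#'   `h2_se`, `loglik`, `converged`, `trajectory` (accepted objective values),
#'   `solutions` (`b`, `a`, `m` BLUPs at the optimum).
#' @export
reml_univariate <- function(frame, rel, start = NULL, eps = 1e-8,
                            control = list(rel.tol = 1e-10)) {
  stopifnot(inherits(frame, "model_frame"), inherits(rel, "relationship_set"))
  if (frame$q != length(rel$ids)) stop("frame and relationship set disagree on pedigree size")
  if (frame$n < frame$p + 3L) stop("need at least p + 3 records")
  y <- frame$y
  W <- cbind(Matrix::Matrix(frame$X, sparse = TRUE), frame$Z1,
             if (frame$maternal) frame$Z2)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  Wty <- Matrix::crossprod(W, y)
  yty <- sum(y^2)
  p <- frame$p; q <- frame$q; s <- frame$s
  K <- rel$Hinv
  dim_c <- p + q + s
  ia <- p + seq_len(q)
  im <- if (s > 0) p + q + seq_len(s) else integer(0)
  Pa <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(dim_c, dim_c))
  Pa[ia, ia] <- K
  Pa <- Matrix::forceSymmetric(Pa)
  Pm <- Matrix::sparseMatrix(i = im, j = im, x = rep(1, s), dims = c(dim_c, dim_c))
  Pm <- Matrix::forceSymmetric(Pm)

  # Profiled restricted likelihood over the variance ratios
  # g = (sigma2_a, sigma2_m) / sigma2_e: with C_g = W'W + Pa/ga + Pm/gm the
  # residual variance solves in closed form, sigma2_e = y'Py_g / (n - p), and
  # -2logL(g) = (n-p)(log sigma2_e + 1) + q log ga + s log gm + log|C_g|
  # (constants dropped). One sparse Cholesky per evaluation; the profile
  # removes the flat overall-scale direction.
  trajectory <- numeric(0)
  n_ <- frame$n
  prof <- function(lg) {
    ga <- exp(lg[1]); gm <- if (s > 0) exp(lg[2]) else 1
    C <- WtW + Pa / ga + if (s > 0) Pm / gm else 0
    ld <- sparse_logdet(C)
    if (!is.finite(ld)) return(list(val = 1e10))
    sol <- Matrix::solve(C, Wty)
    Sg <- yty - sum(sol * Wty)
    if (Sg <= 0) return(list(val = 1e10))
    se2 <- Sg / (n_ - p)
    val <- (n_ - p) * (log(se2) + 1) + q * log(ga) + s * log(gm) + ld
    list(val = as.numeric(val), se2 = se2, sol = sol)
  }
  obj <- function(lg) {
    v <- prof(lg)$val
    if (length(trajectory) == 0L || v < trajectory[length(trajectory)]) {
      trajectory <<- c(trajectory, v)
    }
    v
  }
  vy <- var(y)
  if (is.null(start)) start <- c(0.3, if (s > 0) 0.1 else eps, 0.6) * vy
  lg0 <- log(pmax(start[1:2] / start[3], 1e-8))[seq_len(if (s > 0) 2 else 1)]
  lo <- log(eps); hi <- log(1e8)
  fit <- nlminb(lg0, obj, lower = lo, upper = hi, control = control)
  lg <- fit$par

  # Newton polish with central differences (step sizes chosen against the
  # ~1e-8 sparse-Cholesky evaluation noise on the deviance).
  free <- lg > lo + 1
  if (any(free)) {
    f_free <- function(x) {
      full <- lg; full[free] <- x
      prof(full)$val
    }
    for (it in 1:5) {
      x0 <- lg[free]
      hstep <- rep(1e-4, length(x0))
      g <- vapply(seq_along(x0), function(i) {
        e <- numeric(length(x0)); e[i] <- hstep[i]
        (f_free(x0 + e) - f_free(x0 - e)) / (2 * hstep[i])
      }, numeric(1))
      Hm <- num_hessian(f_free, x0, h = rep(5e-4, length(x0)))
      step <- tryCatch(solve(Hm, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      if (max(abs(step)) > 1) step <- step / max(abs(step))
      x1 <- pmin(pmax(x0 - step, lo), hi)
      if (f_free(x1) <= f_free(x0) + 1e-6) lg[free] <- x1 else break
      if (max(abs(x1 - x0)) < 1e-9) break
    }
    trajectory <- c(trajectory, prof(lg)$val)
  }
  at_opt <- prof(lg)
  se2_hat <- at_opt$se2
  th <- c(exp(lg[1]) * se2_hat, if (s > 0) exp(lg[2]) * se2_hat else 0, se2_hat)
  if (th[1] <= 2 * eps * se2_hat) th[1] <- 0
  if (s > 0 && th[2] <= 2 * eps * se2_hat) th[2] <- 0

  # unprofiled deviance, used for the observed information
  neg2logL <- function(thv) {
    sa <- max(thv[1], eps); sm <- max(thv[2], eps); se <- max(thv[3], eps)
    C <- WtW / se + Pa / sa + if (s > 0) Pm / sm else 0
    ld <- sparse_logdet(C)
    if (!is.finite(ld)) return(1e10)
    sol <- Matrix::solve(C, Wty / se)
    ypy <- yty / se - sum(sol * (Wty / se))
    as.numeric(n_ * log(se) + q * log(sa) + s * log(sm) + ld + ypy)
  }

  # observed information and SEs (guard boundary components)
  interior <- th > 1e-6 * se2_hat
  se_vec <- rep(NA_real_, 3)
  covmat <- matrix(NA_real_, 3, 3)
  if (any(interior)) {
    fI <- function(x) {
      full <- th; full[interior] <- x
      0.5 * neg2logL(pmax(full, eps))
    }
    Hm <- num_hessian(fI, th[interior], h = pmax(abs(th[interior]) * 5e-3, 1e-7))
    ok <- tryCatch({
      ci <- solve(Hm)
      covmat[interior, interior] <- ci
      se_vec[interior] <- sqrt(pmax(diag(as.matrix(ci)), 0))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) warning("observed information is singular; SEs unavailable")
  }

  tot <- sum(th)
  h2 <- th[1] / tot
  grad <- c((tot - th[1]) / tot^2, -th[1] / tot^2, -th[1] / tot^2)
  h2_se <- if (all(is.finite(covmat[interior, interior]))) {
    g <- grad; g[!interior] <- 0
    v <- drop(t(g) %*% ifelse(is.na(covmat), 0, covmat) %*% g)
    sqrt(max(v, 0))
  } else NA_real_

  # BLUP solutions at the optimum
  se_ <- th[3]; sa_ <- max(th[1], eps); sm_ <- max(th[2], eps)
  C <- WtW / se_ + Pa / sa_ + if (s > 0) Pm / sm_ else 0
  sol <- as.numeric(Matrix::solve(C, Wty / se_))
  names(th) <- c("sigma2_a", "sigma2_m", "sigma2_e")
  names(se_vec) <- names(th)
  structure(list(varcomp = th, se = se_vec, h2 = h2, h2_se = h2_se,
                 loglik = -at_opt$val / 2,
                 converged = fit$convergence == 0,
                 message = fit$message, trajectory = trajectory,
                 solutions = list(b = sol[seq_len(p)], a = sol[ia], m = sol[im])),
            class = "reml_fit")
}

# Shared precomputation for the bivariate likelihood: partitions records by
# trait-overlap pattern and caches the cross-product pieces that reassemble
# W'R^-1 W for any residual covariance.
bivariate_setup <- function(frame1, frame2, rel) {
  for (fr in list(frame1, frame2)) stopifnot(inherits(fr, "model_frame"))
  q <- frame1$q
  if (frame2$q != q || q != length(rel$ids)) stop("frames and relationship set must share the pedigree")
  # common maternal level set
  dl <- unique(c(frame1$dam_levels, frame2$dam_levels))
  s <- length(dl)
  if (is.null(frame1$dam_idx) || is.null(frame2$dam_idx)) {
    stop("bivariate models require frames built with maternal = TRUE")
  }
  Z2_1 <- Matrix::sparseMatrix(i = seq_len(frame1$n),
                               j = match(frame1$dam_levels, dl)[frame1$dam_idx],
                               x = 1, dims = c(frame1$n, s))
  Z2_2 <- Matrix::sparseMatrix(i = seq_len(frame2$n),
                               j = match(frame2$dam_levels, dl)[frame2$dam_idx],
                               x = 1, dims = c(frame2$n, s))
  p1 <- frame1$p; p2 <- frame2$p
  zero <- function(nr, nc) Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                                x = numeric(0), dims = c(nr, nc))
  # full design, trait-stacked: columns = [b1, b2, a1(q), a2(q), m1(s), m2(s)]
  W1 <- cbind(Matrix::Matrix(frame1$X, sparse = TRUE), zero(frame1$n, p2),
              frame1$Z1, zero(frame1$n, q), Z2_1, zero(frame1$n, s))
  W2 <- cbind(zero(frame2$n, p1), Matrix::Matrix(frame2$X, sparse = TRUE),
              zero(frame2$n, q), frame2$Z1, zero(frame2$n, s), Z2_2)
  both <- intersect(frame1$animal, frame2$animal)
  i1b <- match(both, frame1$animal)   # one record per animal per trait
  i2b <- match(both, frame2$animal)
  i1o <- setdiff(seq_len(frame1$n), i1b)
  i2o <- setdiff(seq_len(frame2$n), i2b)
  y1 <- frame1$y; y2 <- frame2$y
  piece <- function(Wa, ya, Wb = NULL, yb = NULL) {
    if (is.null(Wb)) {
      list(M = Matrix::forceSymmetric(Matrix::crossprod(Wa)),
           v = Matrix::crossprod(Wa, ya), yy = sum(ya^2))
    } else {
      list(M = Matrix::crossprod(Wa, Wb), v = NULL,
           yy = sum(ya * yb),
           v_ab = Matrix::crossprod(Wa, yb), v_ba = Matrix::crossprod(Wb, ya))
    }
  }
  # penalty-structure templates embedded at full MME dimension, so the
  # per-evaluation coefficient matrix is a plain linear combination
  p <- p1 + p2
  dim_c <- p + 2 * q + 2 * s
  Kt <- as(as(rel$Hinv, "generalMatrix"), "TsparseMatrix")
  emb <- function(ti, tj, oi, oj) {
    Matrix::sparseMatrix(i = ti + oi, j = tj + oj, x = Kt@x,
                         dims = c(dim_c, dim_c))
  }
  Ka11 <- emb(Kt@i + 1L, Kt@j + 1L, p, p)
  Ka22 <- emb(Kt@i + 1L, Kt@j + 1L, p + q, p + q)
  Ka12 <- emb(Kt@i + 1L, Kt@j + 1L, p, p + q) +
    emb(Kt@i + 1L, Kt@j + 1L, p + q, p)
  ms <- seq_len(s)
  Im11 <- Matrix::sparseMatrix(i = p + 2 * q + ms, j = p + 2 * q + ms, x = rep(1, s),
                               dims = c(dim_c, dim_c))
  Im22 <- Matrix::sparseMatrix(i = p + 2 * q + s + ms, j = p + 2 * q + s + ms,
                               x = rep(1, s), dims = c(dim_c, dim_c))
  Im12 <- Matrix::sparseMatrix(i = c(p + 2 * q + ms, p + 2 * q + s + ms),
                               j = c(p + 2 * q + s + ms, p + 2 * q + ms),
                               x = rep(1, 2 * s), dims = c(dim_c, dim_c))
  list(
    q = q, s = s, p = p, dim = dim_c,
    p1 = p1, p2 = p2,
    n1 = frame1$n, n2 = frame2$n, n_both = length(both),
    K = rel$Hinv,
    Ka11 = Ka11, Ka22 = Ka22, Ka12 = Ka12,
    Im11 = Im11, Im22 = Im22, Im12 = Im12,
    cache = new.env(parent = emptyenv()),
    P11b = piece(W1[i1b, , drop = FALSE], y1[i1b]),
    P11o = if (length(i1o)) piece(W1[i1o, , drop = FALSE], y1[i1o]) else NULL,
    P22b = piece(W2[i2b, , drop = FALSE], y2[i2b]),
    P22o = if (length(i2o)) piece(W2[i2o, , drop = FALSE], y2[i2o]) else NULL,
    P12b = piece(W1[i1b, , drop = FALSE], y1[i1b],
                 W2[i2b, , drop = FALSE], y2[i2b])
  )
}

# -2 restricted log-likelihood (up to an additive constant) for the bivariate
# model given 2x2 covariance matrices Sa, Sm, Se.
bivariate_neg2logL <- function(setup, Sa, Sm, Se) {
  for (S in list(Sa, Sm, Se)) {
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) return(1e10)
  }
  iSe <- solve(Se); iSa <- solve(Sa); iSm <- solve(Sm)
  su <- setup
  M <- iSe[1, 1] * su$P11b$M + iSe[2, 2] * su$P22b$M +
    iSe[1, 2] * (su$P12b$M + Matrix::t(su$P12b$M))
  v <- iSe[1, 1] * su$P11b$v + iSe[2, 2] * su$P22b$v +
    iSe[1, 2] * (su$P12b$v_ab + su$P12b$v_ba)
  yy <- iSe[1, 1] * su$P11b$yy + iSe[2, 2] * su$P22b$yy + 2 * iSe[1, 2] * su$P12b$yy
  ldR <- su$n_both * as.numeric(determinant(Se, logarithm = TRUE)$modulus)
  if (!is.null(su$P11o)) {
    M <- M + su$P11o$M / Se[1, 1]
    v <- v + su$P11o$v / Se[1, 1]
    yy <- yy + su$P11o$yy / Se[1, 1]
    ldR <- ldR + (su$n1 - su$n_both) * log(Se[1, 1])
  }
  if (!is.null(su$P22o)) {
    M <- M + su$P22o$M / Se[2, 2]
    v <- v + su$P22o$v / Se[2, 2]
    yy <- yy + su$P22o$yy / Se[2, 2]
    ldR <- ldR + (su$n2 - su$n_both) * log(Se[2, 2])
  }
  C <- M + iSa[1, 1] * su$Ka11 + iSa[2, 2] * su$Ka22 + iSa[1, 2] * su$Ka12 +
    iSm[1, 1] * su$Im11 + iSm[2, 2] * su$Im22 + iSm[1, 2] * su$Im12
  C <- Matrix::forceSymmetric(C)
  ch <- NULL
  if (!is.null(su$cache$factor)) {
    ch <- tryCatch(stats::update(su$cache$factor, C), error = function(e) NULL)
  }
  if (is.null(ch)) {
    ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE),
                   error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    su$cache$factor <- ch
  }
  ld <- 2 * as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus)
  if (!is.finite(ld)) return(1e10)
  sol <- Matrix::solve(ch, v, system = "A")
  ypy <- yy - sum(sol * v)
  val <- ldR + su$q * as.numeric(determinant(Sa, logarithm = TRUE)$modulus) +
    su$s * as.numeric(determinant(Sm, logarithm = TRUE)$modulus) + ld + ypy
  as.numeric(val)
}

theta_to_mats <- function(th) {
  mk <- function(v) matrix(c(v[1], v[2], v[2], v[3]), 2)
  list(Sa = mk(th[1:3]), Sm = mk(th[4:6]), Se = mk(th[7:9]))
}

# unconstrained Cholesky parameterization of a 2x2 covariance
par_to_cov <- function(p) {
  L <- matrix(c(exp(p[1]), p[2], 0, exp(p[3])), 2)
  L %*% t(L)
}
cov_to_par <- function(S) {
  L <- t(chol(S))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

#' Bivariate REML and genetic/phenotypic correlations
#'
#' Fits the two-trait single-step animal model with unstructured 2x2
#' additive, maternal permanent environmental and residual covariance
#' matrices (Kronecker products with H, I and I respectively), maximizing the
#' restricted likelihood over an unconstrained Cholesky parameterization (so
#' every iterate is positive definite). Reports the genetic correlation
#' `r_g = cov_a / sqrt(va1 va2)`, the phenotypic correlation from the summed
#' component (co)variances, delta-method SEs, and the +/- 2 SE significance
#' flags.
#'
#' @param frame1,frame2 [model_frame()]s for the two traits (may cover
#'   different, overlapping animal sets).
#' @param rel shared `relationship_set`.
#' @param start optional list with 2x2 matrices `Sa`, `Sm`, `Se`.
#' @param control passed to [stats::nlminb()].
#' @return object of class `bivariate_fit`: `Sa`, `Sm`, `Se`, `r_g`, `r_g_se`,
#'   `r_p`, `r_p_se`, `significant_g`, `significant_p`, `h2` (per trait),
#'   `loglik`, `converged`.
#' @export
reml_bivariate <- function(frame1, frame2, rel, start = NULL,
                           control = list(rel.tol = 1e-9)) {
  setup <- bivariate_setup(frame1, frame2, rel)
  v1 <- var(frame1$y); v2 <- var(frame2$y)
  if (is.null(start)) {
    # warm start: univariate fits give the diagonals, the phenotypic
    # correlation of the shared animals seeds every covariance
    u1 <- tryCatch(reml_univariate(frame1, rel, control = list(rel.tol = 1e-8)),
                   error = function(e) NULL)
    u2 <- tryCatch(reml_univariate(frame2, rel, control = list(rel.tol = 1e-8)),
                   error = function(e) NULL)
    both <- intersect(frame1$animal, frame2$animal)
    rp0 <- if (length(both) > 10) {
      cor(frame1$y[match(both, frame1$animal)], frame2$y[match(both, frame2$animal)])
    } else 0.1
    rp0 <- max(min(rp0, 0.9), -0.9)
    d <- function(u, v, i) if (!is.null(u)) max(u$varcomp[i], 0.02 * v) else
      c(0.3, 0.1, 0.6)[i] * v
    mk <- function(i) {
      x1 <- d(u1, v1, i); x2 <- d(u2, v2, i)
      matrix(c(x1, rp0 * sqrt(x1 * x2), rp0 * sqrt(x1 * x2), x2), 2)
    }
    start <- list(Sa = mk(1), Sm = mk(2), Se = mk(3))
  }
  par0 <- c(cov_to_par(start$Sa), cov_to_par(start$Sm), cov_to_par(start$Se))
  objective <- function(p) {
    bivariate_neg2logL(setup, par_to_cov(p[1:3]), par_to_cov(p[4:6]),
                       par_to_cov(p[7:9]))
  }
  fit <- nlminb(par0, objective, control = control)
  Sa <- par_to_cov(fit$par[1:3]); Sm <- par_to_cov(fit$par[4:6])
  Se <- par_to_cov(fit$par[7:9])
  th <- c(Sa[1, 1], Sa[1, 2], Sa[2, 2], Sm[1, 1], Sm[1, 2], Sm[2, 2],
          Se[1, 1], Se[1, 2], Se[2, 2])

  nll_theta <- function(t9) {
    m <- theta_to_mats(t9)
    # bending: repair a slightly indefinite probe to its nearest PSD + ridge
    fix <- function(S) {
      e <- eigen(S, symmetric = TRUE)
      if (min(e$values) <= 0) {
        S <- e$vectors %*% diag(pmax(e$values, 1e-10), 2) %*% t(e$vectors)
      }
      S
    }
    0.5 * bivariate_neg2logL(setup, fix(m$Sa), fix(m$Sm), fix(m$Se))
  }
  covth <- tryCatch(solve(num_hessian(nll_theta, th)), error = function(e) NULL)

  corr_fun_g <- function(t9) t9[2] / sqrt(t9[1] * t9[3])
  corr_fun_p <- function(t9) {
    (t9[2] + t9[5] + t9[8]) /
      sqrt((t9[1] + t9[4] + t9[7]) * (t9[3] + t9[6] + t9[9]))
  }
  delta_se <- function(fun) {
    if (is.null(covth)) return(NA_real_)
    g <- numeric(9)
    for (i in 1:9) {
      h <- max(abs(th[i]) * 1e-5, 1e-9)
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      g[i] <- (fun(tp) - fun(tm)) / (2 * h)
    }
    v <- drop(t(g) %*% covth %*% g)
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }
  r_g <- corr_fun_g(th); r_p <- corr_fun_p(th)
  r_g_se <- delta_se(corr_fun_g); r_p_se <- delta_se(corr_fun_p)
  tot <- c(th[1] + th[4] + th[7], th[3] + th[6] + th[9])
  structure(list(Sa = Sa, Sm = Sm, Se = Se,
                 r_g = r_g, r_g_se = r_g_se, r_p = r_p, r_p_se = r_p_se,
                 significant_g = significance(r_g, r_g_se),
                 significant_p = significance(r_p, r_p_se),
                 h2 = c(trait1 = th[1] / tot[1], trait2 = th[3] / tot[2]),
                 loglik = -fit$objective / 2, converged = fit$convergence == 0,
                 message = fit$message),
            class = "bivariate_fit")
}

#' Two-standard-error significance rule
#'
#' An estimate is declared significant when its absolute value exceeds twice
#' its standard error (an approximate 95% interval excluding zero).
#'
#' @param estimate the estimate.
#' @param se its standard error (>= 0); `NA` propagates.
#' @return logical flag (NA if `se` is NA).
#' @export
significance <- function(estimate, se) {
  if (is.na(se)) return(NA)
  if (se < 0) stop("standard error must be non-negative")
  abs(estimate) > 2 * se
}
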