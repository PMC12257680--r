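#' Deviations of aligned curves from the group mean
#'
#' Pointwise subtraction of the flock-year group mean curve from every
#' animal's aligned curve on the shared prediction grid. These deviation
#' series are the raw material of the general resilience indicators.
#'
#' @param aligned matrix grid x animals of aligned curve values.
#' @param mean_curve group mean curve on the same grid.
#' @param grid the shared grid.
#' @param ids animal ids (defaults to column names).
#' @return matrix of deviations (grid x animals), attribute `grid` attached.
#' @export
compute_deviations <- function(aligned, mean_curve, grid, ids = colnames(aligned)) {
  aligned <- as.matrix(aligned)
  if (nrow(aligned) != length(mean_curve) || nrow(aligned) != length(grid)) {
    stop("grid mismatch between aligned curves and mean curve")
  }
  dev <- aligned - mean_curve
  colnames(dev) <- ids
  attr(dev, "grid") <- grid
  dev
}

#' Log-variance of a deviation series
#'
#' Natural log of the (n-1)-denominator variance of the deviations. Lower
#' values indicate an animal tracking its contemporaries closely, i.e. higher
#' general resilience.
#'
#' @param x deviation values (>= 2).
#' @return the indicator, or `NA` when the variance is zero (flagged missing
#'   rather than `-Inf`).
#' @export
lnvar <- function(x) {
  if (length(x) < 2L) stop("need at least 2 deviations")
  v <- sum((x - mean(x))^2) / (length(x) - 1)
  if (v == 0) return(NA_real_)
  log(v)
}

#' Lag-1 autocorrelation of a deviation series
#'
#' `sum_{i<n} (x_i - xbar)(x_{i+1} - xbar) / sum_i (x_i - xbar)^2`: n-1 lagged
#' products over n squared terms. High positive values mean disturbances
#' persist across adjacent positions (slow recovery).
#'
#' @param x deviation values (>= 3).
#' @return the indicator, or `NA` for a zero denominator.
#' @export
auto_lag1 <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 deviations")
  xc <- x - mean(x)
  den <- sum(xc^2)
  if (den == 0) return(NA_real_)
  sum(xc[-n] * xc[-1]) / den
}

#' Skewness of a deviation series
#'
#' Mean of cubed standardized deviations, with the standard deviation using
#' the (n-1) denominator. Negative skewness signals predominantly downward
#' (unfavourable) excursions.
#'
#' @param x deviation values (>= 3).
#' @return the indicator, or `NA` for zero sd.
#' @export
dev_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 deviations")
  s <- sqrt(sum((x - mean(x))^2) / (n - 1))
  if (s == 0) return(NA_real_)
  sum(((x - mean(x)) / s)^3) / n
}

#' Mean absolute change of a deviation series
#'
#' `(1/(n-1)) sum_{i=2..n} |x_i - x_{i-1}|`: the average point-to-point jump,
#' capturing short-term instability.
#'
#' @param x deviation values (>= 2).
#' @return the indicator (always >= 0).
#' @export
abs_change <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 deviations")
  sum(abs(diff(x))) / (n - 1)
}

#' Detect the weaning collapse-and-recovery window on a group mean curve
#'
#' Starting from the weaning anchor, finds the first local minimum of the
#' group mean within `search_span` whose prominence (drop below the
#' surrounding values) reaches `prominence`, then the recovery crest after it.
#' Local extrema come from sign changes of first differences. Groups where no
#' qualifying minimum exists are flagged `detected = FALSE` and are excluded
#' from the weaning traits downstream.
#'
#' @param mean_curve group mean values on `grid`.
#' @param grid the group prediction grid.
#' @param anchor weaning anchor position (same units as `grid`).
#' @param search_span how far beyond the anchor to search (grid units);
#'   default half the grid range.
#' @param prominence minimum prominence; default 0.1 x sd of the mean curve.
#' @return object of class `weaning_window`: `t_w`, `t_min`, `t_max`,
#'   `detected`, plus the values of the mean curve at those positions.
#' @export
detect_weaning_window <- function(mean_curve, grid, anchor,
                                  search_span = diff(range(grid)) / 2,
                                  prominence = 0.1 * sd(mean_curve)) {
  if (anchor < min(grid) || anchor > max(grid)) stop("anchor outside grid")
  iw <- which.min(abs(grid - anchor))
  t_w <- grid[iw]
  span_end <- min(max(grid), t_w + search_span)
  ie <- max(which(grid <= span_end))
  undetected <- structure(list(t_w = t_w, t_min = NA_real_, t_max = NA_real_,
                               detected = FALSE, values = NULL),
                          class = "weaning_window")
  if (ie - iw < 2L) return(undetected)

  seg <- mean_curve[iw:ie]
  d <- diff(seg)
  # local minima: derivative sign change - to +
  mins <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  if (!length(mins)) return(undetected)
  for (m in mins) {
    left_max <- max(seg[1:m])
    right <- seg[m:length(seg)]
    right_max <- max(right)
    prom <- min(left_max, right_max) - seg[m]
    if (is.na(prom) || prom < prominence) next
    # recovery crest: first local max after the minimum, else the running max
    dr <- diff(right)
    maxs <- which(dr[-length(dr)] > 0 & dr[-1] <= 0) + 1L
    i_rel <- if (length(maxs)) maxs[1] else which.max(right)
    if (right[i_rel] - seg[m] < prominence) next
    i_min <- iw + m - 1L
    i_max <- i_min + i_rel - 1L
    return(structure(list(t_w = t_w, t_min = grid[i_min], t_max = grid[i_max],
                          detected = TRUE,
                          values = c(w = mean_curve[iw], min = mean_curve[i_min],
                                     max = mean_curve[i_max])),
                     class = "weaning_window"))
  }
  undetected
}

#' Map an age to a position along the wool staple
#'
#' Wool grows continuously between birth and sampling, so an age maps
#' proportionally to staple length, measured from the birth end (tip).
#'
#' @param age age in days, within `[0, sampling_age]`.
#' @param sampling_age age at wool sampling, days.
#' @param staple_length staple length, mm.
#' @return position in mm from the staple tip.
#' @export
map_age_to_staple <- function(age, sampling_age, staple_length) {
  if (any(age < 0 | age > sampling_age)) stop("age outside [0, sampling_age]")
  age / sampling_age * staple_length
}

#' Weaning response and recovery rates for one animal
#'
#' Rates of change of the animal's aligned curve across the group-level
#' weaning window: `ROC_response = (f(t_min) - f(t_w)) / (t_min - t_w)` and
#' `ROC_recovery = (f(t_max) - f(t_min)) / (t_max - t_min)`.
#'
#' @param f aligned animal curve values on `grid`.
#' @param grid group prediction grid.
#' @param window a detected [detect_weaning_window()] result.
#' @return named vector `c(ROC_response, ROC_recovery)`; both `NA` when the
#'   window is undetected.
#' @export
roc_traits <- function(f, grid, window) {
  if (!isTRUE(window$detected)) {
    return(c(ROC_response = NA_real_, ROC_recovery = NA_real_))
  }
  fa <- approx(grid, f, xout = c(window$t_w, window$t_min, window$t_max))$y
  c(ROC_response = (fa[2] - fa[1]) / (window$t_min - window$t_w),
    ROC_recovery = (fa[3] - fa[2]) / (window$t_max - window$t_min))
}

#' Area between an animal's curve and the group mean over the weaning window
#'
#' Composite-trapezoid area under the animal curve minus area under the group
#' mean over `[t_w, t_max]`. Negative values indicate a larger collapse and/or
#' slower recovery than the group.
#'
#' @param f aligned animal curve values on `grid`.
#' @param mean_curve group mean values on `grid`.
#' @param grid group prediction grid.
#' @param window a [detect_weaning_window()] result.
#' @return the ABC value, `NA` when the window is undetected.
#' @export
abc_trait <- function(f, mean_curve, grid, window) {
  if (!isTRUE(window$detected)) return(NA_real_)
  sel <- grid >= window$t_w & grid <= window$t_max
  xs <- grid[sel]
  if (length(xs) < 2L) return(NA_real_)
  trapz(xs, f[sel]) - trapz(xs, mean_curve[sel])
}

#' Flock-year 3-SD outlier filtering of a trait table
#'
#' Per trait and flock-year, masks (sets to `NA`) values lying more than
#' 3 group standard deviations from the group mean. A single pass: the mean
#' and sd include the outliers, and masking is not re-iterated.
#'
#' @param traits long `data.frame` with columns `animal`, `flock_year`,
#'   `trait`, `value` (extra columns are preserved).
#' @param n_sd threshold in group standard deviations (default 3).
#' @return list: `traits` (input with outliers masked and an `outlier_flag`
#'   column) and `log` (one row per masked cell).
#' @export
remove_outliers <- function(traits, n_sd = 3) {
  stopifnot(all(c("animal", "flock_year", "trait", "value") %in% names(traits)))
  out <- traits
  out$outlier_flag <- FALSE
  key <- interaction(traits$trait, traits$flock_year, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k & !is.na(traits$value))
    if (length(idx) < 3L) next
    v <- traits$value[idx]
    s <- sd(v)
    if (is.na(s) || s == 0) next
    bad <- abs(v - mean(v)) > n_sd * s
    out$outlier_flag[idx[bad]] <- TRUE
  }
  log <- out[out$outlier_flag, c("animal", "flock_year", "trait", "value")]
  out$value[out$outlier_flag] <- NA_real_
  rownames(log) <- NULL
  list(traits = out, log = log)
}

#' All seven resilience indicators for one aligned flock-year group
#'
#' Computes deviations from the group mean and derives Lnvar, Auto, Skewness
#' and ABS per animal, plus the weaning traits ROC_response, ROC_recovery and
#' ABC when a weaning window is detected on the group mean.
#'
#' @param aligned matrix grid x animals of aligned curves.
#' @param mean_curve group mean curve.
#' @param grid group prediction grid.
#' @param anchor weaning anchor position on the grid.
#' @param series series label ("FD" or "BW"), carried through.
#' @param flock_year group label, carried through.
#' @param ... passed to [detect_weaning_window()].
#' @return list: `traits` (long `data.frame` animal/series/flock_year/trait/
#'   value) and `window` (the `weaning_window`).
#' @export
group_indicators <- function(aligned, mean_curve, grid, anchor,
                             series = "FD", flock_year = NA_character_, ...) {
  dev <- compute_deviations(aligned, mean_curve, grid)
  ids <- colnames(aligned)
  window <- detect_weaning_window(mean_curve, grid, anchor, ...)
  rows <- lapply(seq_along(ids), function(j) {
    x <- dev[, j]
    roc <- roc_traits(aligned[, j], grid, window)
    data.frame(animal = ids[j], series = series, flock_year = flock_year,
               trait = c("Lnvar", "Auto", "Skewness", "ABS",
                         "ROC_response", "ROC_recovery", "ABC"),
               value = c(lnvar(x), auto_lag1(x), dev_skewness(x), abs_change(x),
                         roc[1], roc[2],
                         abc_trait(aligned[, j], mean_curve, grid, window)),
               stringsAsFactors = FALSE)
  })
  list(traits = do.call(rbind, rows), window = window)
}
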