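#' Euclidean distance from an origin
#'
#' @param coords obs x 2 coordinate matrix
#' @param origin length-2 numeric; default `c(0, 0)`. Passing the tissue
#'   centroid instead is often the better choice for datasets whose
#'   coordinate frame has an arbitrary corner origin.
#' @return non-negative numeric distance per observation
#' @export
distance_from_origin <- function(coords, origin = c(0, 0)) {
  C <- as.matrix(coords)
  sv_assert(ncol(C) == 2 && all(is.finite(C)), "`coords` must be finite obs x 2")
  sv_assert(length(origin) == 2 && all(is.finite(origin)),
            "`origin` must be a finite (x, y) pair")
  sqrt((C[, 1] - origin[1])^2 + (C[, 2] - origin[2])^2)
}

# equal-width bins over [min t, max t]; left-closed, last bin closed both
# ends, so every observation lands in exactly one bin
time_bins <- function(t, n_bins) {
  sv_assert(n_bins >= 2, "`n_bins` must be >= 2")
  rng <- range(t)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  if (rng[1] == rng[2]) {
    bin <- rep(1L, length(t))
  } else {
    bin <- findInterval(t, edges, rightmost.closed = TRUE)
    bin[bin > n_bins] <- n_bins
  }
  list(bin = bin, edges = edges)
}

#' Binned variance of distances over pseudotime
#'
#' Pseudotime is divided into `n_bins` equal-width intervals (default ten);
#' in each occupied bin the population variance (1/n, not the n-1 sample
#' estimator) of the distances is computed, with the bin timestamp taken as
#' the median pseudotime of its members. A cubic polynomial
#' `sigma^2 = a t^3 + b t^2 + c t + d` is fitted through the per-bin
#' variances against bin median time whenever at least four bins are
#' usable. Bins with fewer than 2 observations carry NA and are excluded
#' from the fit.
#'
#' @param d numeric distances per observation (see
#'   [distance_from_origin()])
#' @param t numeric pseudotime per observation, same length
#' @param n_bins number of equal-width intervals (default 10)
#' @return object of class `spatiotemporal_profile` with `bin_edges`,
#'   `bin_median_times`, `variances`, `n_per_bin`, and
#'   `cubic_coeffs_variance` (named a, b, c, d; NA if < 4 usable bins)
#' @export
binned_variance <- function(d, t, n_bins = 10) {
  sv_assert(length(d) == length(t), "`d` and `t` must have equal length")
  tb <- time_bins(t, n_bins)
  med <- vars <- rep(NA_real_, n_bins)
  nper <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    ix <- which(tb$bin == b)
    nper[b] <- length(ix)
    if (length(ix) < 2) next
    med[b] <- median(t[ix])
    db <- d[ix]
    vars[b] <- mean((db - mean(db))^2)   # population variance
  }
  ok <- is.finite(vars)
  cc <- if (sum(ok) >= 4) cubic_fit(med[ok], vars[ok])$coefficients else
    setNames(rep(NA_real_, 4), c("a", "b", "c", "d"))
  structure(list(bin_edges = tb$edges, bin_median_times = med,
                 variances = vars, n_per_bin = nper,
                 cubic_coeffs_variance = cc,
                 p_lo = NULL, p_hi = NULL,
                 cubic_coeffs_p_lo = NULL, cubic_coeffs_p_hi = NULL,
                 percentiles = NULL),
            class = "spatiotemporal_profile")
}

#' Least-squares cubic polynomial fit
#'
#' Fits `y = a x^3 + b x^2 + c x + d`. Needs at least 4 finite pairs; a
#' rank-deficient design (e.g. duplicated x with fewer than four distinct
#' abscissae) yields the minimum-norm least-squares solution with a
#' warning.
#'
#' @param x,y numeric vectors of equal length
#' @return list with `coefficients` (named a, b, c, d), `fitted`,
#'   `residual_ss`
#' @export
cubic_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  sv_assert(length(x) >= 4, "cubic fit needs at least 4 finite (x, y) pairs")
  X <- cbind(x^3, x^2, x, 1)
  qrX <- qr(X)
  if (qrX$rank < 4) {
    warning("rank-deficient cubic design (duplicated x): minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    beta <- as.numeric(beta)
  } else {
    beta <- qr.coef(qrX, y)
  }
  fitted <- as.numeric(X %*% beta)
  list(coefficients = setNames(as.numeric(beta), c("a", "b", "c", "d")),
       fitted = fitted, residual_ss = sum((y - fitted)^2))
}

#' Percentile trends of distances over pseudotime
#'
#' Robust proxies for the spatial extent of the population: per time bin,
#' the `lo`th and `hi`th percentiles of distance (linear interpolation
#' between order statistics, R's default type-7 quantile), each fitted with
#' the same cubic model as [binned_variance()]. Returns a full profile
#' (variance part included).
#'
#' @inheritParams binned_variance
#' @param lo,hi percentile bounds in \[0, 100\] (defaults 10 and 90)
#' @return a `spatiotemporal_profile` with `p_lo`, `p_hi`,
#'   `cubic_coeffs_p_lo`, `cubic_coeffs_p_hi` and `percentiles = c(lo, hi)`
#'   filled in addition to the variance fields
#' @export
percentile_trends <- function(d, t, n_bins = 10, lo = 10, hi = 90) {
  sv_assert(lo >= 0 && hi <= 100 && lo <= hi, "need 0 <= lo <= hi <= 100")
  prof <- binned_variance(d, t, n_bins)
  tb <- time_bins(t, n_bins)
  p_lo <- p_hi <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    ix <- which(tb$bin == b)
    if (length(ix) < 2) next
    qs <- stats::quantile(d[ix], c(lo, hi) / 100, names = FALSE, type = 7)
    p_lo[b] <- qs[1]; p_hi[b] <- qs[2]
  }
  fit_or_na <- function(y) {
    ok <- is.finite(y)
    if (sum(ok) >= 4) cubic_fit(prof$bin_median_times[ok], y[ok])$coefficients
    else setNames(rep(NA_real_, 4), c("a", "b", "c", "d"))
  }
  prof$p_lo <- p_lo
  prof$p_hi <- p_hi
  prof$cubic_coeffs_p_lo <- fit_or_na(p_lo)
  prof$cubic_coeffs_p_hi <- fit_or_na(p_hi)
  prof$percentiles <- c(lo, hi)
  prof
}

#' @export
print.spatiotemporal_profile <- function(x, ...) {
  occ <- sum(is.finite(x$variances))
  cat(sprintf("spatiotemporal_profile: %d/%d occupied bins\n",
              occ, length(x$variances)))
  if (any(is.finite(x$cubic_coeffs_variance))) {
    cat("  variance cubic:",
        paste(sprintf("%s=%.4g", names(x$cubic_coeffs_variance),
                      x$cubic_coeffs_variance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Mean nonzero expression per observation
#'
#' `Y_i` is the mean over the strictly positive entries of row i; all-zero
#' rows yield 0 and are flagged in the `"all_zero"` attribute.
#'
#' @param X obs x genes non-negative matrix
#' @return numeric vector with logical attribute `all_zero`
#' @export
mean_nonzero_expression <- function(X) {
  X <- as_dense(X)
  sv_assert(min(X) >= 0, "`X` must be non-negative")
  npos <- rowSums(X > 0)
  y <- ifelse(npos > 0, rowSums(X) / npos, 0)
  attr(y, "all_zero") <- npos == 0
  y
}

minmax01 <- function(x) {
  r <- range(x)
  if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0, length(x))
}

#' Per-cell-type time-versus-space regulation weight
#'
#' Models each spot's mean expression as a convex combination of its
#' developmental time and its spatial distance from the origin,
#' `Y'_i = omega T_i + (1 - omega) D_i`, with one omega shared by all spots
#' of a cell type. Since T, D and Y carry different units, each is min-max
#' rescaled to \[0, 1\] over the dataset before fitting (disable with
#' `rescale = FALSE` if inputs are already commensurate). The squared-error
#' loss `sum (Y' - Y)^2` is minimized per type in closed form:
#' `omega* = sum((T - D) (Y - D)) / sum((T - D)^2)`, clipped to \[0, 1\].
#' omega near 1 marks time-driven expression, near 0 space-driven.
#'
#' @param t pseudotime per observation
#' @param d spatial distance per observation (see
#'   [distance_from_origin()])
#' @param y mean expression per observation (see
#'   [mean_nonzero_expression()])
#' @param types cell-type label per observation
#' @param rescale min-max rescale t, d and y to \[0, 1\] first (default TRUE)
#' @return object of class `omega_estimates`: a tibble with columns `type`,
#'   `omega`, `loss`, `n`, `reason` (NA unless omega is undefined for a
#'   type)
#' @export
estimate_omega <- function(t, d, y, types, rescale = TRUE) {
  n <- length(t)
  sv_assert(length(d) == n && length(y) == n && length(types) == n,
            "t, d, y and types must be aligned per observation")
  if (rescale) {
    t <- minmax01(t); d <- minmax01(d); y <- minmax01(y)
  }
  types <- as.character(types)
  tys <- sv_sort(unique(types))
  res <- lapply(tys, function(ty) {
    ix <- types == ty
    tt <- t[ix]; dd <- d[ix]; yy <- y[ix]
    denom <- sum((tt - dd)^2)
    if (denom == 0) {
      return(tibble(type = ty, omega = NA_real_, loss = NA_real_,
                    n = sum(ix),
                    reason = "T and D identical within type: omega undefined"))
    }
    om <- sum((tt - dd) * (yy - dd)) / denom
    om <- min(1, max(0, om))
    loss <- sum((om * tt + (1 - om) * dd - yy)^2)
    tibble(type = ty, omega = om, loss = loss, n = sum(ix),
           reason = NA_character_)
  })
  out <- do.call(rbind, res)
  class(out) <- c("omega_estimates", class(out))
  out
}
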