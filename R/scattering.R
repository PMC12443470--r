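# Theoretical SAXS profiles, Guinier analysis and chi-square profile fitting.

#' Default q-grid for computed profiles
#' @param q_max upper bound, 1/Angstrom.
#' @param n number of points (including q = 0).
#' @return numeric vector from 0 to `q_max`.
#' @export
default_q_grid <- function(q_max = 0.5, n = 201L) seq(0, q_max, length.out = n)

#' Theoretical scattering profile by the Debye formula
#'
#' Exact orientational average of scattering from a rigid point set:
#' \deqn{I(q) = \sum_i \sum_j f_i f_j \frac{\sin(q r_{ij})}{q r_{ij}}}
#' with the sinc limit \eqn{\sin(x)/x \to 1} as \eqn{x \to 0}, so that
#' \eqn{I(0) = (\sum_i f_i)^2}. No hydration-shell or excluded-volume terms
#' are included: the profile is the vacuum scattering of the weighted beads,
#' which is sufficient for relative per-frame chi-square ranking.
#'
#' @param points N x 3 coordinates, Angstrom.
#' @param form_factors length-N non-negative weights; default all 1.
#' @param q_grid increasing q values >= 0, 1/Angstrom.
#' @return [saxs_curve()] on `q_grid`.
#' @export
debye_profile <- function(points, form_factors = NULL,
                          q_grid = default_q_grid()) {
  points <- as.matrix(points)
  if (is.vector(points) && length(points) == 3L) points <- matrix(points, 1L)
  stopifnot(ncol(points) == 3L, nrow(points) >= 1L)
  if (!all(is.finite(points))) stop("non-finite coordinate in points")
  n <- nrow(points)
  if (is.null(form_factors)) form_factors <- rep(1, n)
  stopifnot(length(form_factors) == n, all(form_factors >= 0))
  if (any(q_grid < 0) || any(diff(q_grid) <= 0))
    stop("q_grid must be non-negative and strictly increasing")
  f <- as.numeric(form_factors)
  self_term <- sum(f^2)
  if (n == 1L) {
    return(saxs_curve(q_grid, rep(self_term, length(q_grid))))
  }
  # pairwise distances from dist() come in lower-triangle column-major order
  # ((2,1), (3,1), ..., (n,1), (3,2), ...); build weight products to match
  d <- as.numeric(stats::dist(points))
  jj <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  ii <- unlist(lapply(seq_len(n - 1L), function(j) (j + 1L):n), use.names = FALSE)
  wpair <- f[ii] * f[jj]
  I <- vapply(q_grid, function(q) {
    if (q == 0) return(self_term + 2 * sum(wpair))
    x <- q * d
    s <- ifelse(x < 1e-8, 1, sin(x) / x)
    self_term + 2 * sum(wpair * s)
  }, numeric(1))
  saxs_curve(q_grid, I)
}

#' Radius of gyration of a weighted point set
#'
#' \eqn{R_g = \sqrt{\sum_i w_i |r_i - r_{cm}|^2 / \sum_i w_i}} with
#' \eqn{r_{cm}} the weighted center of mass.
#'
#' @param points N x 3 coordinates, Angstrom.
#' @param weights length-N non-negative weights, default all 1; must not sum
#'   to zero.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(points, weights = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  if (sum(weights) <= 0) stop("weights must not all be zero")
  w <- weights / sum(weights)
  cm <- colSums(points * w)
  sqrt(sum(w * rowSums(sweep(points, 2, cm)^2)))
}

#' Guinier analysis of a scattering curve
#'
#' Weighted linear regression of \eqn{\ln I} on \eqn{q^2} over the small-q
#' window \eqn{q R_g \le} `qRg_limit`: slope \eqn{= -R_g^2/3}, intercept
#' \eqn{= \ln I(0)}. The window is chosen by iterating the fit to
#' self-consistency on Rg, starting from the smallest-q points.
#'
#' @param curve saxs_curve; intensities inside the window must be positive.
#' @param qRg_limit Guinier validity bound, default 1.3.
#' @param max_iter self-consistency iteration cap.
#' @return list with `I0`, `rg` (Angstrom), `n_points`, `q_window`
#'   (range of q used) and `converged`.
#' @export
guinier_fit <- function(curve, qRg_limit = 1.3, max_iter = 50L) {
  stopifnot(inherits(curve, "saxs_curve"))
  use0 <- curve$q > 0
  q <- curve$q[use0]; I <- curve$I[use0]
  sg <- if (!is.null(curve$sigma)) curve$sigma[use0] else NULL
  fit_window <- function(sel) {
    if (any(I[sel] <= 0)) stop("non-positive intensity inside Guinier window")
    y <- log(I[sel]); x <- q[sel]^2
    w <- if (!is.null(sg)) (I[sel] / sg[sel])^2 else rep(1, sum(sel))
    fit <- stats::lm(y ~ x, weights = w)
    cf <- stats::coef(fit)
    if (cf[2] >= 0) stop("non-negative Guinier slope: no Rg can be estimated")
    list(I0 = exp(cf[1]), rg = sqrt(-3 * cf[2]))
  }
  # start with the 5 smallest-q points (or 3 if fewer available)
  sel <- seq_along(q) <= max(3L, min(5L, length(q)))
  if (sum(sel) < 3L) stop("no valid Guinier window: fewer than 3 points")
  est <- fit_window(sel)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    new_sel <- q * est$rg <= qRg_limit
    if (sum(new_sel) < 3L)
      stop("no valid Guinier window: fewer than 3 points satisfy q*Rg <= ",
           qRg_limit)
    if (identical(new_sel, sel)) { converged <- TRUE; break }
    sel <- new_sel
    est <- fit_window(sel)
  }
  list(I0 = unname(est$I0), rg = unname(est$rg), n_points = sum(sel),
       q_window = range(q[sel]), converged = converged)
}

#' Chi-square fit of a computed profile against an experimental curve
#'
#' Finds the scale c (and optional constant background b) minimizing
#' \eqn{\sum_k [(I_{exp,k} - c I_{calc,k} - b)/\sigma_k]^2} by closed-form
#' weighted least squares, after linear interpolation of the computed curve
#' onto the experimental q-grid (no extrapolation: the experimental grid must
#' lie inside the computed one). Curves without sigma get a uniform
#' substitute `0.01 * max(I_exp)` (flagged in the result).
#'
#' @param calc computed saxs_curve.
#' @param exp_curve experimental saxs_curve.
#' @param fit_background logical; fit the constant offset b (default FALSE).
#' @param normalization chi-square denominator: `"n-p"` (default; p = number
#'   of fitted parameters), `"n-1"`, or `"n"`.
#' @return list with `scale_c`, `offset_b`, `chi2`, `n_points`, `residuals`
#'   (standardized), `sigma_substituted`.
#' @export
fit_profile <- function(calc, exp_curve, fit_background = FALSE,
                        normalization = c("n-p", "n-1", "n")) {
  stopifnot(inherits(calc, "saxs_curve"), inherits(exp_curve, "saxs_curve"))
  normalization <- match.arg(normalization)
  if (min(exp_curve$q) < min(calc$q) - 1e-12 ||
      max(exp_curve$q) > max(calc$q) + 1e-12)
    stop("experimental q-range extends beyond the computed curve; ",
         "no extrapolation is performed")
  Ic <- stats::approx(calc$q, calc$I, xout = exp_curve$q)$y
  Ie <- exp_curve$I
  n <- length(Ie)
  p <- if (fit_background) 2L else 1L
  if (n < p + 1L) stop("fewer experimental points (", n,
                       ") than fitted parameters + 1")
  sigma_substituted <- is.null(exp_curve$sigma)
  sg <- if (sigma_substituted) rep(0.01 * max(Ie, 1e-12), n) else exp_curve$sigma
  w <- 1 / sg^2
  if (fit_background) {
    sw <- sum(w); swc <- sum(w * Ic); swe <- sum(w * Ie)
    swcc <- sum(w * Ic^2); swce <- sum(w * Ic * Ie)
    den <- sw * swcc - swc^2
    if (abs(den) < 1e-300) stop("degenerate design in background fit")
    c_hat <- (sw * swce - swc * swe) / den
    b_hat <- (swe - c_hat * swc) / sw
  } else {
    c_hat <- sum(w * Ic * Ie) / sum(w * Ic^2)
    b_hat <- 0
  }
  resid <- (Ie - c_hat * Ic - b_hat) / sg
  dof <- switch(normalization, "n-p" = n - p, "n-1" = n - 1L, "n" = n)
  list(scale_c = c_hat, offset_b = b_hat,
       chi2 = sum(resid^2) / dof,
       n_points = n, residuals = resid,
       sigma_substituted = sigma_substituted)
}

#' Screen every frame of an ensemble against an experimental SAXS curve
#'
#' Computes a Debye profile for each frame over the selected atoms, fits it
#' to the experimental curve and ranks frames by chi-square; the frame in
#' best agreement with the data is the chi-square argmin (ties broken toward
#' the lowest frame index).
#'
#' @param ensemble conformer_ensemble.
#' @param exp_curve experimental saxs_curve.
#' @param selection logical or integer index into the topology atoms, or the
#'   string `"CA"` (default) for C-alpha atoms.
#' @param form_factors per-selected-atom weights; default all 1.
#' @param q_grid q-grid for the computed profiles; by default the
#'   experimental grid itself, so no interpolation is involved.
#' @param fit_background,normalization passed to [fit_profile()].
#' @return list with `chi2_per_frame`, `best_frame` (1-based), `table`
#'   (data.frame frame/chi2/scale/offset), and `curve_best` (the scaled
#'   computed profile of the best frame on the experimental grid).
#' @export
screen_ensemble <- function(ensemble, exp_curve, selection = "CA",
                            form_factors = NULL, q_grid = NULL,
                            fit_background = FALSE,
                            normalization = "n-p") {
  stopifnot(inherits(ensemble, "conformer_ensemble"),
            inherits(exp_curve, "saxs_curve"))
  idx <- resolve_selection(ensemble$topology, selection)
  if (!length(idx)) stop("empty atom selection")
  if (is.null(q_grid)) q_grid <- exp_curve$q
  m <- n_frames(ensemble)
  fits <- vector("list", m)
  for (k in seq_len(m)) {
    prof <- debye_profile(ensemble$frames[k, idx, , drop = TRUE],
                          form_factors, q_grid)
    fits[[k]] <- fit_profile(prof, exp_curve, fit_background, normalization)
  }
  chi2 <- vapply(fits, `[[`, numeric(1), "chi2")
  best <- which.min(chi2)  # which.min takes the first (lowest-index) minimum
  best_fit <- fits[[best]]
  prof_best <- debye_profile(ensemble$frames[best, idx, , drop = TRUE],
                             form_factors, q_grid)
  Ic <- stats::approx(prof_best$q, prof_best$I, xout = exp_curve$q)$y
  list(chi2_per_frame = chi2,
       best_frame = best,
       table = data.frame(frame = seq_len(m),
                          chi2 = chi2,
                          scale = vapply(fits, `[[`, numeric(1), "scale_c"),
                          offset = vapply(fits, `[[`, numeric(1), "offset_b")),
       curve_best = saxs_curve(exp_curve$q,
                               best_fit$scale_c * Ic + best_fit$offset_b))
}

# resolve an atom selection against a structure_model topology
resolve_selection <- function(model, selection) {
  at <- model$atoms
  if (is.character(selection) && length(selection) == 1L) {
    if (identical(selection, "all")) return(seq_len(nrow(at)))
    return(which(at$atom_name == selection))
  }
  if (is.logical(selection)) {
    stopifnot(length(selection) == nrow(at))
    return(which(selection))
  }
  as.integer(selection)
}
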