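# Synthetic inputs with the statistical structure the analysis assumes:
# C2-symmetric bead dimers, hinge-opening ensembles with thermal noise and a
# mobile loop, noisy synthetic SAXS experiments, crystal mimics.

#' Rotate points about an axis (Rodrigues)
#' @param points N x 3 matrix.
#' @param origin point on the axis.
#' @param axis axis direction (need not be unit length).
#' @param angle_deg rotation angle in degrees, right-hand rule about `axis`.
#' @return rotated N x 3 matrix.
#' @export
rotate_about_axis <- function(points, origin, axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(as.matrix(points), 2, origin) %*% t(R), 2, origin, `+`)
}

# one smooth, self-avoiding bead curve: a toroidal coil sampled at an exact
# 3.8 A consecutive chord length (the canonical C-alpha virtual bond).
bead_coil <- function(n_res, spacing = 3.8) {
  n_coils <- max(6, ceiling(n_res / 13))
  R <- max(14, 0.75 * n_coils)        # keeps coil-to-coil pitch >= ~4.7 A
  a <- 8
  tt <- seq(0, 2 * pi, length.out = max(20000L, 50L * n_res))
  dense <- cbind((R + a * cos(n_coils * tt)) * cos(tt),
                 (R + a * cos(n_coils * tt)) * sin(tt),
                 a * sin(n_coils * tt))
  beads <- matrix(NA_real_, n_res, 3)
  beads[1, ] <- dense[1, ]
  i <- 2L
  for (k in 2:n_res) {
    last <- beads[k - 1L, ]
    while (i <= nrow(dense) &&
           sum((dense[i, ] - last)^2) < spacing^2) i <- i + 1L
    if (i > nrow(dense))
      stop("bead curve exhausted before ", n_res, " residues")
    # exact chord: solve |p0 + s (p1 - p0) - last| = spacing on the segment
    p0 <- dense[i - 1L, ]; p1 <- dense[i, ]
    dvec <- p1 - p0; f0 <- p0 - last
    A <- sum(dvec^2); B <- 2 * sum(f0 * dvec); C <- sum(f0^2) - spacing^2
    s <- (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
    beads[k, ] <- p0 + s * dvec
  }
  beads
}

#' Build a C2-symmetric bead dimer template
#'
#' Chain A is a smooth self-avoiding bead curve (one C-alpha bead per
#' residue, exact 3.8 Angstrom consecutive spacing); chain B is its exact C2
#' image about `fold_axis`. Chain B is then rotated rigidly about the axis
#' through the two `marker2` beads so that the template's hinge dihedral
#' marker1A-marker2A-marker2B-marker1B is exactly zero — the template is the
#' closed (theta = 0) reference state. Deterministic: the same arguments
#' always give bitwise-identical coordinates.
#'
#' @param n_res residues per chain, >= 10; default 480 (the AADC-like
#'   numbering through residue 470).
#' @param fold_axis direction of the two-fold axis through the origin,
#'   default z.
#' @param marker1,marker2 hinge marker residues, defaults 173 and 470.
#' @return structure_model with chains `A` and `B`.
#' @export
make_dimer_template <- function(n_res = 480L, fold_axis = c(0, 0, 1),
                                marker1 = 173L, marker2 = 470L) {
  if (n_res < 10L) stop("n_res must be at least 10")
  stopifnot(marker1 >= 1, marker1 <= n_res, marker2 >= 1, marker2 <= n_res,
            marker1 != marker2)
  xa <- bead_coil(n_res)
  # offset the chain off the fold axis so the C2 image does not overlap
  span <- max(xa[, 1]) - min(xa[, 1])
  xa[, 1] <- xa[, 1] - mean(range(xa[, 1])) + span / 2 + 6
  xb <- rotate_about_axis(xa, c(0, 0, 0), fold_axis, 180)
  mk <- function(ch, xyz) data.frame(
    chain = ch, res_seq = seq_len(n_res), res_name = "ALA", atom_name = "CA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = 0, occ = 1,
    stringsAsFactors = FALSE)
  model <- structure_model(rbind(mk("A", xa), mk("B", xb)))
  # zero the hinge dihedral by rotating chain B about the marker2 axis
  m1a <- locate_atom(model, "A", marker1); m1b <- locate_atom(model, "B", marker1)
  m2a <- locate_atom(model, "A", marker2); m2b <- locate_atom(model, "B", marker2)
  if (sqrt(sum((m2b - m2a)^2)) < 1e-6)
    stop("marker2 beads coincide: hinge axis undefined")
  th0 <- dihedral_angle(m1a, m2a, m2b, m1b)
  sel <- model$atoms$chain == "B"
  xyz_b <- as.matrix(model$atoms[sel, c("x", "y", "z")])
  # rotating chain B by +phi about the marker axis shifts the dihedral by -phi
  xyz_b <- rotate_about_axis(xyz_b, m2a, m2b - m2a, th0)
  model$atoms[sel, c("x", "y", "z")] <- xyz_b
  attr(model, "markers") <- c(marker1 = marker1, marker2 = marker2)
  model
}

#' Specification of a synthetic hinge-opening ensemble
#'
#' Describes the study conditions the generator emulates: a C2 dimer whose
#' chain B opens about the axis through the two `marker2` residues by a
#' per-frame dihedral, per-atom Gaussian thermal noise, and a flexible-loop
#' region with inflated fluctuations.
#'
#' @param n_res residues per chain, default 480.
#' @param marker1,marker2 hinge markers, defaults 173, 470.
#' @param theta_list hinge dihedral per frame in degrees; default 20 frames
#'   from 0 to 38 degrees in 2-degree steps.
#' @param sigma_thermal Gaussian displacement SD per axis, Angstrom;
#'   default 0.5.
#' @param loop_range residue interval with inflated noise; default 324:357
#'   (the flexible-loop numbering of the AADC-like chain) when it fits in
#'   `n_res`, otherwise the central fifth of the chain.
#' @param loop_factor noise multiplier inside `loop_range`, >= 1; default 3.
#' @param seed integer seed; required whenever `sigma_thermal > 0`.
#' @return list of class `hinge_spec`.
#' @export
hinge_ensemble_spec <- function(n_res = 480L, marker1 = 173L, marker2 = 470L,
                                theta_list = seq(0, 38, by = 2),
                                sigma_thermal = 0.5,
                                loop_range = NULL, loop_factor = 3,
                                seed = NULL) {
  stopifnot(n_res >= 10L, marker1 >= 1, marker1 <= n_res,
            marker2 >= 1, marker2 <= n_res, sigma_thermal >= 0,
            loop_factor >= 1, length(theta_list) >= 1)
  if (is.null(loop_range)) {
    loop_range <- if (n_res >= 357L) 324:357 else
      seq(floor(n_res * 0.4), ceiling(n_res * 0.6))
  }
  if (any(loop_range < 1) || any(loop_range > n_res))
    stop("loop_range outside 1..n_res")
  if (sigma_thermal > 0 && is.null(seed))
    stop("a seed is required when sigma_thermal > 0 (no hidden entropy)")
  structure(list(n_res = as.integer(n_res), marker1 = as.integer(marker1),
                 marker2 = as.integer(marker2),
                 theta_list = as.numeric(theta_list),
                 sigma_thermal = sigma_thermal,
                 loop_range = as.integer(loop_range),
                 loop_factor = loop_factor,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "hinge_spec")
}

#' Generate a hinge-opening conformer ensemble
#'
#' Frame k is the [make_dimer_template()] dimer with chain B rotated about
#' the marker2A-marker2B axis so that the hinge dihedral
#' marker1A-marker2A-marker2B-marker1B equals `theta_list[k]` before noise;
#' i.i.d. Gaussian displacements of SD `sigma_thermal` per axis are then
#' added, multiplied by `loop_factor` for residues inside `loop_range` (both
#' chains). Fully reproducible under the spec's seed.
#'
#' @param spec [hinge_ensemble_spec()].
#' @return conformer_ensemble with one frame per entry of `theta_list`.
#' @export
generate_hinge_ensemble <- function(spec) {
  stopifnot(inherits(spec, "hinge_spec"))
  template <- make_dimer_template(spec$n_res, marker1 = spec$marker1,
                                  marker2 = spec$marker2)
  at <- template$atoms
  m2a <- locate_atom(template, "A", spec$marker2)
  m2b <- locate_atom(template, "B", spec$marker2)
  axis <- m2b - m2a
  if (sqrt(sum(axis^2)) < 1e-6) stop("hinge axis degenerate")
  m1a <- locate_atom(template, "A", spec$marker1)
  m1b <- locate_atom(template, "B", spec$marker1)
  # reject markers lying on the hinge axis (dihedral undefined)
  for (p in list(m1a, m1b)) {
    w <- p - m2a
    perp <- w - axis * sum(w * axis) / sum(axis^2)
    if (sqrt(sum(perp^2)) < 1e-6)
      stop("marker1 bead lies on the hinge axis: dihedral undefined")
  }
  sel_b <- which(at$chain == "B")
  base <- as.matrix(at[, c("x", "y", "z")])
  m <- length(spec$theta_list)
  n <- nrow(at)
  arr <- array(NA_real_, c(m, n, 3L))
  loop_rows <- at$res_seq %in% spec$loop_range
  if (spec$sigma_thermal > 0) set.seed(spec$seed)
  for (k in seq_len(m)) {
    xyz <- base
    if (spec$theta_list[k] != 0)
      xyz[sel_b, ] <- rotate_about_axis(base[sel_b, ], m2a, axis,
                                        -spec$theta_list[k])
    if (spec$sigma_thermal > 0) {
      noise <- matrix(stats::rnorm(n * 3L, sd = spec$sigma_thermal), n, 3L)
      noise[loop_rows, ] <- noise[loop_rows, ] * spec$loop_factor
      xyz <- xyz + noise
    }
    arr[k, , ] <- xyz
  }
  conformer_ensemble(template, arr)
}

#' Simulate a noisy SAXS experiment from a structure
#'
#' Computes the Debye profile of the model's beads and perturbs it with the
#' multiplicative-plus-floor error model of synchrotron batch measurements:
#' \deqn{I_{exp}(q) = I_{true}(q)\,(1 + \epsilon_q),\quad
#'   \epsilon_q \sim N(0, noise\_frac)} with reported uncertainty
#' \eqn{\sigma_q = noise\_frac \cdot I_{true}(q) + floor\_frac \cdot
#' \max I_{true}}. With both fractions zero the exact computed curve is
#' returned (without a sigma column).
#'
#' @param model structure_model (or one ensemble frame).
#' @param noise_frac relative multiplicative noise SD, >= 0; default 0.02.
#' @param floor_frac additive sigma floor as a fraction of the intensity
#'   maximum, >= 0; default 1e-5. The forward scattering of a dimer exceeds
#'   the wide-angle intensity by about four orders of magnitude, so the
#'   floor must stay far below the maximum or it dominates the error bars
#'   at every informative q.
#' @param q_grid experimental q-grid (q > 0); default 70 points on
#'   0.01..0.35 1/Angstrom.
#' @param selection atom selection, default C-alpha.
#' @param seed integer seed; required when `noise_frac > 0`.
#' @return saxs_curve with sigma (unless both fractions are zero).
#' @export
synth_saxs_experiment <- function(model, noise_frac = 0.02,
                                  floor_frac = 1e-5,
                                  q_grid = seq(0.01, 0.35, length.out = 70L),
                                  selection = "CA", seed = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (noise_frac < 0 || floor_frac < 0)
    stop("noise parameters must be non-negative")
  idx <- resolve_selection(model, selection)
  true <- debye_profile(coords(model)[idx, , drop = FALSE], q_grid = q_grid)
  if (noise_frac == 0 && floor_frac == 0) return(true)
  if (noise_frac > 0) {
    if (is.null(seed)) stop("a seed is required when noise_frac > 0")
    set.seed(seed)
    eps <- stats::rnorm(length(q_grid), sd = noise_frac)
  } else eps <- rep(0, length(q_grid))
  sigma <- noise_frac * true$I + floor_frac * max(true$I)
  saxs_curve(q_grid, true$I * (1 + eps), sigma)
}

#' Make a crystal-structure mimic with a missing loop
#'
#' Removes the atoms of `missing_range` (emulating a disordered stretch with
#' no electron density) and assigns B-factors, either from an RMSF profile
#' through \eqn{B = (8\pi^2/3)\,RMSF^2} or as a constant.
#'
#' @param model structure_model.
#' @param missing_range residue interval to delete; must lie inside the
#'   model's residues.
#' @param chains chains the deletion applies to; default all chains.
#' @param rmsf_source optional data.frame from [rmsf_profile()] (columns
#'   `chain`, `res_id`, `rmsf`) used to set B-factors.
#' @param default_b constant B-factor (Angstrom squared) when no RMSF source
#'   is given; default 20.
#' @return structure_model with the stretch removed and B-factors set.
#' @export
make_crystal_mimic <- function(model, missing_range, chains = NULL,
                               rmsf_source = NULL, default_b = 20) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  if (is.null(chains)) chains <- unique(at$chain)
  present <- unique(at$res_seq[at$chain %in% chains])
  if (!all(missing_range %in% present))
    stop("missing_range extends outside the model's residues")
  drop <- at$chain %in% chains & at$res_seq %in% missing_range
  at <- at[!drop, , drop = FALSE]
  if (!nrow(at)) stop("deletion removed every atom")
  if (is.null(rmsf_source)) {
    at$b <- default_b
  } else {
    key_at <- paste(at$chain, at$res_seq)
    key_rm <- paste(rmsf_source$chain, rmsf_source$res_id)
    hit <- match(key_at, key_rm)
    if (any(is.na(hit)))
      stop("rmsf_source lacks residues present in the model")
    at$b <- B_FROM_RMSF * rmsf_source$rmsf[hit]^2
  }
  structure_model(at)
}
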