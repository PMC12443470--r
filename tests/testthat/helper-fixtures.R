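# Shared fixtures and independent oracles for the test suite.
# Templates are cached per size: building one is deterministic but not free.

.fixture_cache <- new.env(parent = emptyenv())

cached_template <- function(n_res, marker1, marker2) {
  key <- paste0("tmpl_", n_res, "_", marker1, "_", marker2)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- make_dimer_template(n_res, marker1 = marker1,
                                                 marker2 = marker2)
  .fixture_cache[[key]]
}

# desk-scale dimer used throughout: 120 residues per chain, hinge markers at
# residues 40 (probe) and 110 (axis)
small_template <- function() cached_template(120L, 40L, 110L)

small_spec <- function(theta_list, sigma_thermal = 0, seed = NULL, ...) {
  hinge_ensemble_spec(n_res = 120L, marker1 = 40L, marker2 = 110L,
                      theta_list = theta_list,
                      sigma_thermal = sigma_thermal, seed = seed, ...)
}

# hand-built fixed-column PDB text
pdb_atom_line <- function(serial, name, resn, chain, resi, x, y, z,
                          occ = 1, b = 0, altloc = " ") {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resn, chain, resi, x, y, z, occ, b)
}

# build an ensemble directly from a coordinate list (topology = k-th atom of
# chain A, residues numbered 1..N)
toy_ensemble <- function(frame_list) {
  n <- nrow(frame_list[[1L]])
  topo <- structure_model(data.frame(
    chain = "A", res_seq = seq_len(n), res_name = "ALA", atom_name = "CA",
    x = frame_list[[1L]][, 1], y = frame_list[[1L]][, 2],
    z = frame_list[[1L]][, 3], b = 0, occ = 1))
  conformer_ensemble(topo, frame_list)
}

# ---- independent oracles ----------------------------------------------------

# Debye sum as an explicit double loop (no vectorization shared with the
# implementation)
debye_brute <- function(points, f, q) {
  n <- nrow(points)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r <- sqrt(sum((points[i, ] - points[j, ])^2))
    x <- q * r
    total <- total + f[i] * f[j] * (if (x < 1e-12) 1 else sin(x) / x)
  }
  total
}

# 1-D grid search for the profile scale factor, refined by optimize()
grid_fit_oracle <- function(Ic, Ie, sg, dof) {
  rss <- function(cc) sum(((Ie - cc * Ic) / sg)^2)
  grid <- seq(0.01, 10, length.out = 20000L)
  c0 <- grid[which.min(vapply(grid, rss, numeric(1)))]
  opt <- stats::optimize(rss, c(c0 - 0.01, c0 + 0.01), tol = 1e-12)
  list(scale = opt$minimum, chi2 = opt$objective / dof)
}

# reference gromos clustering written against the distance matrix only
gromos_reference <- function(D, cutoff) {
  m <- nrow(D)
  left <- seq_len(m)
  assign <- integer(m)
  centers <- integer(0)
  cl <- 0L
  while (length(left)) {
    cl <- cl + 1L
    nb <- lapply(left, function(i) left[D[i, left] <= cutoff])
    counts <- lengths(nb)
    pick <- which(counts == max(counts))[1L]
    centers <- c(centers, left[pick])
    members <- nb[[pick]]
    assign[members] <- cl
    left <- setdiff(left, members)
  }
  list(assignments = assign, centers = centers)
}

# brute-force NSD over a 10-degree Euler-angle grid with local refinement
nsd_grid_oracle <- function(a, b) {
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  da <- dimerhinge:::mean_nn_dist(a); db <- dimerhinge:::mean_nn_dist(b)
  val <- function(R, tr = c(0, 0, 0))
    dimerhinge:::nsd_fixed(a0, sweep(b0 %*% t(R), 2, tr, `+`), da, db)
  step <- 10 * pi / 180
  best <- Inf; best_p <- NULL
  for (az in seq(0, 2 * pi - step, by = step))
    for (el in seq(0, pi, by = step))
      for (rr in seq(0, 2 * pi - step, by = step)) {
        v <- val(dimerhinge:::rot_from_angles(c(az, el, rr)))
        if (v < best) { best <- v; best_p <- c(az, el, rr) }
      }
  opt <- stats::optim(c(best_p, 0, 0, 0), function(p)
    val(dimerhinge:::rot_from_angles(p[1:3]), p[4:6]),
    method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-12))
  min(best, opt$value)
}

# rigid-body RMSD minimum by direct numeric optimization (no SVD)
rmsd_numeric_oracle <- function(mobile, target) {
  obj <- function(p) {
    R <- dimerhinge:::rot_from_angles(p[1:3])
    moved <- sweep(mobile %*% t(R), 2, p[4:6], `+`)
    sqrt(mean(rowSums((moved - target)^2)))
  }
  best <- Inf
  for (s in 1:5) {
    set.seed(s)
    opt <- stats::optim(c(runif(3, -pi, pi), rnorm(3)), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    opt <- stats::optim(opt$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, opt$value)
  }
  best
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_r <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_r)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
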