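# Per-residue and per-frame ensemble statistics: RMSF/B-factor, RMSD/Rg
# series, gromos clustering, dynamics cross-correlation.

B_FROM_RMSF <- 8 * pi^2 / 3

# superpose every frame of an M x N x 3 array onto a reference structure;
# two-pass: fit to the initial reference mean, recompute the mean, refit.
superpose_frames <- function(arr, fit_reference = c("mean", "first"),
                             passes = 2L) {
  fit_reference <- match.arg(fit_reference)
  m <- dim(arr)[1]
  ref <- if (fit_reference == "first") arr[1, , , drop = TRUE] else
    apply(arr, c(2, 3), mean)
  for (pass in seq_len(passes)) {
    for (k in seq_len(m)) {
      sup <- kabsch_superpose(arr[k, , , drop = TRUE], ref)
      arr[k, , ] <- apply_superposition(arr[k, , , drop = TRUE], sup)
    }
    ref <- apply(arr, c(2, 3), mean)
  }
  arr
}

#' Per-residue root mean square fluctuation with B-factor conversion
#'
#' RMSF of each selected atom about its ensemble-mean position, after
#' optional least-squares superposition of every frame (two-pass fit to the
#' ensemble mean). The predicted crystallographic B-factor uses the harmonic
#' relation \eqn{B = (8\pi^2/3)\,RMSF^2}.
#'
#' @param ensemble conformer_ensemble with >= 2 frames.
#' @param selection atom selection as in [screen_ensemble()]; default C-alpha.
#' @param fit_reference `"mean"` (default) or `"first"`.
#' @param superpose logical; set FALSE to analyse raw coordinates.
#' @return data.frame with `chain`, `res_id`, `rmsf` (Angstrom) and `b_pred`
#'   (Angstrom squared).
#' @export
rmsf_profile <- function(ensemble, selection = "CA",
                         fit_reference = c("mean", "first"),
                         superpose = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  fit_reference <- match.arg(fit_reference)
  if (n_frames(ensemble) < 2L) stop("RMSF needs at least 2 frames")
  idx <- resolve_selection(ensemble$topology, selection)
  if (!length(idx)) stop("empty atom selection")
  arr <- ensemble$frames[, idx, , drop = FALSE]
  if (superpose) arr <- superpose_frames(arr, fit_reference)
  mu <- apply(arr, c(2, 3), mean)
  dev2 <- sweep(arr, c(2, 3), mu)^2
  msf <- apply(dev2, 2, function(x) mean(rowSums(matrix(x, ncol = 3))))
  at <- ensemble$topology$atoms[idx, ]
  data.frame(chain = at$chain, res_id = at$res_seq,
             rmsf = sqrt(msf), b_pred = B_FROM_RMSF * msf)
}

#' Per-frame RMSD and radius-of-gyration series
#'
#' RMSD of each frame to a reference frame after optimal superposition, and
#' the (unit-weight) radius of gyration of the selection, per frame.
#'
#' @param ensemble conformer_ensemble.
#' @param selection atom selection, default C-alpha.
#' @param reference reference frame index, default 1.
#' @return data.frame with `frame`, `rmsd`, `rg` (Angstrom).
#' @export
ensemble_series <- function(ensemble, selection = "CA", reference = 1L) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  idx <- resolve_selection(ensemble$topology, selection)
  if (!length(idx)) stop("empty atom selection")
  ref <- ensemble$frames[reference, idx, , drop = TRUE]
  m <- n_frames(ensemble)
  rmsd <- numeric(m); rg <- numeric(m)
  for (k in seq_len(m)) {
    x <- ensemble$frames[k, idx, , drop = TRUE]
    rmsd[k] <- kabsch_superpose(x, ref)$rmsd
    rg[k] <- radius_of_gyration(x)
  }
  data.frame(frame = seq_len(m), rmsd = rmsd, rg = rg)
}

# pairwise superposed-RMSD matrix over a selection
pairwise_rmsd <- function(ensemble, selection = "CA") {
  idx <- resolve_selection(ensemble$topology, selection)
  m <- n_frames(ensemble)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) {
    xi <- ensemble$frames[i, idx, , drop = TRUE]
    j <- i + 1L
    while (j <= m) {
      D[i, j] <- D[j, i] <-
        kabsch_superpose(ensemble$frames[j, idx, , drop = TRUE], xi)$rmsd
      j <- j + 1L
    }
  }
  D
}

#' Gromos clustering of an ensemble
#'
#' Iterative neighbour-count clustering on the pairwise superposed-RMSD
#' matrix: the frame with the most neighbours within `cutoff` becomes a
#' cluster center, it and its neighbours are assigned and removed, and the
#' procedure repeats until no frames remain. Ties on neighbour count are
#' broken toward the lowest frame index. Note that trajectory-analysis
#' suites conventionally state this cutoff in nm; here it is Angstrom and
#' always explicit.
#'
#' @param ensemble conformer_ensemble.
#' @param cutoff neighbour cutoff in Angstrom, > 0 (no default: the value is
#'   study-specific and unit confusion is common).
#' @param selection atom selection, default C-alpha.
#' @return list with `cutoff`, `assignments` (frame -> cluster id, discovery
#'   order), `centers` (frame index per cluster) and `sizes`.
#' @export
gromos_cluster <- function(ensemble, cutoff, selection = "CA") {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (missing(cutoff) || !is.numeric(cutoff) || cutoff <= 0)
    stop("cutoff must be a positive RMSD in Angstrom")
  D <- pairwise_rmsd(ensemble, selection)
  m <- nrow(D)
  remaining <- rep(TRUE, m)
  assignments <- integer(m)
  centers <- integer(0)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    idx <- which(remaining)
    counts <- vapply(idx, function(i) sum(D[i, idx] <= cutoff), integer(1))
    center <- idx[which.max(counts)]       # first max = lowest frame index
    members <- idx[D[center, idx] <= cutoff]
    assignments[members] <- cl
    centers <- c(centers, center)
    remaining[members] <- FALSE
  }
  list(cutoff = cutoff, assignments = assignments, centers = centers,
       sizes = as.integer(table(factor(assignments, levels = seq_len(cl)))))
}

#' Dynamics cross-correlation matrix
#'
#' Normalized covariance of atomic displacement vectors about their
#' time-mean positions:
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#'   {\sqrt{\langle|\Delta r_i|^2\rangle \langle|\Delta r_j|^2\rangle}}}
#' after per-frame superposition onto the ensemble mean (two-pass). +1 means
#' fully correlated motion, -1 fully anti-correlated. Zero-variance atoms
#' get a zero row/column with unit diagonal and a warning.
#'
#' @param ensemble conformer_ensemble with >= 3 frames.
#' @param selection atom selection, default C-alpha.
#' @param superpose logical, default TRUE.
#' @return list with `res_ids`, `chain` and `matrix` (N x N in -1..1).
#' @export
dccm <- function(ensemble, selection = "CA", superpose = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (n_frames(ensemble) < 3L) stop("DCCM needs at least 3 frames")
  idx <- resolve_selection(ensemble$topology, selection)
  if (!length(idx)) stop("empty atom selection")
  arr <- ensemble$frames[, idx, , drop = FALSE]
  if (superpose) arr <- superpose_frames(arr, "mean")
  m <- dim(arr)[1]
  mu <- apply(arr, c(2, 3), mean)
  num <- matrix(0, dim(arr)[2], dim(arr)[2])
  for (d in 1:3) {
    Dd <- arr[, , d] - matrix(mu[, d], m, dim(arr)[2], byrow = TRUE)
    num <- num + crossprod(Dd)
  }
  num <- num / m
  v <- diag(num)
  zero <- v <= .Machine$double.eps
  if (any(zero))
    warning(sum(zero), " zero-variance atom(s) in DCCM; rows/columns set to 0")
  vs <- sqrt(ifelse(zero, 1, v))
  C <- num / outer(vs, vs)
  C[zero, ] <- 0
  C[, zero] <- 0
  diag(C) <- 1
  C[C > 1] <- 1; C[C < -1] <- -1
  at <- ensemble$topology$atoms[idx, ]
  list(res_ids = at$res_seq, chain = at$chain, matrix = C)
}

#' Region-vs-region correlation summary of a DCCM
#'
#' Summary statistics of the correlation block between two residue sets
#' (e.g. a mobile loop against the helix it is coupled to).
#'
#' @param dccm_result result of [dccm()].
#' @param region_1,region_2 residue-number vectors; must be present in
#'   `res_ids`.
#' @param chain_1,chain_2 optional chain restriction for each region.
#' @return list with `mean`, `min`, `max` and `n_pairs` over the block.
#' @export
region_cross_correlation <- function(dccm_result, region_1, region_2,
                                     chain_1 = NULL, chain_2 = NULL) {
  pick <- function(region, chain) {
    sel <- dccm_result$res_ids %in% region
    if (!is.null(chain)) sel <- sel & dccm_result$chain %in% chain
    if (!any(sel)) stop("region contains no residues present in the DCCM")
    if (!all(region %in% dccm_result$res_ids[if (is.null(chain)) TRUE else
      dccm_result$chain %in% chain]))
      stop("region names residues absent from the DCCM")
    which(sel)
  }
  i <- pick(region_1, chain_1)
  j <- pick(region_2, chain_2)
  block <- dccm_result$matrix[i, j, drop = FALSE]
  list(mean = mean(block), min = min(block), max = max(block),
       n_pairs = length(block))
}
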