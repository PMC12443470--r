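# Superposition and shape-similarity metrics.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid superposition of `mobile` onto `target` over a given
#' correspondence. Reflections are never allowed (biological chirality): the
#' rotation is a proper orthogonal matrix, det = +1.
#'
#' @param mobile,target N x 3 coordinate matrices in correspondence, N >= 3.
#' @param weights optional non-negative per-pair weights.
#' @return list with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom, over the correspondence) and `n_matched`. The transform maps
#'   mobile points as `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, target, weights = NULL) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3L, ncol(target) == 3L,
            nrow(mobile) == nrow(target))
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 correspondence pairs")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  ct <- colSums(target * w)
  A <- sweep(mobile, 2, cm)
  B <- sweep(target, 2, ct)
  # degeneracy: all points collinear (covariance rank < 2)
  if (sum(svd(A * sqrt(w))$d > 1e-9 * max(1, max(abs(A)))) < 2L)
    stop("degenerate (collinear) point configuration in superposition")
  H <- t(A * w) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  list(rotation = R,
       translation = as.numeric(ct - R %*% cm),
       rmsd = rmsd,
       n_matched = n)
}

#' Apply a superposition transform
#' @param xyz N x 3 matrix.
#' @param sup result of [kabsch_superpose()].
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(xyz, sup) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, `+`)
}

# mean nearest-neighbour distance within one bead set
mean_nn_dist <- function(xyz) {
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# NSD value for a fixed relative placement of b
nsd_fixed <- function(a, b, da, db) {
  cross <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  cross[cross < 0] <- 0
  term_a <- mean(apply(cross, 1, min)) / db^2
  term_b <- mean(apply(cross, 2, min)) / da^2
  sqrt((term_a + term_b) / 2)
}

rot_from_angles <- function(p) {
  # intrinsic z-y-x Euler composition; p in radians
  cz <- cos(p[1]); sz <- sin(p[1])
  cy <- cos(p[2]); sy <- sin(p[2])
  cx <- cos(p[3]); sx <- sin(p[3])
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Normalized spatial discrepancy between two bead sets
#'
#' Correspondence-free shape dissimilarity: the superposition-minimized,
#' nearest-neighbour-normalized discrepancy
#' \deqn{NSD = \min \sqrt{\tfrac12\left[\frac{1}{N_a d_b^2}\sum_i \min_j |a_i-b_j|^2
#'   + \frac{1}{N_b d_a^2}\sum_j \min_i |b_j-a_i|^2\right]}}
#' where \eqn{d_x} is the mean nearest-neighbour distance within set x and
#' the minimum runs over rigid placements of set b. Zero means identical
#' shapes. The minimization is deterministic: principal-axis alignments (the
#' four proper axis-sign combinations, applied in both mapping directions)
#' seed a Nelder-Mead refinement over the six rigid parameters.
#'
#' @param set_a,set_b bead coordinate matrices (N x 3), each with >= 2 beads.
#' @return unitless NSD >= 0.
#' @export
nsd <- function(set_a, set_b) {
  a <- as.matrix(set_a); b <- as.matrix(set_b)
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("NSD needs at least 2 beads in each set")
  da <- mean_nn_dist(a); db <- mean_nn_dist(b)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  ea <- eigen(crossprod(a0) / nrow(a0), symmetric = TRUE)$vectors
  eb <- eigen(crossprod(b0) / nrow(b0), symmetric = TRUE)$vectors
  if (det(ea) < 0) ea[, 3] <- -ea[, 3]
  if (det(eb) < 0) eb[, 3] <- -eb[, 3]
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  starts <- list()
  for (s in signs) {
    starts[[length(starts) + 1L]] <- ea %*% diag(s) %*% t(eb)
    starts[[length(starts) + 1L]] <- t(eb %*% diag(s) %*% t(ea))
  }
  make_obj <- function(R0) function(p) {
    Rp <- rot_from_angles(p[1:3]) %*% R0
    bt <- sweep(b0 %*% t(Rp), 2, p[4:6], `+`)
    nsd_fixed(a0, bt, da, db)
  }
  v0 <- vapply(starts, function(R0) make_obj(R0)(rep(0, 6)), numeric(1))
  best <- min(v0)
  if (best < 1e-8) return(best)   # exact rigid copy: nothing to refine
  # simplex-refine the two most promising axis alignments
  for (k in order(v0)[1:2]) {
    opt <- stats::optim(rep(0, 6), make_obj(starts[[k]]),
                        method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-10))
    if (opt$value < best) best <- opt$value
  }
  best
}

#' Alignment-quality Q-score
#'
#' Joint coverage/accuracy score of a structural alignment in the
#' SSM/superpose convention:
#' \deqn{Q = \frac{N_{align}^2}{(1 + (RMSD/r_0)^2)\, n_a n_b}}
#' Q = 1 for a full-length zero-RMSD match; Q = 0.5 for a full-length match
#' at RMSD = r0.
#'
#' @param n_align number of aligned residue pairs (>= 1).
#' @param rmsd RMSD over the aligned pairs, Angstrom.
#' @param n_a,n_b residue counts of the two structures (each >= n_align).
#' @param r0 distance scale in Angstrom, default 3.0.
#' @return Q in (0, 1].
#' @export
qscore <- function(n_align, rmsd, n_a, n_b, r0 = 3.0) {
  if (r0 <= 0) stop("r0 must be positive")
  stopifnot(n_align >= 1, n_a >= n_align, n_b >= n_align, rmsd >= 0)
  n_align^2 / ((1 + (rmsd / r0)^2) * n_a * n_b)
}

#' Chain A vs chain B asymmetry of a dimer
#'
#' Measures how far the two chains of a dimer depart from exact structural
#' equivalence: the normalized spatial discrepancy (NSD_AB) between the two
#' chains' C-alpha bead sets, and the alignment quality (Q_AB) of the
#' residue-number-matched C-alpha correspondence after optimal superposition.
#'
#' @param model structure_model containing both chains.
#' @param chain_a,chain_b chain identifiers, default `"A"`, `"B"`.
#' @param r0 Q-score distance scale, Angstrom.
#' @return list with `nsd_ab`, `q_ab`, `rmsd_matched`, `n_matched`.
#' @export
chain_asymmetry <- function(model, chain_a = "A", chain_b = "B", r0 = 3.0) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  ca_a <- at[at$chain == chain_a & at$atom_name == "CA", ]
  ca_b <- at[at$chain == chain_b & at$atom_name == "CA", ]
  if (!nrow(ca_a)) stop("chain '", chain_a, "' absent or has no CA atoms")
  if (!nrow(ca_b)) stop("chain '", chain_b, "' absent or has no CA atoms")
  common <- intersect(ca_a$res_seq, ca_b$res_seq)
  if (length(common) < 3L)
    stop("fewer than 3 residues in common between chains '", chain_a,
         "' and '", chain_b, "'")
  xa <- as.matrix(ca_a[match(common, ca_a$res_seq), c("x", "y", "z")])
  xb <- as.matrix(ca_b[match(common, ca_b$res_seq), c("x", "y", "z")])
  sup <- kabsch_superpose(xb, xa)
  q <- qscore(length(common), sup$rmsd, nrow(ca_a), nrow(ca_b), r0 = r0)
  list(nsd_ab = nsd(as.matrix(ca_a[, c("x", "y", "z")]),
                    as.matrix(ca_b[, c("x", "y", "z")])),
       q_ab = q,
       rmsd_matched = sup$rmsd,
       n_matched = length(common))
}
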