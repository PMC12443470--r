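# Geometric hinge descriptors: distance/angle/dihedral primitives and the
# fixed 13-variable panel of one dimer model.

vnorm <- function(v) sqrt(sum(v^2))

#' Planar angle at a vertex
#'
#' Angle p1-p2-p3 at vertex p2, in degrees, in the closed interval 0..180.
#'
#' @param p1,p2,p3 3-vectors, Angstrom.
#' @return angle in degrees.
#' @export
planar_angle <- function(p1, p2, p3) {
  u <- as.numeric(p1) - as.numeric(p2)
  v <- as.numeric(p3) - as.numeric(p2)
  if (vnorm(u) < 1e-12 || vnorm(v) < 1e-12)
    stop("degenerate angle: a flank point coincides with the vertex")
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Signed dihedral angle
#'
#' Dihedral p1-p2-p3-p4 in degrees in (-180, 180], IUPAC sign convention
#' (right-hand rule about the p2 -> p3 axis; the cis planar arrangement is 0,
#' trans is 180).
#'
#' @param p1,p2,p3,p4 3-vectors, Angstrom.
#' @return signed dihedral in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- as.numeric(p2) - as.numeric(p1)
  b2 <- as.numeric(p3) - as.numeric(p2)
  b3 <- as.numeric(p4) - as.numeric(p3)
  if (vnorm(b2) < 1e-12) stop("degenerate dihedral: central bond has zero length")
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stop("degenerate dihedral: flank point collinear with the central bond")
  m1 <- cr(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# locate exactly one atom by (chain, res_seq, atom_name)
locate_atom <- function(model, chain, res_seq, atom_name = "CA") {
  at <- model$atoms
  hit <- which(at$chain == chain & at$res_seq == res_seq &
                 at$atom_name == atom_name)
  if (length(hit) == 0L)
    stop("no atom '", atom_name, "' in chain ", chain, " residue ", res_seq)
  if (length(hit) > 1L)
    stop("ambiguous selection: chain ", chain, " residue ", res_seq,
         " atom '", atom_name, "'")
  as.numeric(at[hit, c("x", "y", "z")])
}

#' Distance between two named atoms
#'
#' Euclidean distance between two atoms addressed as
#' (chain, residue number, atom name) — e.g. a catalytic-tyrosine hydroxyl to
#' cofactor distance. Each selection must resolve to exactly one atom.
#'
#' @param model structure_model.
#' @param sel1,sel2 lists with elements `chain`, `res_seq`, and optionally
#'   `atom_name` (default `"CA"`).
#' @return distance in Angstrom.
#' @export
pair_distance <- function(model, sel1, sel2) {
  g <- function(s) locate_atom(model, s$chain, s$res_seq,
                               if (is.null(s$atom_name)) "CA" else s$atom_name)
  vnorm(g(sel1) - g(sel2))
}

#' Names of the 13 panel variables, in fixed declared order
#' @return character vector of length 13.
#' @export
descriptor_names <- function() {
  c("C_CA", "C_CB", "C_173A", "C_173B", "C_470A", "C_470B",
    "d_173A_173B", "d_470A_470B", "ang_CA_C_CB", "ang_173A_C_173B",
    "dih_173A_470A_470B_173B", "NSD_AB", "Q_AB")
}

#' The 13-variable geometric panel of one dimer model
#'
#' Computes the fixed descriptor panel that characterizes the hinge geometry
#' of a two-chain dimer: distances from the dimer center to each chain center
#' and to the two marker residues of each chain, the two inter-chain marker
#' distances, the chain-center and marker angles at the dimer center, the
#' inter-chain hinge dihedral marker1A-marker2A-marker2B-marker1B, and the
#' chain asymmetry pair (NSD_AB, Q_AB). Centers are geometric (unit-weight)
#' centers over all atoms of the dimer / chain; marker positions are C-alpha
#' atoms. The variable names use the default markers 173 and 470 regardless
#' of the marker arguments, so descriptor tables are always column-compatible.
#'
#' @param model structure_model with both chains.
#' @param chain_a,chain_b chain ids, default `"A"`, `"B"`.
#' @param marker1,marker2 marker residue numbers, defaults 173 and 470
#'   (helix-6 probe and hinge-axis residues).
#' @param model_label label stored with the record.
#' @param mass_weighted logical; if TRUE centers use a crude per-residue mass
#'   proxy (all atoms weight 1 remains the default, geometric centers).
#' @return one-row data.frame: `model_label` plus the 13 variables in the
#'   order of [descriptor_names()].
#' @export
descriptor_panel <- function(model, chain_a = "A", chain_b = "B",
                             marker1 = 173L, marker2 = 470L,
                             model_label = "model", mass_weighted = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  xa <- as.matrix(at[at$chain == chain_a, c("x", "y", "z")])
  xb <- as.matrix(at[at$chain == chain_b, c("x", "y", "z")])
  if (!nrow(xa)) stop("chain '", chain_a, "' absent from model")
  if (!nrow(xb)) stop("chain '", chain_b, "' absent from model")
  C  <- colMeans(rbind(xa, xb))
  CA <- colMeans(xa)
  CB <- colMeans(xb)
  m1a <- locate_atom(model, chain_a, marker1)
  m1b <- locate_atom(model, chain_b, marker1)
  m2a <- locate_atom(model, chain_a, marker2)
  m2b <- locate_atom(model, chain_b, marker2)
  asym <- chain_asymmetry(model, chain_a, chain_b)
  rec <- data.frame(
    model_label = model_label,
    C_CA = vnorm(CA - C),
    C_CB = vnorm(CB - C),
    C_173A = vnorm(m1a - C),
    C_173B = vnorm(m1b - C),
    C_470A = vnorm(m2a - C),
    C_470B = vnorm(m2b - C),
    d_173A_173B = vnorm(m1a - m1b),
    d_470A_470B = vnorm(m2a - m2b),
    ang_CA_C_CB = planar_angle(CA, C, CB),
    ang_173A_C_173B = planar_angle(m1a, C, m1b),
    dih_173A_470A_470B_173B = dihedral_angle(m1a, m2a, m2b, m1b),
    NSD_AB = asym$nsd_ab,
    Q_AB = asym$q_ab,
    stringsAsFactors = FALSE
  )
  rec
}

#' Descriptor panels for every frame of an ensemble
#'
#' @param ensemble conformer_ensemble.
#' @param frames frame indices to evaluate (default all).
#' @param label_prefix prefix for the per-frame model labels.
#' @inheritParams descriptor_panel
#' @return data.frame, one row per frame, columns as [descriptor_panel()].
#' @export
descriptor_table <- function(ensemble, chain_a = "A", chain_b = "B",
                             marker1 = 173L, marker2 = 470L,
                             frames = NULL, label_prefix = "frame") {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (is.null(frames)) frames <- seq_len(n_frames(ensemble))
  rows <- lapply(frames, function(k)
    descriptor_panel(ensemble_frame(ensemble, k), chain_a, chain_b,
                     marker1, marker2,
                     model_label = paste0(label_prefix, "_", k)))
  do.call(rbind, rows)
}
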