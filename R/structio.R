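# ---- constructors -----------------------------------------------------------

#' Build a structure model from an atom table
#'
#' A `structure_model` is the unit of single-structure analysis: a flat atom
#' table with chain identity, author residue numbering, coordinates in
#' Angstrom, B-factors and occupancies.
#'
#' @param atoms data.frame with columns `chain`, `res_seq`, `res_name`,
#'   `atom_name`, `x`, `y`, `z`, `b`, `occ`.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "res_seq", "res_name", "atom_name", "x", "y", "z", "b", "occ")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  if (nrow(atoms) == 0L) stop("structure model must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(atoms$b < 0, na.rm = TRUE)) stop("negative B-factor in atom table")
  key <- paste(atoms$chain, atoms$res_seq, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, res_seq, atom_name) in atom table: ", key[anyDuplicated(key)])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat("structure_model:", nrow(x$atoms), "atoms;",
      length(ch), "chain(s):",
      paste(sprintf("%s=%d", names(ch), as.integer(ch)), collapse = " "), "\n")
  invisible(x)
}

#' Coordinate matrix of a structure model
#'
#' @param model structure_model.
#' @return N x 3 numeric matrix (Angstrom).
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Build a conformer ensemble
#'
#' A `conformer_ensemble` couples one shared topology (the atom identity list
#' of a [structure_model]) with M coordinate frames, the unit of
#' trajectory-derived analysis.
#'
#' @param topology structure_model providing atom identities (its coordinates
#'   are ignored).
#' @param frames numeric array M x N x 3, or a list of N x 3 matrices.
#' @param frame_labels integer labels, default `seq_len(M)`.
#' @return object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(topology, frames, frame_labels = NULL) {
  stopifnot(inherits(topology, "structure_model"))
  if (is.list(frames)) {
    m <- length(frames)
    n <- nrow(frames[[1L]])
    arr <- array(NA_real_, c(m, n, 3L))
    for (k in seq_len(m)) arr[k, , ] <- as.matrix(frames[[k]])
    frames <- arr
  }
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] == 3L)
  if (dim(frames)[2] != nrow(topology$atoms))
    stop("frame atom count (", dim(frames)[2], ") does not match topology (",
         nrow(topology$atoms), ")")
  if (dim(frames)[1] < 1L) stop("ensemble must contain at least one frame")
  if (!all(is.finite(frames))) stop("non-finite coordinates in frames")
  if (is.null(frame_labels)) frame_labels <- seq_len(dim(frames)[1])
  structure(list(topology = topology, frames = frames,
                 frame_labels = as.integer(frame_labels)),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("conformer_ensemble:", dim(x$frames)[1], "frames x",
      dim(x$frames)[2], "atoms\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble conformer_ensemble.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$frames)[1]

#' Extract one frame of an ensemble as a structure model
#' @param ensemble conformer_ensemble.
#' @param k frame index (1-based).
#' @return structure_model with the topology's identities and frame k's
#'   coordinates.
#' @export
ensemble_frame <- function(ensemble, k) {
  stopifnot(inherits(ensemble, "conformer_ensemble"),
            k >= 1, k <= n_frames(ensemble))
  at <- ensemble$topology$atoms
  at$x <- ensemble$frames[k, , 1]
  at$y <- ensemble$frames[k, , 2]
  at$z <- ensemble$frames[k, , 3]
  structure_model(at)
}

#' Build a scattering curve
#'
#' @param q momentum transfer, 1/Angstrom, strictly increasing. A leading
#'   q = 0 point is allowed on computed curves.
#' @param intensity scattered intensity, arbitrary units.
#' @param sigma optional per-point uncertainty, same units as `intensity`.
#' @return object of class `saxs_curve` (a data.frame with columns `q`, `I`
#'   and optionally `sigma`).
#' @export
saxs_curve <- function(q, intensity, sigma = NULL) {
  stopifnot(length(q) == length(intensity))
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(q < 0)) stop("q must be non-negative")
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q))
    if (any(sigma <= 0)) stop("sigma must be positive where present")
  }
  out <- data.frame(q = as.numeric(q), I = as.numeric(intensity))
  if (!is.null(sigma)) out$sigma <- as.numeric(sigma)
  class(out) <- c("saxs_curve", "data.frame")
  out
}

# ---- PDB fixed-column parsing ----------------------------------------------

pdb_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    return(readLines(source, warn = FALSE))
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

fx <- function(lines, from, to) substr(lines, from, to)

num_or_stop <- function(txt, lineno, what) {
  v <- suppressWarnings(as.numeric(txt))
  bad <- which(is.na(v) & !grepl("^\\s*$", txt))
  if (length(bad))
    stop("non-numeric ", what, " field in PDB line ", lineno[bad[1L]],
         ": '", txt[bad[1L]], "'")
  v
}

parse_atom_block <- function(lines, lineno) {
  rec <- fx(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) stop("no parseable ATOM/HETATM records in PDB input")
  icode <- trimws(fx(lines, 27, 27))
  if (any(icode != ""))
    stop("insertion codes are not supported (PDB line ",
         lineno[which(icode != "")[1L]], ")")
  occ <- suppressWarnings(as.numeric(fx(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(fx(lines, 61, 66)))
  b[is.na(b)] <- 0
  at <- data.frame(
    chain     = fx(lines, 22, 22),
    res_seq   = as.integer(num_or_stop(fx(lines, 23, 26), lineno, "residue number")),
    res_name  = trimws(fx(lines, 18, 20)),
    atom_name = trimws(fx(lines, 13, 16)),
    altloc    = trimws(fx(lines, 17, 17)),
    x = num_or_stop(fx(lines, 31, 38), lineno, "coordinate"),
    y = num_or_stop(fx(lines, 39, 46), lineno, "coordinate"),
    z = num_or_stop(fx(lines, 47, 54), lineno, "coordinate"),
    b = b, occ = occ,
    stringsAsFactors = FALSE
  )
  # altloc: keep highest occupancy; ties prefer altloc 'A' (then alphabetical)
  if (any(at$altloc != "")) {
    key <- paste(at$chain, at$res_seq, at$atom_name)
    ord <- order(key, -at$occ, at$altloc)
    at <- at[ord, ]
    at <- at[!duplicated(paste(at$chain, at$res_seq, at$atom_name)), ]
    at <- at[order(as.integer(rownames(at))), ]
  }
  at$altloc <- NULL
  rownames(at) <- NULL
  at
}

parse_remark465 <- function(lines) {
  r <- lines[fx(lines, 1, 10) == "REMARK 465"]
  if (!length(r)) return(NULL)
  # data rows: "REMARK 465     RES C SSSEQI"
  res <- trimws(substr(r, 16, 18))
  ch <- trimws(substr(r, 20, 20))
  num <- suppressWarnings(as.integer(substr(r, 22, 26)))
  ok <- !is.na(num) & ch != ""
  if (!any(ok)) return(NULL)
  data.frame(chain = ch[ok], res_seq = num[ok], res_name = res[ok])
}

#' Read a single structure from PDB text
#'
#' Parses ATOM/HETATM records with fixed-column PDB semantics. If the input
#' contains multiple MODEL blocks only the first is kept (use
#' [read_ensemble()] for trajectories). Alternate locations are reduced to the
#' highest-occupancy conformer (ties broken toward altloc 'A'); insertion
#' codes are rejected.
#'
#' @param source path to a PDB file, or PDB text (single string or character
#'   vector of lines).
#' @return [structure_model()]. If the file carries REMARK 465 records the
#'   missing residues are attached as attribute `"remark465"`.
#' @export
read_structure <- function(source) {
  lines <- pdb_lines(source)
  lineno <- seq_along(lines)
  rem465 <- parse_remark465(lines)
  # restrict to first MODEL block if present
  mstart <- which(fx(lines, 1, 6) == "MODEL ")
  if (length(mstart)) {
    mend <- which(fx(lines, 1, 6) == "ENDMDL")
    end1 <- if (length(mend)) mend[1L] else length(lines)
    sel <- seq(mstart[1L], end1)
    lines <- lines[sel]; lineno <- lineno[sel]
  }
  model <- structure_model(parse_atom_block(lines, lineno))
  if (!is.null(rem465)) attr(model, "remark465") <- rem465
  model
}

#' Read a multi-model PDB as a conformer ensemble
#'
#' MODEL/ENDMDL blocks must share an identical atom identity sequence; a file
#' without MODEL records is read as a single-frame ensemble.
#'
#' @param source path or PDB text as in [read_structure()].
#' @return [conformer_ensemble()]; `frame_labels` are the MODEL serial
#'   numbers when present.
#' @export
read_ensemble <- function(source) {
  lines <- pdb_lines(source)
  lineno <- seq_along(lines)
  rec <- fx(lines, 1, 6)
  mstart <- which(rec == "MODEL ")
  if (!length(mstart)) {
    model <- read_structure(lines)
    return(conformer_ensemble(model, array(coords(model), c(1L, nrow(model$atoms), 3L))))
  }
  mend <- which(rec == "ENDMDL")
  if (length(mend) < length(mstart)) mend <- c(mend, length(lines))
  labels <- suppressWarnings(as.integer(substr(lines[mstart], 11, 14)))
  labels[is.na(labels)] <- seq_along(mstart)[is.na(labels)]
  blocks <- lapply(seq_along(mstart), function(k) {
    sel <- seq(mstart[k], mend[k])
    parse_atom_block(lines[sel], lineno[sel])
  })
  ident <- lapply(blocks, function(b) paste(b$chain, b$res_seq, b$atom_name))
  for (k in seq_along(blocks)[-1L]) {
    if (!identical(ident[[k]], ident[[1L]]))
      stop("model ", labels[k], " atom identities differ from model ",
           labels[1L], " (", length(ident[[k]]), " vs ", length(ident[[1L]]),
           " atoms)")
  }
  topo <- structure_model(blocks[[1L]])
  arr <- array(NA_real_, c(length(blocks), nrow(topo$atoms), 3L))
  for (k in seq_along(blocks))
    arr[k, , ] <- as.matrix(blocks[[k]][, c("x", "y", "z")])
  conformer_ensemble(topo, arr, labels)
}

# ---- PDB writing ------------------------------------------------------------

format_atom_lines <- function(at) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          seq_len(nrow(at)) %% 100000L,
          ifelse(nchar(at$atom_name) < 4L, paste0(" ", at$atom_name), at$atom_name),
          at$res_name, at$chain, at$res_seq,
          at$x, at$y, at$z, at$occ, at$b)
}

#' Write a structure model as PDB text
#' @param model structure_model.
#' @param path output file; if `NULL` the lines are returned invisibly.
#' @return invisibly, the character vector of PDB lines.
#' @export
write_structure <- function(model, path = NULL) {
  stopifnot(inherits(model, "structure_model"))
  lines <- c(format_atom_lines(model$atoms), "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write a conformer ensemble as multi-model PDB text
#' @param ensemble conformer_ensemble.
#' @param path output file; if `NULL` the lines are returned invisibly.
#' @return invisibly, the character vector of PDB lines.
#' @export
write_ensemble <- function(ensemble, path = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  out <- unlist(lapply(seq_len(n_frames(ensemble)), function(k) {
    fr <- ensemble_frame(ensemble, k)
    c(sprintf("MODEL     %4d", ensemble$frame_labels[k]),
      format_atom_lines(fr$atoms), "ENDMDL")
  }), use.names = FALSE)
  lines <- c(out, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# ---- SAXS curve I/O ---------------------------------------------------------

#' Read an experimental SAXS curve from 2/3-column text
#'
#' Rows are whitespace-separated `q I [sigma]` triples; lines starting with
#' `#` (and blank lines) are skipped. Experimental curves must have strictly
#' increasing q > 0.
#'
#' @param source path or text.
#' @param q_unit `"inverse-A"` (default) or `"inverse-nm"`; inverse-nm input
#'   is converted to 1/Angstrom (divided by 10).
#' @return [saxs_curve()].
#' @export
read_saxs_curve <- function(source, q_unit = c("inverse-A", "inverse-nm")) {
  q_unit <- match.arg(q_unit)
  lines <- pdb_lines(source)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop("SAXS curve needs at least 2 data rows")
  rows <- strsplit(trimws(lines), "\\s+")
  ncol <- unique(lengths(rows))
  if (length(ncol) != 1L || !(ncol %in% c(2L, 3L)))
    stop("SAXS curve rows must have uniformly 2 or 3 numeric columns")
  vals <- suppressWarnings(matrix(as.numeric(unlist(rows)), ncol = ncol, byrow = TRUE))
  if (any(is.na(vals))) stop("non-numeric value in SAXS curve data")
  q <- vals[, 1]
  if (q_unit == "inverse-nm") q <- q / 10
  if (any(q <= 0)) stop("experimental q values must be strictly positive")
  if (any(diff(q) <= 0)) stop("q values must be strictly increasing")
  sg <- if (ncol == 3L) vals[, 3] else NULL
  if (!is.null(sg) && any(sg < 0)) stop("negative sigma in SAXS curve")
  if (!is.null(sg) && any(sg == 0)) stop("sigma must be positive where present")
  saxs_curve(q, vals[, 2], sg)
}

#' Write a scattering curve as 3-column text
#' @param curve saxs_curve.
#' @param path output file.
#' @param header logical, write a `#` comment header.
#' @return invisibly, the path.
#' @export
write_saxs_curve <- function(curve, path, header = TRUE) {
  stopifnot(inherits(curve, "saxs_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("# q(1/A)  I  sigma", con)
  if (is.null(curve$sigma)) {
    writeLines(sprintf("%.6g %.8g", curve$q, curve$I), con)
  } else {
    writeLines(sprintf("%.6g %.8g %.8g", curve$q, curve$I, curve$sigma), con)
  }
  invisible(path)
}

# ---- missing-residue (gap) detection ---------------------------------------

#' Detect unmodeled residue stretches
#'
#' Compares the residues present in a model against an expected per-chain
#' range and reports every maximal contiguous run of missing residue numbers,
#' the way missing electron-density stretches are counted in crystal
#' structures (gap length is the inclusive count `end - start + 1`).
#'
#' @param model structure_model.
#' @param expected named list mapping chain id to an integer vector of
#'   expected residue numbers (e.g. `list(A = 1:480)`). If `NULL`, REMARK 465
#'   records attached by [read_structure()] are used directly.
#' @return data.frame of class `gap_report` with columns `chain`, `start`,
#'   `end`, `length`, sorted by chain then start.
#' @export
detect_missing_residues <- function(model, expected = NULL) {
  stopifnot(inherits(model, "structure_model"))
  runs_of <- function(v) {
    v <- sort(unique(v))
    if (!length(v)) return(NULL)
    brk <- c(0L, which(diff(v) > 1L), length(v))
    data.frame(start = v[brk[-length(brk)] + 1L], end = v[brk[-1L]])
  }
  gaps <- list()
  if (is.null(expected)) {
    rem <- attr(model, "remark465")
    if (is.null(rem))
      stop("no expected residue ranges supplied and no REMARK 465 records present")
    for (ch in unique(rem$chain)) {
      r <- runs_of(rem$res_seq[rem$chain == ch])
      if (!is.null(r)) gaps[[ch]] <- cbind(chain = ch, r)
    }
  } else {
    if (!length(expected) || any(!lengths(expected)))
      stop("expected residue ranges must be non-empty")
    for (ch in names(expected)) {
      have <- unique(model$atoms$res_seq[model$atoms$chain == ch])
      miss <- setdiff(as.integer(expected[[ch]]), have)
      r <- runs_of(miss)
      if (!is.null(r)) gaps[[ch]] <- cbind(chain = ch, r)
    }
  }
  out <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(chain = character(), start = integer(), end = integer())
  out$length <- out$end - out$start + 1L
  out <- out[order(out$chain, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gap_report", "data.frame")
  out
}
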