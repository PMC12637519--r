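# Backbone representation, internal <-> Cartesian conversion, superposition,
# hinge rotations and clash detection.  Coordinates are in Angstrom, angles
# in degrees, stored in (-180, 180].

# atom-name <-> integer type codes shared with the C++ kernels
.ATYPE <- c(N = 0L, CA = 1L, C = 2L, O = 3L, CB = 4L, SG = 5L)

.atype_of <- function(name) {
  a <- unname(.ATYPE[name])
  a[is.na(a)] <- 6L
  a
}

#' Ideal backbone geometry constants
#'
#' The fixed bond lengths (Angstrom) and angles (degrees) used to build
#' peptide backbones in internal coordinates.  These are standard
#' stereochemical target values; they are centralized here so that every
#' chain built by the package shares exactly one geometry.
#'
#' @return a named list with elements `bonds` and `angles`.
#' @export
backbone_geometry <- function() {
  list(
    bonds = c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231,
              CA_CB = 1.521),
    angles = c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7,
               CA_C_O = 120.8, C_CA_CB = 110.1)
  )
}

#' Wrap angles into (-180, 180] degrees
#' @param x numeric vector of angles in degrees.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w <= -180] <- w[w <= -180] + 360
  ifelse(abs(w + 180) < 1e-12, 180, w)
}

#' Smallest circular difference between two angles (degrees)
#' @param a,b numeric vectors of angles in degrees.
#' @return absolute circular differences.
#' @export
angle_diff <- function(a, b) {
  d <- abs(wrap_angle(a - b))
  pmin(d, 360 - d)
}

# ---------------------------------------------------------------------------
# chain conformation container

.new_conf <- function(xyz, name, chain, resno, grp, pseudo, seq, seq_resno,
                      segment_id, idr_chain, anchor = "start",
                      attachments = list()) {
  structure(list(
    xyz = xyz, name = name, chain = chain, resno = as.integer(resno),
    grp = as.integer(grp), pseudo = as.integer(pseudo),
    atype = .atype_of(name),
    seq = seq, seq_resno = as.integer(seq_resno),
    segment_id = segment_id, idr_chain = idr_chain, anchor = anchor,
    attachments = attachments
  ), class = "chain_conf")
}

#' @export
print.chain_conf <- function(x, ...) {
  cat(sprintf("<chain_conf> %s: chain %s residues %d-%d, %d atoms, %d attachment(s)\n",
              x$segment_id, x$idr_chain, min(x$seq_resno), max(x$seq_resno),
              nrow(x$xyz), length(x$attachments)))
  invisible(x)
}

.conf_rows <- function(conf, chain = NULL, resno = NULL, name = NULL,
                       grp = NULL) {
  keep <- rep(TRUE, nrow(conf$xyz))
  if (!is.null(chain)) keep <- keep & conf$chain %in% chain
  if (!is.null(resno)) keep <- keep & conf$resno %in% resno
  if (!is.null(name)) keep <- keep & conf$name %in% name
  if (!is.null(grp)) keep <- keep & conf$grp %in% grp
  which(keep)
}

# backbone triad (N, CA, C) coordinates of one residue
.triad <- function(obj, chain, resno) {
  rows <- vapply(c("N", "CA", "C"), function(nm) {
    r <- which(obj$chain == chain & obj$resno == resno & obj$name == nm)
    if (length(r) != 1L)
      stop(sprintf("residue %s/%d lacks a unique %s atom", chain, resno, nm))
    r[1]
  }, integer(1))
  obj$xyz[rows, , drop = FALSE]
}

#' Build a backbone chain from a sequence and dihedral angles
#'
#' Places N, CA, C, O (and CB for non-glycine residues) atoms with ideal
#' bond geometry (see [backbone_geometry()]) from per-residue phi/psi/omega
#' dihedrals.  The phi of the first residue and the omega of the first
#' peptide bond are undefined and ignored; the psi of the last residue only
#' orients its carbonyl oxygen.
#'
#' @param sequence one-letter amino-acid string.
#' @param dihedrals numeric matrix with one row per residue and columns
#'   phi, psi and optionally omega (degrees, in (-180, 180]); omega
#'   defaults to 180 (trans).
#' @param start_frame optional 3x3 matrix with rows N, CA, C giving the
#'   placement of the first residue; defaults to a canonical frame at the
#'   origin.
#' @param chain_id,resno_start,segment_id chain identifier, author residue
#'   number of the first residue, and segment label.
#' @return a `chain_conf` object.
#' @export
build_chain <- function(sequence, dihedrals, start_frame = NULL,
                        chain_id = "A", resno_start = 1L,
                        segment_id = "segment") {
  seq <- strsplit(sequence, "")[[1]]
  n <- length(seq)
  dihedrals <- as.matrix(dihedrals)
  if (nrow(dihedrals) != n)
    stop("dihedrals must have one row per residue")
  if (ncol(dihedrals) == 2L) dihedrals <- cbind(dihedrals, 180)
  if (any(!is.finite(dihedrals)))
    stop("non-finite dihedral angles")
  if (any(dihedrals <= -180 | dihedrals > 180))
    stop("dihedral angles must lie in (-180, 180]")
  if (is.null(start_frame)) start_frame <- matrix(0, 0, 3)
  res <- cpp_build_chain(dihedrals[, 1], dihedrals[, 2], dihedrals[, 3],
                         seq != "G", start_frame)
  resno <- resno_start - 1L + res$ridx
  nm <- c("N", "CA", "C", "O", "CB")[res$atype + 1L]
  .new_conf(res$xyz, nm, rep(chain_id, length(nm)), resno,
            grp = rep(0L, length(nm)), pseudo = resno,
            seq = seq, seq_resno = resno_start:(resno_start + n - 1L),
            segment_id = segment_id, idr_chain = chain_id)
}

#' Measure backbone dihedral angles of a chain
#'
#' The inverse of [build_chain()] up to the angles that are undefined at
#' the termini (reported as `NA`).  A broken chain (C-N distance above
#' `max_gap`) raises a discontinuity error.
#'
#' @param chain a `chain_conf`.
#' @param max_gap maximum tolerated C-N peptide-bond distance in Angstrom.
#' @return a matrix with columns phi, psi, omega (degrees, `NA` where
#'   undefined).
#' @export
measure_dihedrals <- function(chain, max_gap = 2.0) {
  resnos <- chain$seq_resno[chain$seq_resno %in%
                              chain$resno[chain$grp == 0L &
                                            chain$chain == chain$idr_chain]]
  if (length(resnos) < 2L)
    stop("need at least 2 residues to measure dihedrals")
  tri <- lapply(c("N", "CA", "C"), function(nm) {
    rows <- vapply(resnos, function(r) {
      i <- which(chain$chain == chain$idr_chain & chain$resno == r &
                   chain$name == nm & chain$grp == 0L)
      if (length(i) != 1L) stop(sprintf("residue %d lacks atom %s", r, nm))
      i
    }, integer(1))
    chain$xyz[rows, , drop = FALSE]
  })
  m <- cpp_measure_dihedrals(tri[[1]], tri[[2]], tri[[3]], max_gap)
  out <- cbind(phi = m$phi, psi = m$psi, omega = m$omega)
  rownames(out) <- resnos
  out
}

# ---------------------------------------------------------------------------
# rigid transforms and superposition

#' Create a rigid transform
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation length-3 numeric vector (Angstrom).
#' @return a `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates or an object
#' @param x an n x 3 matrix, `chain_conf` or `rigid_body`.
#' @param transform a `rigid_transform`.
#' @return the transformed object.
#' @export
apply_transform <- function(x, transform) {
  if (is.matrix(x))
    return(x %*% t(transform$rotation) +
             matrix(transform$translation, nrow(x), 3, byrow = TRUE))
  x$xyz <- apply_transform(x$xyz, transform)
  x
}

#' Least-squares superposition (Kabsch)
#'
#' Finds the rigid transform minimizing the RMSD between paired points.
#'
#' @param mobile,reference n x 3 coordinate matrices with paired rows
#'   (n >= 3, not collinear).
#' @return list with `transform` (mapping mobile onto reference) and
#'   `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, reference) {
  P <- as.matrix(mobile)
  Q <- as.matrix(reference)
  if (nrow(P) != nrow(Q)) stop("point sets must be paired")
  if (nrow(P) < 3L) stop("need at least 3 paired points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  # collinear points leave the rotation about the common axis undetermined
  if (s$d[2] < max(s$d[1], 1) * 1e-9 && nrow(P) > 0) {
    sp <- svd(Pc)
    if (sp$d[2] < max(sp$d[1], 1) * 1e-8)
      stop("collinear points: rotation is underdetermined")
  }
  d <- sign(det(tcrossprod(s$v, s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  moved <- P %*% t(R) + matrix(t, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(transform = rigid_transform(R, t), rmsd = rmsd)
}

# exact transform between congruent backbone triads (origin at CA)
.triad_transform <- function(from, to) {
  frame <- function(m) {
    e1 <- m[3, ] - m[2, ]; e1 <- e1 / sqrt(sum(e1^2))
    v <- m[1, ] - m[2, ]
    e2 <- v - sum(v * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
    cbind(e1, e2, pracma_cross(e1, e2))
  }
  A <- frame(from); B <- frame(to)
  R <- B %*% t(A)
  rigid_transform(R, to[2, ] - as.numeric(R %*% from[2, ]))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---------------------------------------------------------------------------
# hinge rotations

# rows moved by rotating the phi or psi dihedral of `resno`, honouring the
# anchored end of the kinematic chain (atoms on the anchored side stay put)
.movable_rows <- function(conf, resno, kind) {
  own <- conf$chain == conf$idr_chain & conf$grp == 0L & conf$resno == resno
  pr <- conf$pseudo
  at <- conf$atype
  if (!identical(conf$anchor, "end")) {
    if (kind == "phi")
      mv <- pr > resno | (own & at %in% c(.ATYPE[["C"]], .ATYPE[["O"]],
                                          .ATYPE[["CB"]]))
    else
      mv <- pr > resno | (own & at == .ATYPE[["O"]])
  } else {
    if (kind == "phi")
      mv <- pr < resno
    else
      mv <- pr < resno | (own & at %in% c(.ATYPE[["N"]], .ATYPE[["CB"]]))
  }
  mv[own & at %in% c(.ATYPE[["N"]], .ATYPE[["CA"]]) & kind == "phi"] <- FALSE
  mv[own & at %in% c(.ATYPE[["CA"]], .ATYPE[["C"]]) & kind == "psi"] <- FALSE
  which(mv)
}

#' Rotate a backbone dihedral of a chain
#'
#' Rotates all atoms on the free side of the chosen hinge (including
#' attached rigid bodies) about the N-CA (phi) or CA-C (psi) axis.  Bond
#' lengths and angles are preserved exactly; atoms on the anchored side do
#' not move.
#'
#' @param chain a `chain_conf`.
#' @param resno author residue number of the hinge residue.
#' @param kind `"phi"` or `"psi"`.
#' @param delta rotation in degrees.
#' @return the rotated `chain_conf`.
#' @export
rotate_dihedral <- function(chain, resno, kind = c("phi", "psi"), delta) {
  kind <- match.arg(kind)
  if (!resno %in% chain$resno[chain$chain == chain$idr_chain & chain$grp == 0L])
    stop(sprintf("residue %d is not part of the flexible chain", resno))
  first <- min(chain$seq_resno)
  if (kind == "phi" && resno == first && !identical(chain$anchor, "end"))
    stop("phi is undefined for the first residue")
  tri <- .triad(chain, chain$idr_chain, resno)
  rows <- .movable_rows(chain, resno, kind)
  if (length(rows) == 0L || delta == 0) return(chain)
  if (kind == "phi") { p0 <- tri[1, ]; p1 <- tri[2, ] }
  else { p0 <- tri[2, ]; p1 <- tri[3, ] }
  chain$xyz <- cpp_rotate_rows(chain$xyz, rows, p0, p1 - p0, delta)
  chain
}

# ---------------------------------------------------------------------------
# clash detection

#' Clash model
#'
#' Heavy-atom steric model used during sampling and CCD: a pair of atoms
#' clashes when closer than `cutoff`, unless excluded.  Exclusions are
#' intra-rigid-body pairs and near-bonded neighbours, approximated as
#' same-chain residues at most two apart; the two-residue margin also
#' covers the covalent 1-3 pairs running through a grafted junction
#' residue.
#'
#' @param cutoff heavy-atom clash distance in Angstrom (default 2.5,
#'   a permissive backbone-level value suited to coarse ensembles).
#' @param cell spatial-hash cell size, at least `cutoff`.
#' @return a `clash_model`.
#' @export
clash_model <- function(cutoff = 2.5, cell = NULL) {
  if (is.null(cell)) cell <- cutoff
  if (cell < cutoff) stop("cell size must be >= cutoff")
  structure(list(cutoff = cutoff, cell = cell), class = "clash_model")
}

.meta_of <- function(x, chain_codes = NULL) {
  if (is.matrix(x))
    return(list(xyz = x, chain = rep("X", nrow(x)),
                resno = seq_len(nrow(x)) * 10L, grp = rep(0L, nrow(x))))
  list(xyz = x$xyz, chain = x$chain, resno = x$resno,
       grp = if (is.null(x$grp)) rep(1L, nrow(x$xyz)) else x$grp)
}

#' List clashing atom pairs
#'
#' @param x a `chain_conf`, `rigid_body` or bare n x 3 matrix (bare
#'   matrices are treated as independent atoms with no exclusions).
#' @param model a [clash_model()].
#' @param use_grid use the spatial hash (`TRUE`) or the all-pairs scan.
#' @return integer matrix of clashing row pairs (zero rows when clash-free).
#' @export
clash_check <- function(x, model = clash_model(), use_grid = TRUE) {
  m <- .meta_of(x)
  ch <- as.integer(factor(m$chain))
  p <- cpp_clash_pairs(m$xyz, ch, m$resno, m$grp, model$cutoff, use_grid)
  colnames(p) <- c("i", "j")
  p
}

# any clash between two atom sets (shared chain-code space)
.clash_between <- function(a, b, cutoff) {
  ma <- .meta_of(a); mb <- .meta_of(b)
  lev <- unique(c(ma$chain, mb$chain))
  cpp_clash_any_between(ma$xyz, match(ma$chain, lev), ma$resno, ma$grp,
                        mb$xyz, match(mb$chain, lev), mb$resno, mb$grp,
                        cutoff)
}

# ---------------------------------------------------------------------------
# membrane plane

#' Membrane headgroup plane
#'
#' The coordinate frame places the membrane normal along +z; the allowed
#' half-space is z > z0.
#'
#' @param z0 headgroup height in Angstrom (default 0).
#' @return a `membrane_plane`.
#' @export
membrane_plane <- function(z0 = 0) {
  structure(list(z0 = z0), class = "membrane_plane")
}

#' Signed height of atoms above the membrane plane
#' @param atom coordinate vector, n x 3 matrix, or object with `$xyz`.
#' @param plane a [membrane_plane()].
#' @return signed z - z0 in Angstrom (positive inside the allowed
#'   half-space).
#' @export
height_above_plane <- function(atom, plane) {
  if (is.list(atom) && !is.null(atom$xyz)) atom <- atom$xyz
  if (is.matrix(atom)) atom[, 3] - plane$z0 else atom[3] - plane$z0
}
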