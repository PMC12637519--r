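# Synthetic fixtures: idealized rigid bodies with tagged anchors, toy CCD
# closure problems with brute-force solutions, and IDR sequences.  All
# fixtures are deterministic given their parameters, and all stand in for
# predicted structural models that the pipeline would otherwise consume as
# input files; they reproduce anchor placement and tether lengths, not
# fold details.

.helix_dihedrals <- function(n) cbind(rep(-63, n), rep(-43, n))
.strand_dihedrals <- function(n) cbind(rep(-135, n), rep(135, n))

# build a short chain and recentre it at `center`
.piece <- function(seq, dihedrals, chain_id, resno_start, center) {
  conf <- build_chain(seq, dihedrals, chain_id = chain_id,
                      resno_start = resno_start, segment_id = "fixture")
  shift <- center - colMeans(conf$xyz)
  conf$xyz <- sweep(conf$xyz, 2, -shift)
  conf
}

# minimal rotation taking unit vector u onto unit vector v (Rodrigues)
.rot_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  ax <- pracma_cross(u, v)
  s <- sqrt(sum(ax^2)); c <- sum(u * v)
  if (s < 1e-12) {
    if (c > 0) return(diag(3))
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- pracma_cross(u, p); ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + K + K %*% K * ((1 - c) / s^2)
}

# rotate a piece about its centroid so that (point - centroid) maps onto
# `direction`, keeping the centroid fixed
.orient_piece <- function(conf, row, direction) {
  ctr <- colMeans(conf$xyz)
  R <- .rot_between(conf$xyz[row, ] - ctr, direction)
  conf$xyz <- sweep(sweep(conf$xyz, 2, ctr) %*% t(R), 2, ctr, "+")
  conf
}

# rotate a piece about its centroid so its principal axes map to x, y, z
# (longest extent along x, smallest along z)
.flatten_piece <- function(conf) {
  ctr <- colMeans(conf$xyz)
  Xc <- sweep(conf$xyz, 2, ctr)
  V <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  conf$xyz <- sweep(Xc %*% V, 2, ctr, "+")
  conf
}

.bind_parts <- function(parts, extra_xyz = NULL, extra_name = NULL,
                        extra_chain = NULL, extra_resno = NULL,
                        tags = integer(), body_id = "body") {
  xyz <- do.call(rbind, c(lapply(parts, `[[`, "xyz"), list(extra_xyz)))
  name <- c(unlist(lapply(parts, `[[`, "name")), extra_name)
  chain <- c(unlist(lapply(parts, `[[`, "chain")), extra_chain)
  resno <- c(unlist(lapply(parts, `[[`, "resno")), extra_resno)
  rigid_body(xyz, name, chain, resno, tags = tags, body_id = body_id)
}

#' Synthetic ULK1C-core rigid body
#'
#' A compact dummy body standing in for the folded ULK1C core (FIP200
#' scaffold dimer region, ULK1 EAT and the C-terminal ATG13 anchor): an
#' idealized helix bundle (chain F), an elongated CA-trace arm ending in
#' the tagged atom `FIP200_tip`, the ULK1 EAT stub (chain U, residues
#' 831-843, whose residue-831 backbone triad is the growth anchor of the
#' ULK1 IDR) carrying the two palmitoylatable cysteine sulfurs tagged
#' `C927:SG` and `C1003:SG`, and an ATG13 overlap stub at residues
#' 362-363 used to graft the body onto the sampled ATG13 IDR.  In the
#' body's local frame the three anchor atoms are near-coplanar at the
#' bottom face (z around 1 Angstrom) so that they can simultaneously
#' engage a flat membrane.
#'
#' @param arm_length number of CA atoms in the arm (default 15).
#' @param sg_offset xy half-separation of the two SG anchors (Angstrom).
#' @return a `rigid_body`.
#' @export
make_core_fixture <- function(arm_length = 20L, sg_offset = 4) {
  h1 <- .piece(strrep("A", 20), .helix_dihedrals(20), "F", 1L, c(10, -6, 10))
  h2 <- .piece(strrep("A", 20), .helix_dihedrals(20), "F", 31L, c(10, 6, 10))
  # EAT helix oriented so residue 831 (the ULK1-IDR tether point) sits on
  # top and the pre-831 chain exits upward: the EAT/MIT tandem is about
  # 25 A tall with its palmitoylatable cysteines on the membrane face and
  # the IDR leaving from the distal face
  eat <- .piece(strrep("A", 13), .helix_dihedrals(13), "U", 831L, c(-12, 0, 12))
  eat <- .orient_piece(eat, which(eat$resno == 831L & eat$name == "CA"),
                       c(0.2, 0.2, 1))
  # ATG13 overlap stub outboard of the bundle, oriented so the incoming
  # IDR (residues < 362) approaches from free space away from the body
  stub <- .piece("AA", .strand_dihedrals(2), "A", 362L, c(14, 20, 14))
  stub <- .orient_piece(stub, which(stub$resno == 363L & stub$name == "CA"),
                        c(10, 0, 10) - c(14, 20, 14))
  arm_x <- seq(26, by = 3.8, length.out = arm_length)
  arm_z <- seq(4, 1, length.out = arm_length)
  arm <- cbind(arm_x, 0, arm_z)
  anchors <- rbind(c(-6, 2 + sg_offset, 3.5), c(-6, 2 + sg_offset, 1.0),
                   c(2, -2 - sg_offset, 3.5), c(2, -2 - sg_offset, 1.0))
  body <- .bind_parts(
    list(h1, h2, eat, stub),
    extra_xyz = rbind(arm, anchors),
    extra_name = c(rep("CA", arm_length), "CA", "SG", "CA", "SG"),
    extra_chain = c(rep("F", arm_length), rep("U", 4)),
    extra_resno = c(100L + seq_len(arm_length), 927L, 927L, 1003L, 1003L),
    body_id = "ulk1c_core")
  n <- nrow(body$xyz)
  body$tags <- c("FIP200_tip" = n - 4L, "C927:SG" = n - 2L,
                 "C1003:SG" = n)
  body
}

#' Synthetic ULK1-KD rigid body
#'
#' A dummy globular body standing in for the ULK1 kinase domain: a
#' spherical CA shell (chain U) plus an extended backbone stub over the
#' overlap residues 277-283 used to graft the body onto the N-terminal
#' end of the sampled ULK1 IDR (graft boundary residue 283).
#'
#' @param radius shell radius in Angstrom (default 14).
#' @param n_shell number of shell atoms (default 60).
#' @return a `rigid_body`.
#' @export
make_kd_fixture <- function(radius = 16, n_shell = 80L) {
  i <- seq_len(n_shell)
  ga <- pi * (3 - sqrt(5))
  zs <- 1 - 2 * (i - 0.5) / n_shell
  r2 <- sqrt(pmax(0, 1 - zs^2))
  shell <- radius * cbind(r2 * cos(ga * i), r2 * sin(ga * i), zs)
  stub <- build_chain(strrep("A", 7), .strand_dihedrals(7), chain_id = "U",
                      resno_start = 277L, segment_id = "kd_stub")
  stub$xyz <- sweep(stub$xyz, 2, c(radius - 0.5, 0.5, 0) - stub$xyz[2, ], "+")
  .bind_parts(list(stub), extra_xyz = shell,
              extra_name = rep("CA", n_shell),
              extra_chain = rep("U", n_shell),
              extra_resno = seq_len(n_shell),
              body_id = "ulk1_kd")
}

#' Synthetic HORMA dimer and bound-peptide pose
#'
#' A dummy ATG13:ATG101 HORMA-dimer body (chain H helix bundle) carrying
#' the ATG13 IDR growth stub (chain A, residues 228-230; the residue-230
#' triad anchors ATG13 IDR sampling), a binding-site centroid tag
#' `HORMA_site`, and a 23-residue backbone pose of ULK1 residues 428-450
#' fixed in the HORMA frame next to the binding site.  The junction
#' residue 450 carries a full backbone for CCD alignment.
#'
#' @param site_offset distance from the bundle centre to the bound pose
#'   (Angstrom).
#' @return list with elements `horma` and `pose`, both `rigid_body`.
#' @export
make_bound_pose_fixture <- function(site_offset = 20) {
  h1 <- .piece(strrep("A", 14), .helix_dihedrals(14), "H", 1L, c(0, 0, 0))
  h2 <- .piece(strrep("A", 14), .helix_dihedrals(14), "H", 21L, c(5, 5, 5))
  # ATG13 growth stub clear of the bundle, exiting along its own strand
  # direction (away from the body) so the IDR can grow unobstructed
  stub <- .piece("AAA", .strand_dihedrals(3), "A", 228L, c(14, 9, 6))
  site <- c(site_offset - 2, -2, 2)
  horma <- .bind_parts(list(h1, h2, stub), extra_xyz = matrix(site, 1, 3),
                       extra_name = "CB", extra_chain = "H",
                       extra_resno = 999L, body_id = "horma_dimer")
  horma$tags <- c("HORMA_site" = nrow(horma$xyz))
  di <- .strand_dihedrals(23)
  di[, 1] <- -75; di[, 2] <- 145
  di[8:12, ] <- matrix(rep(c(-60, -45), each = 5), 5, 2)
  pose <- build_chain(strrep("A", 23), di, chain_id = "U",
                      resno_start = 428L, segment_id = "bound_pose")
  # lie the pose flat (principal axes in the membrane plane) alongside
  # the binding site so neither end dips far below the body
  pose <- .flatten_piece(pose)
  pose$xyz <- sweep(pose$xyz, 2,
                    c(site_offset, -4, 2) - colMeans(pose$xyz), "+")
  pose <- rigid_body(pose$xyz, pose$name, pose$chain, pose$resno,
                     body_id = "ulk1_428_450_pose")
  list(horma = horma, pose = pose)
}

#' Toy CCD closure problem with a brute-force grid solution
#'
#' Builds a short chain (2-6 residues), defines a point anchor on the last
#' CA atom, and computes the exhaustive optimum of the effector-target
#' distance over a 5-degree grid of the free hinge dihedrals (one hinge
#' for 2 residues, three for 3 or more; an exhaustive grid over every
#' backbone dihedral would be combinatorially infeasible, so the toy task
#' exposes exactly these hinges to both the grid oracle and CCD).
#'
#' @param n_res chain length, 2 to 6 residues.
#' @param target optional target coordinate; by default a reachable target
#'   generated by perturbing the hinge dihedrals of the chain itself.
#' @param grid_step grid resolution in degrees (default 5).
#' @return list with `chain`, `task` (an [anchor_task()]), `rotatable`
#'   residue numbers, `hinges`, and `grid_optimum` (Angstrom).
#' @export
make_toy_loop <- function(n_res, target = NULL, grid_step = 5) {
  if (n_res < 2L || n_res > 6L)
    stop("n_res must be in 2..6 (the exhaustive grid explodes beyond that)")
  di <- cbind(runif(n_res, -170, 170), runif(n_res, -170, 170))
  chain <- build_chain(strrep("A", n_res), di, segment_id = "toy_loop")
  hinges <- if (n_res == 2L) list(c(1L, "psi")) else
    list(c(1L, "psi"), c(2L, "phi"), c(2L, "psi"))
  eff_row <- which(chain$chain == "A" & chain$resno == n_res &
                     chain$name == "CA")
  if (is.null(target)) {
    pert <- chain
    for (h in hinges)
      pert <- rotate_dihedral(pert, as.integer(h[1]), h[2],
                              runif(1, -180, 180))
    target <- pert$xyz[eff_row, ]
  }
  movable <- lapply(hinges, function(h)
    .movable_rows(chain, as.integer(h[1]), h[2]))
  axes <- lapply(hinges, function(h) {
    tri <- .triad(chain, "A", as.integer(h[1]))
    rows <- vapply(c("N", "CA", "C"), function(nm)
      which(chain$chain == "A" & chain$resno == as.integer(h[1]) &
              chain$name == nm), integer(1))
    if (h[2] == "phi") rows[c(1, 2)] else rows[c(2, 3)]
  })
  opt <- cpp_grid_scan(chain$xyz, movable, axes, eff_row,
                       as.numeric(target), grid_step)
  task <- anchor_task(data.frame(chain = "A", resno = n_res, name = "CA"),
                      "point", matrix(target, 1, 3))
  list(chain = chain, task = task,
       rotatable = sort(unique(vapply(hinges, function(h) as.integer(h[1]),
                                      integer(1)))),
       hinges = hinges, grid_optimum = opt)
}

# typical IDR amino-acid composition used for the packaged synthetic
# sequences and the composition-matched random generator
.IDR_COMPOSITION <- c(A = 0.070, C = 0.005, D = 0.045, E = 0.090, F = 0.015,
                      G = 0.080, H = 0.020, I = 0.025, K = 0.055, L = 0.055,
                      M = 0.015, N = 0.035, P = 0.120, Q = 0.055, R = 0.055,
                      S = 0.130, T = 0.065, V = 0.045, W = 0.005, Y = 0.015)

#' Composition-matched random IDR sequence
#'
#' Draws a sequence from the package's disorder-typical amino-acid
#' composition (Pro/Ser-rich, aromatics-poor).  Uses the current RNG
#' state.
#'
#' @param length sequence length.
#' @param composition named residue-frequency vector (normalized
#'   internally); defaults to the packaged composition.
#' @return one-letter amino-acid string.
#' @export
random_idr_sequence <- function(length, composition = NULL) {
  if (is.null(composition)) composition <- .IDR_COMPOSITION
  composition <- composition / sum(composition)
  paste(sample(names(composition), length, replace = TRUE,
               prob = composition), collapse = "")
}

#' Packaged IDR sequences
#'
#' Returns the packaged sequences for the ATG13 IDR segment (residues
#' 230-363, 134 residues) and the ULK1 IDR segment (residues 277-831, 555
#' residues).  The packaged sequences are synthetic composition-matched
#' stand-ins of the exact segment lengths (see the header of
#' `extdata/idr_sequences_synthetic.fasta`); ensemble statistics in this
#' package depend on segment length and residue-class (Gly/Pro)
#' composition, which the stand-ins match, not on sequence identity.
#'
#' @return named list with `atg13_230_363` and `ulk1_277_831`.
#' @export
idr_sequences <- function() {
  path <- system.file("extdata", "idr_sequences_synthetic.fasta",
                      package = "memtether")
  fa <- bio3d::read.fasta(path)
  seqs <- apply(fa$ali, 1, function(x) paste(x[x != "-"], collapse = ""))
  list(atg13_230_363 = unname(seqs[grep("atg13", names(seqs))]),
       ulk1_277_831 = unname(seqs[grep("ulk1", names(seqs))]))
}
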