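# Stochastic cyclic coordinate descent: small Gaussian hinge rotations
# accepted only when the effector objective strictly decreases and no new
# clashes are created.  The membrane is deliberately not part of the CCD
# clash test; only protein-protein clashes are enforced here.

#' CCD parameters
#'
#' @param sigma standard deviation of the Gaussian hinge rotation in
#'   degrees (default 1).
#' @param max_moves cap on attempted moves (default 200000).
#' @param anchor_tolerance plane/point anchor tolerance in Angstrom
#'   (default 5: convergence in plane mode requires every effector atom
#'   within this distance of the headgroup height).
#' @param align_threshold alignment-anchor RMSD threshold in Angstrom
#'   (default 0.6, over paired backbone heavy atoms).
#' @param stall_limit stop early when this many consecutive attempted
#'   moves are rejected (0 disables; stalled minimizations report
#'   `converged = FALSE`).
#' @return a `ccd_params`.
#' @export
ccd_params <- function(sigma = 1.0, max_moves = 200000L,
                       anchor_tolerance = 5.0, align_threshold = 0.6,
                       stall_limit = 10000L) {
  stopifnot(sigma > 0, anchor_tolerance > 0, align_threshold > 0,
            max_moves >= 0)
  structure(list(sigma = sigma, max_moves = as.integer(max_moves),
                 anchor_tolerance = anchor_tolerance,
                 align_threshold = align_threshold,
                 stall_limit = as.integer(stall_limit)),
            class = "ccd_params")
}

#' Anchor task driving CCD
#'
#' The effector arm can be atoms on either chain terminus or on an
#' attached rigid body.  The objective is the root-mean-square of the
#' per-effector residuals: Euclidean distance to paired `target` points
#' (`"point"`), |z - z0| to a membrane plane (`"plane"`), or the RMSD to
#' paired reference coordinates in the common frame (`"alignment"`, no
#' re-superposition).
#'
#' @param effectors data frame with columns `chain`, `resno`, `name`
#'   selecting effector atoms.
#' @param kind `"point"`, `"plane"` or `"alignment"`.
#' @param target k x 3 matrix of paired coordinates, or a
#'   [membrane_plane()] for `"plane"`.
#' @return an `anchor_task`.
#' @export
anchor_task <- function(effectors, kind = c("point", "plane", "alignment"),
                        target) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(effectors), nrow(effectors) >= 1L)
  if (kind == "plane" && !inherits(target, "membrane_plane"))
    stop("plane task needs a membrane_plane target")
  if (kind != "plane") {
    target <- as.matrix(target)
    if (nrow(target) != nrow(effectors))
      stop("targets must pair 1:1 with effectors")
  }
  structure(list(effectors = effectors, kind = kind, target = target),
            class = "anchor_task")
}

.effector_rows <- function(conf, effectors) {
  vapply(seq_len(nrow(effectors)), function(i) {
    r <- which(conf$chain == effectors$chain[i] &
                 conf$resno == effectors$resno[i] &
                 conf$name == effectors$name[i])
    if (length(r) < 1L)
      stop(sprintf("effector %s/%d/%s not found", effectors$chain[i],
                   effectors$resno[i], effectors$name[i]))
    r[1]
  }, integer(1))
}

.default_rotatable <- function(conf) {
  res <- sort(unique(conf$resno[conf$chain == conf$idr_chain & conf$grp == 0L]))
  # residues carrying a graft boundary stay frozen so rigid bodies keep
  # their exact grafted pose
  frozen <- unlist(lapply(conf$attachments, `[[`, "at"))
  setdiff(res, frozen)
}

.run_ccd <- function(conf, task, params, context = NULL, rotatable = NULL,
                     max_moves = params$max_moves, check_clash = TRUE,
                     record_deltas = FALSE) {
  if (is.null(rotatable)) rotatable <- .default_rotatable(conf)
  if (length(rotatable) == 0L) stop("no rotatable residues")
  lev <- .ctx_levels(context, unique(conf$chain))
  ctx <- .ctx_meta(context, lev)
  eff <- .effector_rows(conf, task$effectors)
  mode <- match(task$kind, c("point", "plane", "alignment")) - 1L
  tol <- switch(task$kind, point = params$anchor_tolerance,
                plane = params$anchor_tolerance,
                alignment = params$align_threshold)
  tgt <- if (task$kind == "plane") matrix(0, 0, 3) else task$target
  z0 <- if (task$kind == "plane") task$target$z0 else 0
  res <- cpp_ccd(conf$xyz, match(conf$chain, lev), conf$resno, conf$grp,
                 conf$atype, conf$pseudo, match(conf$idr_chain, lev),
                 identical(conf$anchor, "end"), as.integer(rotatable),
                 eff, mode, tgt, z0, params$sigma, as.integer(max_moves),
                 tol, clash_model()$cutoff, check_clash,
                 ctx$xyz, ctx$chain, ctx$resno, ctx$grp, record_deltas,
                 params$stall_limit)
  conf$xyz <- res$xyz
  list(conformation = conf, converged = isTRUE(res$converged),
       attempted = res$attempted, accepted = res$accepted,
       objective = res$objective, trace = res$trace,
       deltas = res$deltas)
}

#' Attempt a single CCD move
#'
#' Draws a residue uniformly among the rotatable residues, a dihedral kind
#' uniformly in {phi, psi}, and a rotation from Normal(0, sigma^2).  The
#' move is accepted iff the objective strictly decreases and no new
#' protein-protein clash is created; a rejected move leaves the chain
#' bit-identical.
#'
#' @param chain a `chain_conf`.
#' @param task an [anchor_task()].
#' @param params a [ccd_params()].
#' @param context optional static clash context (list of objects).
#' @param rotatable residue numbers eligible as hinges (default: all
#'   flexible-chain residues without graft boundaries).
#' @return list with `chain`, `accepted`, `objective`.
#' @export
ccd_move <- function(chain, task, params = ccd_params(), context = NULL,
                     rotatable = NULL) {
  res <- .run_ccd(chain, task, params, context, rotatable, max_moves = 1L,
                  record_deltas = TRUE)
  list(chain = res$conformation, accepted = res$accepted > 0,
       objective = res$objective, delta = res$deltas)
}

#' Minimize an anchor objective by stochastic CCD
#'
#' Repeats [ccd_move()] until the convergence criterion is met (plane
#' mode: every effector atom within `anchor_tolerance` of the headgroup
#' height; alignment mode: RMSD below `align_threshold`; point mode:
#' objective at or below `anchor_tolerance`) or `max_moves` attempted
#' moves.  Non-convergence is a result, not an error.
#'
#' @inheritParams ccd_move
#' @param record_deltas keep the vector of drawn rotations (diagnostics).
#' @return a `ccd_result`: final conformation, `converged` flag, move
#'   counts, final objective and the monotone non-increasing objective
#'   trace over accepted moves.
#' @export
ccd_minimize <- function(chain, task, params = ccd_params(), context = NULL,
                         rotatable = NULL, record_deltas = FALSE) {
  res <- .run_ccd(chain, task, params, context, rotatable,
                  record_deltas = record_deltas)
  structure(res, class = "ccd_result")
}

#' @export
print.ccd_result <- function(x, ...) {
  cat(sprintf("<ccd_result> %s: objective %.3f after %d/%d accepted moves\n",
              if (x$converged) "converged" else "not converged",
              x$objective, x$accepted, x$attempted))
  invisible(x)
}

#' Serializable CCD run report
#' @param result a `ccd_result`.
#' @return list suitable for `jsonlite::toJSON()`.
#' @export
ccd_report <- function(result) {
  list(moves_attempted = result$attempted, moves_accepted = result$accepted,
       acceptance_ratio = if (result$attempted > 0)
         result$accepted / result$attempted else 0,
       final_objective = result$objective, converged = result$converged)
}

#' Alignment-closure test
#'
#' TRUE iff the RMSD between paired coordinates, compared in the common
#' frame without re-superposition, is below `threshold`.
#'
#' @param chain_overlap,reference_overlap paired k x 3 coordinate
#'   matrices (backbone heavy atoms of the overlap residue).
#' @param threshold RMSD threshold in Angstrom (default 0.6).
#' @return logical, with the RMSD as attribute `rmsd`.
#' @export
alignment_close <- function(chain_overlap, reference_overlap, threshold = 0.6) {
  a <- as.matrix(chain_overlap); b <- as.matrix(reference_overlap)
  if (!all(dim(a) == dim(b))) stop("unpaired atoms in alignment test")
  rmsd <- sqrt(mean(rowSums((a - b)^2)))
  structure(rmsd < threshold, rmsd = rmsd)
}
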