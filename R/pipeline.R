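# The staged ULK1C tether protocol: membrane-anchored scaffold built from
# the ATG13 IDR, unbound sampling of the ULK1 IDR with the kinase domain
# attached, and the bound-state construction in which ULK1 428-450 is
# engaged on the ATG13 HORMA dimer.

#' ULK1C preset configuration
#'
#' Residue ranges, anchor names, filter thresholds and CCD tolerances of
#' the staged ULK1C protocol.  Ranges use author (UniProt) numbering and
#' are preserved end-to-end.
#'
#' @param d_mem pre-CCD membrane-proximity filter: both anchor SG atoms
#'   within this height (Angstrom) of the headgroup plane (default 20).
#' @param d_bind ATG13-proximity filter for bound-state candidates:
#'   minimum CA distance from any residue in the bound segment to the
#'   HORMA binding-site centroid (Angstrom, default 45).  The filter only
#'   gates CCD workload -- final junction geometry is set by `align_tol`
#'   -- so the default admits candidates within a few HORMA diameters.
#' @param plane_tol CCD plane-anchor tolerance (Angstrom, default 5).
#' @param align_tol CCD junction-alignment RMSD threshold (Angstrom,
#'   default 0.6).
#' @param n ensemble size per condition per scaffold replica (default
#'   100; the pooled mean over three replicas then carries a standard
#'   error of about 0.4 nm).
#' @param replicas number of scaffold replicas (default 3).
#' @param z0 membrane headgroup height (Angstrom, default 0).
#' @param plane_ccd_moves,align_ccd_moves CCD move caps for the scaffold
#'   plane stage and the junction alignment stage.
#' @return an `ulk1c_preset`.
#' @export
ulk1c_preset <- function(d_mem = 20, d_bind = 45, plane_tol = 5,
                         align_tol = 0.6, n = 100L, replicas = 3L, z0 = 0,
                         plane_ccd_moves = 200000L,
                         align_ccd_moves = 250000L) {
  stopifnot(d_mem > 0, d_bind > 0, plane_tol > 0, align_tol > 0)
  structure(list(
    atg13_range = c(230L, 363L), ulk1_range = c(277L, 831L),
    bound_segment = c(428L, 450L), truncate_through = 449L,
    resample_range = c(277L, 428L), kd_span = c(1L, 283L),
    kd_boundary = 283L, core_boundary = 362L,
    anchors = c("C927:SG", "C1003:SG", "FIP200_tip"),
    d_mem = d_mem, d_bind = d_bind, plane_tol = plane_tol,
    align_tol = align_tol, n = as.integer(n),
    replicas = as.integer(replicas), z0 = z0,
    plane_ccd_moves = as.integer(plane_ccd_moves),
    align_ccd_moves = as.integer(align_ccd_moves)
  ), class = "ulk1c_preset")
}

# place the HORMA assembly in the world frame: a fixed rotation about z
# followed by a translation that rests the body on a ~10 A pedestal above
# the headgroups, representing the membrane-inserted WIPI ring that
# carries the ATG13:ATG101 dimer (the WIPIs themselves are not modelled)
.place_horma <- function(horma, z0, angle = 25, pedestal = 10) {
  th <- angle * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  placed <- apply_transform(horma, rigid_transform(R, c(0, 0, 0)))
  ca230 <- placed$xyz[which(placed$chain == "A" & placed$resno == 230L &
                              placed$name == "CA"), ]
  shift <- c(-ca230[1], -ca230[2], z0 + pedestal - min(placed$xyz[, 3]))
  placed$xyz <- sweep(placed$xyz, 2, shift, "+")
  placed
}

# substring of a segment sequence by author residue numbers
.seq_window <- function(sequence, range_full, lo, hi) {
  substr(sequence, lo - range_full[1] + 1L, hi - range_full[1] + 1L)
}

.anchor_effectors <- function(conf, tag_rows) {
  data.frame(chain = conf$chain[tag_rows], resno = conf$resno[tag_rows],
             name = conf$name[tag_rows])
}

#' Build one membrane-anchored ULK1C scaffold
#'
#' Stage 1 of the protocol: (1) sample the ATG13 IDR (residues 230-363)
#' anchored at the HORMA stub with membrane half-space acceptance; (2)
#' graft the ULK1C core onto the IDR at residue 362; (3) keep candidates
#' whose two anchor SG atoms lie within `d_mem` of the headgroup plane;
#' (4) run plane-mode CCD over the three anchors (two SG atoms and the
#' FIP200 arm tip) until all are within `plane_tol` of the plane.  The
#' membrane is not part of the CCD clash test.
#'
#' @param core the ULK1C-core rigid body (see [make_core_fixture()]).
#' @param preset an [ulk1c_preset()].
#' @param policy a [growth_policy()]; its plane is set from the preset.
#' @param horma placed or local HORMA body ([make_bound_pose_fixture()]);
#'   a local-frame body is placed automatically.
#' @param pose bound-peptide pose in the same local frame as `horma`,
#'   used to verify that the grafted pose's junction and resample-anchor
#'   regions remain sterically accessible on the finished scaffold
#'   (`NULL` skips the check).
#' @param sequence ATG13 IDR sequence (defaults to the packaged one).
#' @param library dihedral library.
#' @param max_tries candidate budget before a diagnostic error.
#' @return a `ulk1c_scaffold`: the anchored conformation, the placed
#'   HORMA body, the membrane plane, anchor rows and CCD report.
#' @export
build_scaffold <- function(core, preset = ulk1c_preset(),
                           policy = growth_policy(),
                           horma = NULL, pose = NULL,
                           sequence = NULL,
                           library = default_dihedral_library(),
                           max_tries = 2000L) {
  plane <- membrane_plane(preset$z0)
  policy$plane <- plane
  if (is.null(sequence)) sequence <- idr_sequences()$atg13_230_363
  idr_seq_full <- idr_sequences()$ulk1_277_831
  if (is.null(horma)) {
    bp <- make_bound_pose_fixture()
    horma <- bp$horma
    if (is.null(pose)) pose <- bp$pose
  }
  if (!any(horma$chain == "A" & horma$resno == 230L))
    stop("HORMA body lacks the ATG13 residue-230 growth stub")
  horma_local <- horma
  if (abs(min(horma$xyz[, 3])) < 1e-6 || min(horma$xyz[, 3]) <= preset$z0)
    horma <- .place_horma(horma, preset$z0)
  pose_w <- NULL
  if (!is.null(pose)) {
    sel <- horma_local$chain == "H" & horma_local$name == "CA"
    selw <- horma$chain == "H" & horma$name == "CA"
    pose_w <- apply_transform(pose, superpose(
      horma_local$xyz[sel, , drop = FALSE],
      horma$xyz[selw, , drop = FALSE])$transform)
    jreg <- pose_w$xyz[pose_w$resno %in% c(preset$resample_range[2],
                                           preset$resample_range[2] + 1L,
                                           (preset$truncate_through - 1L):
                                             (preset$truncate_through + 1L)),
                       , drop = FALSE]
  }
  triad230 <- .triad(horma, "A", 230L)
  seq_chain <- .seq_window(sequence, preset$atg13_range,
                           preset$atg13_range[1], preset$atg13_range[2])
  stats <- c(sample = 0L, attach = 0L, filter = 0L, ccd = 0L, orient = 0L,
             occluded = 0L, infeasible = 0L)
  for (try in seq_len(max_tries)) {
    conf <- tryCatch(
      hierarchical_assemble(seq_chain, library, policy,
                            resno_start = preset$atg13_range[1],
                            anchor = "start", anchor_triad = triad230,
                            context = list(horma), chain_id = "A",
                            segment_id = "atg13_idr"),
      memtether_sampling_error = function(e) NULL)
    if (is.null(conf)) { stats["sample"] <- stats[["sample"]] + 1L; next }
    conf2 <- tryCatch(
      attach_rigid_body(conf, core, at = preset$core_boundary, side = "C",
                        clash = policy$clash),
      memtether_clash_error = function(e) NULL)
    if (is.null(conf2)) { stats["attach"] <- stats[["attach"]] + 1L; next }
    crows <- which(conf2$grp == max(conf2$grp))
    core_meta <- list(xyz = conf2$xyz[crows, , drop = FALSE],
                      chain = conf2$chain[crows],
                      resno = conf2$resno[crows], grp = conf2$grp[crows])
    if (any(height_above_plane(core_meta$xyz, plane) <= 0) ||
        .clash_between(core_meta, horma, policy$clash$cutoff)) {
      stats["attach"] <- stats[["attach"]] + 1L
      next
    }
    tag_rows <- conf2$attachments[[length(conf2$attachments)]]$tags
    sg_rows <- tag_rows[c("C927:SG", "C1003:SG")]
    if (any(height_above_plane(conf2$xyz[sg_rows, , drop = FALSE], plane) >
            preset$d_mem)) {
      stats["filter"] <- stats[["filter"]] + 1L
      next
    }
    task <- anchor_task(.anchor_effectors(conf2, tag_rows[preset$anchors]),
                        "plane", plane)
    res <- ccd_minimize(conf2, task,
                        ccd_params(anchor_tolerance = preset$plane_tol,
                                   max_moves = preset$plane_ccd_moves),
                        context = list(horma))
    if (!res$converged) { stats["ccd"] <- stats[["ccd"]] + 1L; next }
    # CCD does not see the membrane, so the body can end up swung below
    # the plane; such a scaffold cannot host any half-space-respecting
    # IDR sampling (the tether point is buried) and is rejected
    tri831 <- .triad(res$conformation, "U", 831L)
    if (any(height_above_plane(tri831, plane) <= 2)) {
      stats["orient"] <- stats[["orient"]] + 1L
      next
    }
    # the bound-state pose is grafted onto the HORMA frame later; the
    # junction and resample-anchor regions must leave an approach
    # corridor (6 A) for the chains grafted
    # there, or no bound member can be built on this scaffold
    if (!is.null(pose_w)) {
      dmin <- min(vapply(seq_len(nrow(jreg)), function(k)
        min(sqrt(rowSums(sweep(res$conformation$xyz, 2, jreg[k, ])^2))),
        numeric(1)))
      if (dmin < 6) {
        stats["occluded"] <- stats[["occluded"]] + 1L
        next
      }
      # feasibility probe: the scaffold must demonstrably host a closed
      # bound-state candidate within a bounded sampling budget, or the
      # later stage would grind on it indefinitely
      site_w <- tag_coord(horma, "HORMA_site")
      tri831 <- .triad(res$conformation, "U", 831L)
      seg_probe <- .seq_window(idr_seq_full, c(277L, 831L),
                               preset$bound_segment[1], 831L)
      probe_policy <- policy
      feasible <- FALSE
      ccd_tries <- 0L
      for (pa in seq_len(60L)) {
        outc <- .bound_candidate(res$conformation, horma, pose_w, site_w,
                                 tri831, seg_probe, preset, probe_policy,
                                 library)
        if (outc$status == "ok") { feasible <- TRUE; break }
        if (outc$status %in% c("ccd", "halfspace")) {
          ccd_tries <- ccd_tries + 1L
          if (ccd_tries >= 5L) break
        }
      }
      if (!feasible) {
        stats["infeasible"] <- stats[["infeasible"]] + 1L
        next
      }
    }
    anchor_rows <- tag_rows[preset$anchors]
    return(structure(list(conf = res$conformation, horma = horma,
                          plane = plane, anchor_rows = anchor_rows,
                          ccd = ccd_report(res), tries = try,
                          stage_failures = stats),
                     class = "ulk1c_scaffold"))
  }
  stop(structure(class = c("memtether_sampling_error", "error", "condition"),
                 list(message = sprintf(
                   paste0("no scaffold candidate passed within %d tries ",
                          "(sampling %d, attachment %d, filter %d, CCD %d, ",
                          "orientation %d, pose occlusion %d, bound-state ",
                          "probe %d)"),
                   max_tries, stats[["sample"]], stats[["attach"]],
                   stats[["filter"]], stats[["ccd"]],
                   stats[["orient"]], stats[["occluded"]],
                   stats[["infeasible"]]), call = NULL,
                   diagnostics = as.list(stats))))
}

#' @export
print.ulk1c_scaffold <- function(x, ...) {
  resid <- height_above_plane(x$conf$xyz[x$anchor_rows, , drop = FALSE],
                              x$plane)
  cat(sprintf("<ulk1c_scaffold> anchors at %s A above plane (%d tries)\n",
              paste(sprintf("%.2f", resid), collapse = "/"), x$tries))
  invisible(x)
}

# growth spec of the ULK1 IDR on a scaffold (KD attached at the boundary)
.ulk1_spec <- function(scaffold, kd, preset, sequence, range_hi,
                       extra_context = NULL) {
  lo <- preset$kd_boundary
  ctx_conf <- scaffold$conf
  if (range_hi != preset$ulk1_range[2]) {
    # shortened tether variants end at the same EAT anchor but carry
    # lower residue numbers, so the EAT stub would not be recognized as a
    # bonded neighbour; omit it from the clash context instead
    keep <- !(ctx_conf$chain == "U" & ctx_conf$resno >= 829L &
                ctx_conf$resno <= 845L)
    for (f in c("xyz", "name", "chain", "resno", "grp", "pseudo", "atype"))
      ctx_conf[[f]] <- if (f == "xyz") ctx_conf[[f]][keep, , drop = FALSE]
        else ctx_conf[[f]][keep]
  }
  growth_spec(.seq_window(sequence, preset$ulk1_range, lo, range_hi),
              resno_start = lo, chain_id = "U", segment_id = "ulk1_idr",
              anchor = "end",
              anchor_triad = .triad(scaffold$conf, "U", 831L),
              context = c(list(ctx_conf, scaffold$horma), extra_context),
              attachments = list(list(body = kd, at = lo, side = "N")))
}


# one bound-state candidate: grow toward the placed pose, apply the
# proximity rule, truncate, close the junction by CCD, check the
# half-space.  Returns the stage reached ("sample", "filter", "ccd",
# "halfspace" or "ok") plus the CCD result when it ran.
.bound_candidate <- function(conf, horma, pose_w, site_w, triad831, seg_seq,
                             preset, policy, library) {
  jres <- preset$truncate_through + 1L
  j_ca <- pose_w$xyz[pose_w$resno == jres & pose_w$name == "CA", ]
  ctx_grow <- list(conf, horma, pose_w)
  cand <- tryCatch(
    hierarchical_assemble(seg_seq, library, policy,
                          resno_start = preset$bound_segment[1],
                          anchor = "end", anchor_triad = triad831,
                          context = ctx_grow, chain_id = "U",
                          segment_id = "ulk1_idr_candidate",
                          window = list(range = c(jres, jres),
                                        center = j_ca,
                                        dist = preset$d_bind * 0.75)),
    memtether_sampling_error = function(e) NULL)
  if (is.null(cand)) return(list(status = "sample"))
  seg_ca <- cand$xyz[cand$resno >= preset$bound_segment[1] &
                       cand$resno <= preset$bound_segment[2] &
                       cand$name == "CA", , drop = FALSE]
  if (min(sqrt(rowSums(sweep(seg_ca, 2, site_w)^2))) > preset$d_bind)
    return(list(status = "filter"))
  keep <- cand$resno > preset$truncate_through
  trunc <- cand
  for (f in c("xyz", "name", "chain", "resno", "grp", "pseudo", "atype"))
    trunc[[f]] <- if (f == "xyz") cand[[f]][keep, , drop = FALSE] else
      cand[[f]][keep]
  sel <- cand$seq_resno > preset$truncate_through
  trunc$seq <- cand$seq[sel]
  trunc$seq_resno <- cand$seq_resno[sel]
  eff <- data.frame(chain = "U", resno = jres, name = c("N", "CA", "C", "O"))
  tgt <- do.call(rbind, lapply(eff$name, function(nm)
    pose_w$xyz[pose_w$resno == jres & pose_w$name == nm, ]))
  res <- ccd_minimize(trunc, anchor_task(eff, "alignment", tgt),
                      ccd_params(align_threshold = preset$align_tol,
                                 max_moves = preset$align_ccd_moves),
                      context = ctx_grow)
  if (!res$converged) return(list(status = "ccd"))
  if (any(height_above_plane(res$conformation$xyz,
                             membrane_plane(preset$z0)) <= 0))
    return(list(status = "halfspace"))
  list(status = "ok", res = res)
}

#' Sample the unbound ULK1-IDR ensemble
#'
#' Stage 2: the ULK1 IDR (residues 277-831) is sampled tethered at its
#' C-terminal end to the EAT attachment point on the scaffold, with the
#' kinase domain grafted at the overlap boundary (residue 283; the KD body
#' supplies residues 277-282).  Accepted members are clash-free against
#' the scaffold and lie entirely above the membrane.
#'
#' @param scaffold a `ulk1c_scaffold`.
#' @param kd the KD rigid body ([make_kd_fixture()]).
#' @param preset an [ulk1c_preset()].
#' @param n members to accept.
#' @param policy a [growth_policy()] (plane is set from the scaffold).
#' @param sequence ULK1 IDR sequence (defaults to the packaged one).
#' @param library dihedral library.
#' @param range_hi last sampled residue (default 831; lower values
#'   shorten the tether for scaling checks).
#' @return a `tether_ensemble`.
#' @export
sample_unbound <- function(scaffold, kd, preset = ulk1c_preset(), n,
                           policy = growth_policy(), sequence = NULL,
                           library = default_dihedral_library(),
                           range_hi = 831L) {
  policy$plane <- scaffold$plane
  if (is.null(sequence)) sequence <- idr_sequences()$ulk1_277_831
  spec <- .ulk1_spec(scaffold, kd, preset, sequence, range_hi)
  ens <- grow_ensemble(spec, n, library, policy)
  ens$info$condition <- "unbound"
  ens
}

# combine conformations and rigid bodies into one member record
.merge_members <- function(parts, template) {
  xs <- lapply(parts, .meta_of)
  names_all <- unlist(lapply(parts, `[[`, "name"))
  grp_off <- 0L
  grps <- list()
  for (i in seq_along(xs)) {
    g <- xs[[i]]$grp
    g[g > 0L] <- g[g > 0L] + grp_off
    grps[[i]] <- g
    grp_off <- grp_off + max(c(0L, g))
  }
  out <- template
  out$xyz <- do.call(rbind, lapply(xs, `[[`, "xyz"))
  out$name <- names_all
  out$chain <- unlist(lapply(xs, `[[`, "chain"))
  out$resno <- unlist(lapply(xs, `[[`, "resno"))
  out$grp <- unlist(grps)
  out$pseudo <- out$resno
  out$atype <- .atype_of(out$name)
  out$attachments <- list()
  out
}

#' Build the bound ULK1-IDR ensemble
#'
#' Stage 3: (1) the bound-peptide pose (ULK1 428-450) is placed by
#' superposition of the HORMA body onto the scaffold's HORMA frame; (2)
#' fresh candidate IDR conformations (residues 428-831, tethered at the
#' EAT point) are filtered for proximity of the bound segment to the
#' HORMA binding-site centroid (`d_bind`); (3) candidate residues up to
#' 449 are removed; (4) alignment-mode CCD pulls the junction residue 450
#' onto the bound pose until the backbone RMSD is below `align_tol`; (5)
#' the remaining N-terminal residues (277-428) are resampled with the KD
#' attached, subject to clash and half-space acceptance.
#'
#' @inheritParams sample_unbound
#' @param bound_pose the bound-peptide pose in the HORMA local frame.
#' @param horma_local the HORMA body in the same local frame (used for
#'   the placement superposition).
#' @return a `tether_ensemble` whose `info` records per-member junction
#'   RMSD and stage statistics.
#' @export
build_bound <- function(scaffold, bound_pose, kd, preset = ulk1c_preset(), n,
                        policy = growth_policy(),
                        horma_local = make_bound_pose_fixture()$horma,
                        sequence = NULL,
                        library = default_dihedral_library()) {
  policy$plane <- scaffold$plane
  plane <- scaffold$plane
  if (is.null(sequence)) sequence <- idr_sequences()$ulk1_277_831
  # (1) place the pose via superposition of the HORMA domain
  sel_l <- horma_local$chain == "H" & horma_local$name == "CA"
  sel_w <- scaffold$horma$chain == "H" & scaffold$horma$name == "CA"
  sp <- superpose(horma_local$xyz[sel_l, , drop = FALSE],
                  scaffold$horma$xyz[sel_w, , drop = FALSE])
  pose_w <- apply_transform(bound_pose, sp$transform)
  site_w <- tag_coord(scaffold$horma, "HORMA_site")
  ctx_grow <- list(scaffold$conf, scaffold$horma, pose_w)
  triad831 <- .triad(scaffold$conf, "U", 831L)
  lo_c <- preset$bound_segment[1]
  seg_seq <- .seq_window(sequence, preset$ulk1_range, lo_c,
                         preset$ulk1_range[2])
  stats <- c(sample = 0L, filter = 0L, ccd = 0L, halfspace = 0L,
             resample = 0L)
  members <- vector("list", n)
  info <- data.frame(member = seq_len(n), junction_rmsd = NA_real_,
                     ccd_moves = NA_integer_, attempt = NA_integer_)
  got <- 0L
  cap <- policy$max_attempts_factor * n
  attempts <- 0L
  resample_policy <- policy
  resample_policy$max_attempts_factor <- 40L
  while (got < n) {
    if (attempts >= cap)
      stop(structure(
        class = c("memtether_sampling_error", "error", "condition"),
        list(message = sprintf(
          paste0("bound-state construction starved: %d/%d members after %d ",
                 "candidates (sampling %d, proximity filter %d, CCD %d, ",
                 "half-space %d, resampling %d)"), got, n, attempts,
          stats[["sample"]], stats[["filter"]], stats[["ccd"]],
          stats[["halfspace"]], stats[["resample"]]), call = NULL,
          diagnostics = as.list(stats))))
    attempts <- attempts + 1L
    # (2)-(4) candidate generation toward the placed pose, proximity
    # filter, truncation and junction CCD (shared with the scaffold
    # feasibility probe)
    outc <- .bound_candidate(scaffold$conf, scaffold$horma, pose_w, site_w,
                             triad831, seg_seq, preset, policy, library)
    if (outc$status != "ok") {
      stats[outc$status] <- stats[[outc$status]] + 1L
      next
    }
    res <- outc$res
    # (5) resample the N-terminal tether with the KD attached, anchored on
    # the pose's residue-428 triad
    respec <- growth_spec(
      .seq_window(sequence, preset$ulk1_range, preset$kd_boundary,
                  preset$resample_range[2]),
      resno_start = preset$kd_boundary, chain_id = "U",
      segment_id = "ulk1_idr_resampled", anchor = "end",
      anchor_triad = .triad(pose_w, "U", preset$resample_range[2]),
      context = c(ctx_grow, list(res$conformation)),
      attachments = list(list(body = kd, at = preset$kd_boundary,
                              side = "N")))
    reseg <- tryCatch(grow_ensemble(respec, 1L, library, resample_policy),
                      memtether_sampling_error = function(e) NULL)
    if (is.null(reseg)) { stats["resample"] <- stats[["resample"]] + 1L; next }
    seg <- reseg$members[[1]]
    # drop the duplicate copy of the graft residue (the pose's copy is
    # canonical)
    dup <- seg$chain == "U" & seg$grp == 0L &
      seg$resno == preset$resample_range[2]
    for (f in c("xyz", "name", "chain", "resno", "grp", "pseudo", "atype"))
      seg[[f]] <- if (f == "xyz") seg[[f]][!dup, , drop = FALSE] else
        seg[[f]][!dup]
    member <- .merge_members(list(seg, pose_w, res$conformation),
                             template = res$conformation)
    member$seq <- c(seg$seq[-length(seg$seq)], strsplit(seg_seq, "")[[1]])
    member$seq_resno <- c(seg$seq_resno[-length(seg$seq_resno)],
                          lo_c:preset$ulk1_range[2])
    got <- got + 1L
    members[[got]] <- member
    info$junction_rmsd[got] <- res$objective
    info$ccd_moves[got] <- res$accepted
    info$attempt[got] <- attempts
  }
  info$condition <- "bound"
  structure(list(members = members, info = info, plane = plane,
                 attempts = attempts, fails = stats),
            class = "tether_ensemble")
}

#' Run the full staged ULK1C protocol
#'
#' For each scaffold replica: build a membrane-anchored scaffold from a
#' fresh ATG13 IDR conformation, then the unbound and bound ULK1-IDR
#' ensembles of `preset$n` members each.  Per-stage seeds are derived
#' from the root seed (see [derive_seed()]) so each stage is
#' independently reproducible.
#'
#' @param seed integer root seed.
#' @param preset an [ulk1c_preset()].
#' @param policy a [growth_policy()].
#' @param fixtures optional list with elements `core`, `kd`, `horma`,
#'   `pose` (defaults to the packaged synthetic fixtures).
#' @param sequences optional list with `atg13_230_363`, `ulk1_277_831`.
#' @param library dihedral library.
#' @return an `ensemble_pair`: per-replica unbound and bound ensembles,
#'   scaffolds and full provenance.
#' @export
run_ulk1c <- function(seed = 1L, preset = ulk1c_preset(),
                      policy = growth_policy(), fixtures = NULL,
                      sequences = NULL,
                      library = default_dihedral_library()) {
  if (is.null(fixtures)) {
    bp <- make_bound_pose_fixture()
    fixtures <- list(core = make_core_fixture(), kd = make_kd_fixture(),
                     horma = bp$horma, pose = bp$pose)
  }
  if (is.null(sequences)) sequences <- idr_sequences()
  unbound <- list()
  bound <- list()
  scaffolds <- list()
  seeds <- list()
  for (r in seq_len(preset$replicas)) {
    s_sc <- derive_seed(seed, 1L, r)
    s_un <- derive_seed(seed, 2L, r)
    s_bd <- derive_seed(seed, 3L, r)
    seeds[[r]] <- c(scaffold = s_sc, unbound = s_un, bound = s_bd)
    set.seed(s_sc)
    scaffolds[[r]] <- build_scaffold(fixtures$core, preset, policy,
                                     horma = fixtures$horma,
                                     pose = fixtures$pose,
                                     sequence = sequences$atg13_230_363,
                                     library = library)
    set.seed(s_un)
    unbound[[r]] <- sample_unbound(scaffolds[[r]], fixtures$kd, preset,
                                   preset$n, policy,
                                   sequence = sequences$ulk1_277_831,
                                   library = library)
    unbound[[r]]$info$replica <- r
    set.seed(s_bd)
    bound[[r]] <- build_bound(scaffolds[[r]], fixtures$pose, fixtures$kd,
                              preset, preset$n, policy,
                              horma_local = fixtures$horma,
                              sequence = sequences$ulk1_277_831,
                              library = library)
    bound[[r]]$info$replica <- r
  }
  structure(list(unbound = unbound, bound = bound, scaffolds = scaffolds,
                 plane = membrane_plane(preset$z0),
                 provenance = list(seed = seed, stage_seeds = seeds,
                                   preset = unclass(preset),
                                   package_version =
                                     as.character(utils::packageVersion("memtether")))),
            class = "ensemble_pair")
}

#' @export
print.ensemble_pair <- function(x, ...) {
  cat(sprintf("<ensemble_pair> %d replicas, %d unbound + %d bound members\n",
              length(x$scaffolds),
              sum(vapply(x$unbound, function(e) length(e$members), 1)),
              sum(vapply(x$bound, function(e) length(e$members), 1))))
  invisible(x)
}
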