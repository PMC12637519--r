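# Hierarchical chain growth: self-avoiding IDR sampling from the coil
# library with membrane half-space acceptance, and rigid-body attachment.

#' Create a rigid body
#'
#' A rigid body is an immutable atom set (its internal pairwise distances
#' never change) that can be grafted onto a flexible chain or used as a
#' static clash context.  Tagged atoms (e.g. `"C927:SG"`) name anchors for
#' CCD and filters.
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param name atom names (`"N"`, `"CA"`, `"SG"`, ...).
#' @param chain per-atom chain identifiers.
#' @param resno per-atom author residue numbers (preserved end-to-end;
#'   never renumbered).
#' @param tags named integer vector of tagged atom rows.
#' @param body_id label.
#' @return a `rigid_body`.
#' @export
rigid_body <- function(xyz, name, chain, resno, tags = integer(), body_id = "body") {
  stopifnot(nrow(xyz) == length(name), length(name) == length(chain),
            length(chain) == length(resno))
  structure(list(xyz = xyz, name = name, chain = chain,
                 resno = as.integer(resno),
                 grp = rep(1L, nrow(xyz)),
                 tags = tags, body_id = body_id),
            class = "rigid_body")
}

#' @export
print.rigid_body <- function(x, ...) {
  cat(sprintf("<rigid_body> %s: %d atoms, chains %s, tags: %s\n", x$body_id,
              nrow(x$xyz), paste(unique(x$chain), collapse = "/"),
              if (length(x$tags)) paste(names(x$tags), collapse = ", ") else "none"))
  invisible(x)
}

#' Coordinates of a tagged anchor atom
#' @param body a `rigid_body`.
#' @param tag tag name.
#' @return length-3 coordinate vector.
#' @export
tag_coord <- function(body, tag) {
  if (!tag %in% names(body$tags)) stop("no tag '", tag, "' on body ", body$body_id)
  body$xyz[body$tags[[tag]], ]
}

#' Growth policy
#'
#' @param fragment_length residues per fragment (default 5; merged with a
#'   one-residue overlap).
#' @param retry_fragment resampling budget for an internally clashing
#'   fragment.
#' @param retry_merge redraw budget for the mobile child of a failing
#'   merge.
#' @param clash a [clash_model()].
#' @param plane optional [membrane_plane()]; when set, accepted
#'   conformations and their attachments lie entirely above it.
#' @param max_attempts_factor global attempt cap for [grow_ensemble()] is
#'   `max_attempts_factor * n`.
#' @return a `growth_policy`.
#' @export
growth_policy <- function(fragment_length = 5L, retry_fragment = 30L,
                          retry_merge = 30L, clash = clash_model(),
                          plane = NULL, max_attempts_factor = 1000L) {
  stopifnot(fragment_length >= 1L, retry_fragment >= 1L, retry_merge >= 1L)
  structure(list(fragment_length = as.integer(fragment_length),
                 retry_fragment = as.integer(retry_fragment),
                 retry_merge = as.integer(retry_merge),
                 clash = clash, plane = plane,
                 max_attempts_factor = as.integer(max_attempts_factor)),
            class = "growth_policy")
}

# encode the union of chain identifiers of a conf/body and a context list
.ctx_meta <- function(context, lev) {
  if (is.null(context) || length(context) == 0L)
    return(list(xyz = matrix(0, 0, 3), chain = integer(), resno = integer(),
                grp = integer()))
  xs <- lapply(context, .meta_of)
  grp_off <- 0L
  for (i in seq_along(xs)) {
    g <- xs[[i]]$grp
    g[g > 0L] <- g[g > 0L] + grp_off
    xs[[i]]$grp <- g
    grp_off <- grp_off + max(c(0L, g))
  }
  list(xyz = do.call(rbind, lapply(xs, `[[`, "xyz")),
       chain = match(unlist(lapply(xs, `[[`, "chain")), lev),
       resno = unlist(lapply(xs, `[[`, "resno")),
       grp = unlist(lapply(xs, `[[`, "grp")))
}

.ctx_levels <- function(context, extra) {
  unique(c(unlist(lapply(context, function(x) x$chain)), extra))
}

.sampling_failure <- function(msg, diagnostics) {
  stop(structure(class = c("memtether_sampling_error", "error", "condition"),
                 list(message = paste0(msg, " (draws: ", diagnostics$draws,
                                       ", merge failures: ",
                                       diagnostics$merge_fails, ")"),
                      call = NULL, diagnostics = diagnostics)))
}

# shared worker behind sample_fragment / hierarchical_assemble
.sample_segment <- function(sequence, resno_start, library, policy,
                            fragment_length, anchor = "none",
                            anchor_triad = NULL, context = NULL,
                            chain_id = "A", segment_id = "segment",
                            window = NULL) {
  seq <- strsplit(sequence, "")[[1]]
  n <- length(seq)
  if (n < 1L) stop("empty segment")
  lev <- .ctx_levels(context, chain_id)
  ctx <- .ctx_meta(context, lev)
  if (is.null(anchor_triad)) anchor_triad <- matrix(0, 0, 3)
  z0 <- if (is.null(policy$plane)) -Inf else policy$plane$z0
  res <- cpp_sample_chain(.class_index(seq), .lib_matrices(library),
                          seq != "G", as.integer(fragment_length),
                          policy$retry_fragment, policy$retry_merge,
                          identical(anchor, "end"), anchor_triad, z0,
                          ctx$xyz, ctx$chain, ctx$resno, ctx$grp,
                          match(chain_id, lev), as.integer(resno_start),
                          policy$clash$cutoff,
                          if (is.null(window)) numeric() else
                            c(window$range, window$center, window$dist))
  if (!isTRUE(res$ok))
    .sampling_failure(sprintf("segment %s (%d residues) could not be sampled",
                              segment_id, n), res)
  nm <- c("N", "CA", "C", "O", "CB")[res$atype + 1L]
  conf <- .new_conf(res$xyz, nm, rep(chain_id, length(nm)), res$resno,
                    grp = rep(0L, length(nm)), pseudo = res$resno,
                    seq = seq, seq_resno = resno_start:(resno_start + n - 1L),
                    segment_id = segment_id, idr_chain = chain_id,
                    anchor = if (identical(anchor, "none")) "start" else anchor)
  attr(conf, "draws") <- res$draws
  conf
}

#' Sample one fragment from the dihedral library
#'
#' Draws per-residue (phi, psi) pairs from the residue-class distributions
#' (omega fixed at 180) and rebuilds internally clashing fragments up to
#' the retry budget.
#'
#' @param sequence amino-acid string of the fragment.
#' @param library a [dihedral_library()].
#' @param policy a [growth_policy()].
#' @param resno_start author residue number of the first residue.
#' @param chain_id,segment_id identifiers.
#' @return a `chain_conf`.
#' @export
sample_fragment <- function(sequence, library = default_dihedral_library(),
                            policy = growth_policy(), resno_start = 1L,
                            chain_id = "A", segment_id = "fragment") {
  .sample_segment(sequence, resno_start, library, policy,
                  fragment_length = nchar(sequence), chain_id = chain_id,
                  segment_id = segment_id)
}

#' Hierarchically assemble a self-avoiding segment
#'
#' Fragments of `policy$fragment_length` residues are sampled from the
#' library and merged pairwise by exact superposition of the one-residue
#' overlap (N, CA, C of the shared residue).  Merges that clash, dip below
#' a configured membrane plane, or hit the static context redraw the
#' mobile child up to the retry budget.  With `anchor = "start"` or
#' `"end"` the respective terminal residue is pinned to `anchor_triad`
#' (rows N, CA, C) and all absolute-frame intermediates are checked
#' against plane and context.
#'
#' @inheritParams sample_fragment
#' @param anchor `"none"`, `"start"` or `"end"`.
#' @param anchor_triad 3x3 matrix (rows N, CA, C) pinning the anchored
#'   terminal residue.
#' @param context list of `chain_conf`/`rigid_body` objects acting as a
#'   static clash context.
#' @param window optional terminal proximity constraint,
#'   `list(range = c(lo, hi), center = c(x, y, z), dist = d)`: once an
#'   absolute-frame intermediate contains residues `lo:hi`, their minimum
#'   CA distance to `center` must not exceed `d` (enforced with local
#'   redraws like every other acceptance constraint).
#' @return a `chain_conf`.
#' @export
hierarchical_assemble <- function(sequence,
                                  library = default_dihedral_library(),
                                  policy = growth_policy(),
                                  resno_start = 1L, anchor = "none",
                                  anchor_triad = NULL, context = NULL,
                                  chain_id = "A", segment_id = "segment",
                                  window = NULL) {
  .sample_segment(sequence, resno_start, library, policy,
                  fragment_length = policy$fragment_length, anchor = anchor,
                  anchor_triad = anchor_triad, context = context,
                  chain_id = chain_id, segment_id = segment_id,
                  window = window)
}

#' Attach a rigid body to a chain
#'
#' With `method = "graft"` (the hierarchical-chain-growth convention used
#' by the pipeline) the body is placed by exact superposition of the
#' backbone triad of the boundary residue `at`, and the body's copy of
#' that residue is dropped; chain residues on the body side of the
#' boundary, if any, are replaced by the body.  With `method = "lsq"` the
#' body is placed by least-squares superposition over the backbone N, CA,
#' C atoms of all `overlap` residues (for imported models whose overlap
#' conformation need not match the chain).
#'
#' Attachment records the body as a rigid group whose atoms move with
#' downstream dihedral rotations.  A body that clashes with the chain
#' outside the overlap raises an error (callers resample).
#'
#' @param chain a `chain_conf`.
#' @param body a `rigid_body` sharing backbone residues with the chain.
#' @param at boundary residue number (graft method).
#' @param side which side of `at` the body occupies: `"N"` (body carries
#'   lower residue numbers) or `"C"`.
#' @param method `"graft"` or `"lsq"`.
#' @param overlap residue numbers used for `"lsq"` superposition.
#' @param clash a [clash_model()] used for the attachment clash test; set
#'   `NULL` to skip.
#' @return the combined `chain_conf` (attachment recorded).
#' @export
attach_rigid_body <- function(chain, body, at = NULL, side = c("N", "C"),
                              method = c("graft", "lsq"), overlap = NULL,
                              clash = clash_model()) {
  method <- match.arg(method)
  side <- match.arg(side)
  hostch <- chain$idr_chain
  bch <- body$chain[which(body$resno %in% c(at, overlap))][1]
  if (is.na(bch)) stop("body does not carry the overlap residues")
  if (method == "graft") {
    if (is.null(at)) stop("graft method needs a boundary residue 'at'")
    tf <- .triad_transform(.triad(body, bch, at), .triad(chain, hostch, at))
    placed <- apply_transform(body, tf)
    drop_body <- placed$chain == bch & placed$resno == at
    keep_chain <- rep(TRUE, nrow(chain$xyz))
    if (side == "N")
      keep_chain <- !(chain$chain == hostch & chain$grp == 0L &
                        chain$resno < at)
    else
      keep_chain <- !(chain$chain == hostch & chain$grp == 0L &
                        chain$resno > at)
    overlap_rmsd <- 0
  } else {
    if (is.null(overlap) || length(overlap) < 1L)
      stop("lsq method needs at least one overlap residue")
    sel_b <- body$chain == bch & body$resno %in% overlap &
      body$name %in% c("N", "CA", "C")
    sel_c <- chain$chain == hostch & chain$grp == 0L &
      chain$resno %in% overlap & chain$name %in% c("N", "CA", "C")
    if (sum(sel_b) != sum(sel_c) || sum(sel_b) < 3L)
      stop("overlap residues lack paired backbone atoms")
    ob <- order(body$resno[sel_b], body$name[sel_b])
    oc <- order(chain$resno[sel_c], chain$name[sel_c])
    sp <- superpose(body$xyz[sel_b, , drop = FALSE][ob, ],
                    chain$xyz[sel_c, , drop = FALSE][oc, ])
    placed <- apply_transform(body, sp$transform)
    drop_body <- placed$chain == bch & placed$resno %in% overlap
    keep_chain <- rep(TRUE, nrow(chain$xyz))
    overlap_rmsd <- sp$rmsd
    at <- if (side == "N") max(overlap) else min(overlap)
  }
  new_grp <- max(chain$grp) + 1L
  brows <- which(!drop_body)
  out <- chain
  out$xyz <- rbind(chain$xyz[keep_chain, , drop = FALSE],
                   placed$xyz[brows, , drop = FALSE])
  out$name <- c(chain$name[keep_chain], placed$name[brows])
  out$chain <- c(chain$chain[keep_chain], placed$chain[brows])
  out$resno <- c(chain$resno[keep_chain], placed$resno[brows])
  out$grp <- c(chain$grp[keep_chain], rep(new_grp, length(brows)))
  out$pseudo <- c(chain$pseudo[keep_chain], rep(as.integer(at), length(brows)))
  out$atype <- .atype_of(out$name)
  tags <- body$tags
  if (length(tags)) {
    # re-point tags at rows of the combined object
    kept_map <- cumsum(!drop_body)
    tags <- vapply(tags, function(i) {
      if (drop_body[i]) return(NA_integer_)
      sum(keep_chain) + kept_map[i]
    }, integer(1))
    tags <- tags[!is.na(tags)]
  }
  out$attachments <- c(chain$attachments,
                       list(list(body_id = body$body_id, grp = new_grp,
                                 at = as.integer(at), side = side,
                                 method = method, overlap_rmsd = overlap_rmsd,
                                 tags = tags)))
  if (!is.null(clash)) {
    body_part <- list(xyz = out$xyz[out$grp == new_grp, , drop = FALSE],
                      chain = out$chain[out$grp == new_grp],
                      resno = out$resno[out$grp == new_grp],
                      grp = out$grp[out$grp == new_grp])
    rest <- list(xyz = out$xyz[out$grp != new_grp, , drop = FALSE],
                 chain = out$chain[out$grp != new_grp],
                 resno = out$resno[out$grp != new_grp],
                 grp = out$grp[out$grp != new_grp])
    if (.clash_between(body_part, rest, clash$cutoff))
      stop(structure(class = c("memtether_clash_error", "error", "condition"),
                     list(message = sprintf(
                       "rigid body %s clashes with the chain on attachment",
                       body$body_id), call = NULL)))
  }
  out
}

#' Grow an ensemble of accepted conformations
#'
#' Repeatedly assembles the segment described by `spec`, attaches its
#' rigid bodies, and applies the acceptance constraints (self-avoidance,
#' clash against the static context, and -- when a membrane is configured
#' -- every atom of chain and attachments strictly above the plane) until
#' `n` conformations are accepted or the global attempt cap
#' (`policy$max_attempts_factor * n`) is exceeded.
#'
#' @param spec a [growth_spec()].
#' @param n number of accepted conformations.
#' @param library a [dihedral_library()].
#' @param policy a [growth_policy()].
#' @return a `tether_ensemble`: list of members plus per-member provenance
#'   (`info`) and acceptance statistics.
#' @export
grow_ensemble <- function(spec, n, library = default_dihedral_library(),
                          policy = growth_policy()) {
  stopifnot(n >= 1L)
  members <- vector("list", n)
  info <- data.frame(member = seq_len(n), attempt = NA_integer_,
                     draws = NA_real_)
  cap <- policy$max_attempts_factor * n
  got <- 0L
  attempts <- 0L
  fails <- c(sample = 0L, attach = 0L)
  while (got < n) {
    if (attempts >= cap) {
      stop(structure(
        class = c("memtether_sampling_error", "error", "condition"),
        list(message = sprintf(
          paste0("acceptance rate below floor: %d/%d accepted after %d ",
                 "attempts (sample failures: %d, attachment failures: %d)"),
          got, n, attempts, fails[["sample"]], fails[["attach"]]),
          call = NULL,
          diagnostics = list(accepted = got, attempts = attempts,
                             fails = fails))))
    }
    attempts <- attempts + 1L
    member <- tryCatch({
      if (identical(spec$geometry, "virtual_bond")) {
        .sample_virtual_bond(spec, policy)
      } else {
        conf <- hierarchical_assemble(spec$sequence, library, policy,
                                      resno_start = spec$resno_start,
                                      anchor = spec$anchor,
                                      anchor_triad = spec$anchor_triad,
                                      context = spec$context,
                                      chain_id = spec$chain_id,
                                      segment_id = spec$segment_id)
        for (att in spec$attachments) {
          conf <- attach_rigid_body(conf, att$body, at = att$at,
                                    side = att$side, clash = policy$clash)
          arows <- which(conf$grp == max(conf$grp))
          if (!is.null(policy$plane) &&
              any(height_above_plane(conf$xyz[arows, , drop = FALSE],
                                     policy$plane) <= 0))
            stop(structure(class = c("memtether_clash_error", "error",
                                     "condition"),
                           list(message = "attachment below membrane",
                                call = NULL)))
          if (length(spec$context) &&
              .clash_between(list(xyz = conf$xyz[arows, , drop = FALSE],
                                  chain = conf$chain[arows],
                                  resno = conf$resno[arows],
                                  grp = conf$grp[arows]),
                             .ctx_flat(spec$context), policy$clash$cutoff))
            stop(structure(class = c("memtether_clash_error", "error",
                                     "condition"),
                           list(message = "attachment clashes with context",
                                call = NULL)))
        }
        conf
      }
    },
    memtether_sampling_error = function(e) { fails["sample"] <<- fails[["sample"]] + 1L; NULL },
    memtether_clash_error = function(e) { fails["attach"] <<- fails[["attach"]] + 1L; NULL })
    if (is.null(member)) next
    got <- got + 1L
    members[[got]] <- member
    info$attempt[got] <- attempts
    info$draws[got] <- if (!is.null(attr(member, "draws"))) attr(member, "draws") else NA_real_
  }
  structure(list(members = members, info = info, plane = policy$plane,
                 attempts = attempts, fails = fails),
            class = "tether_ensemble")
}

# flatten a context list into one meta set (chains kept as characters)
.ctx_flat <- function(context) {
  xs <- lapply(context, .meta_of)
  list(xyz = do.call(rbind, lapply(xs, `[[`, "xyz")),
       chain = unlist(lapply(xs, `[[`, "chain")),
       resno = unlist(lapply(xs, `[[`, "resno")),
       grp = unlist(lapply(xs, `[[`, "grp")))
}

#' @export
print.tether_ensemble <- function(x, ...) {
  cat(sprintf("<tether_ensemble> %d members (%d attempts)\n",
              length(x$members), x$attempts))
  invisible(x)
}

#' Growth specification for [grow_ensemble()]
#'
#' @param sequence amino-acid string of the segment.
#' @param resno_start author residue number of the first residue.
#' @param chain_id,segment_id identifiers.
#' @param anchor `"none"`, `"start"` or `"end"`.
#' @param anchor_triad 3x3 N/CA/C matrix pinning the anchored residue.
#' @param context list of static `chain_conf`/`rigid_body` objects.
#' @param attachments list of `list(body =, at =, side =)` rigid-body
#'   grafts applied after assembly.
#' @param geometry `"backbone"` (default) or `"virtual_bond"`: the latter
#'   samples a freely-jointed CA-only chain with bond length
#'   `virtual_bond_length`, the analytically solvable polymer reference
#'   used to validate the sampler.
#' @param virtual_bond_length CA-CA virtual bond length in Angstrom.
#' @return a `growth_spec`.
#' @export
growth_spec <- function(sequence, resno_start = 1L, chain_id = "A",
                        segment_id = "segment", anchor = "none",
                        anchor_triad = NULL, context = NULL,
                        attachments = list(), geometry = "backbone",
                        virtual_bond_length = 3.8) {
  structure(list(sequence = sequence, resno_start = as.integer(resno_start),
                 chain_id = chain_id, segment_id = segment_id,
                 anchor = anchor, anchor_triad = anchor_triad,
                 context = context, attachments = attachments,
                 geometry = geometry,
                 virtual_bond_length = virtual_bond_length),
            class = "growth_spec")
}

.sample_virtual_bond <- function(spec, policy) {
  n <- nchar(spec$sequence)
  z0 <- if (is.null(policy$plane)) -Inf else policy$plane$z0
  cutoff <- if (is.null(policy$clash)) 0 else policy$clash$cutoff
  res <- cpp_sample_fjc(n, spec$virtual_bond_length, cutoff, z0,
                        policy$retry_merge)
  if (!isTRUE(res$ok))
    .sampling_failure("virtual-bond chain rejected",
                      list(draws = res$attempts, merge_fails = 0))
  seq <- strsplit(spec$sequence, "")[[1]]
  resno <- spec$resno_start:(spec$resno_start + n - 1L)
  .new_conf(res$xyz, rep("CA", n), rep(spec$chain_id, n), resno,
            grp = rep(0L, n), pseudo = resno, seq = seq, seq_resno = resno,
            segment_id = spec$segment_id, idr_chain = spec$chain_id)
}
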