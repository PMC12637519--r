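# PDB and configuration I/O.  Structure files use fixed-column PDB records
# (Angstrom, author residue numbers preserved); ensembles are multi-model
# files with MODEL numbers equal to the 1-based member index.

#' Read a PDB structure
#'
#' Reads ATOM records of heavy atoms from a (possibly multi-model) PDB
#' file.  Chain identifiers and author residue numbers are preserved.
#' Files with insertion codes are rejected; residues missing any backbone
#' atom (N, CA, C) are reported by name unless `require_backbone` is
#' `FALSE`.
#'
#' @param path PDB file.
#' @param require_backbone check that every residue carries N, CA and C.
#' @return list of models; each model is a `structure_model` with fields
#'   `xyz`, `name`, `chain`, `resno`, `aa`.
#' @export
read_structure <- function(path, require_backbone = TRUE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (any(!is.na(at$insert) & at$insert != ""))
    stop("insertion codes are not supported (found in ", path, ")")
  if (require_backbone) {
    key <- paste(at$chain, at$resno)
    missing <- vapply(split(at$elety, key), function(e)
      !all(c("N", "CA", "C") %in% e), logical(1))
    # CA-only entries from coarse models are allowed when a residue has
    # exactly one CA atom and nothing else is expected; anything partial
    # is an error
    part <- names(missing)[missing &
                             vapply(split(at$elety, key), function(e)
                               !identical(unique(e), "CA"), logical(1))]
    if (length(part))
      stop("residues missing backbone atoms: ",
           paste(utils::head(part, 10), collapse = ", "),
           if (length(part) > 10) " ..." else "")
  }
  nmod <- nrow(pdb$xyz)
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    structure(list(xyz = xyz[seq_len(nrow(at)), , drop = FALSE],
                   name = at$elety, chain = at$chain,
                   resno = as.integer(at$resno), aa = at$resid,
                   grp = rep(0L, nrow(at))),
              class = "structure_model")
  })
}

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")

.resname_of <- function(member) {
  res3 <- rep("ALA", nrow(member$xyz))
  if (!is.null(member$seq) && !is.null(member$seq_resno)) {
    m <- match(member$resno, member$seq_resno)
    ok <- !is.na(m) & member$chain == member$idr_chain
    res3[ok] <- unname(.aa3[member$seq[m[ok]]])
    res3[is.na(res3)] <- "ALA"
  }
  res3
}

.pdb_atom_line <- function(serial, name, resname, chain, resno, xyz) {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, nm, resname, substr(chain, 1, 1), resno,
          xyz[1], xyz[2], xyz[3], substr(name, 1, 1))
}

.model_lines <- function(member) {
  res3 <- .resname_of(member)
  ord <- order(match(member$chain, unique(member$chain)), member$resno)
  vapply(seq_along(ord), function(k) {
    i <- ord[k]
    .pdb_atom_line(k, member$name[i], res3[i], member$chain[i],
                   member$resno[i], member$xyz[i, ])
  }, character(1))
}

#' Write an ensemble as a multi-model PDB file
#'
#' MODEL numbers are the 1-based member indices; output is byte-stable
#' for identical ensembles.
#'
#' @param ensemble a `tether_ensemble`, or a list of members.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  members <- if (inherits(ensemble, "tether_ensemble")) ensemble$members
  else ensemble
  if (length(members) < 1L) stop("ensemble has no members")
  con <- file(path, "wb")
  on.exit(close(con))
  for (m in seq_along(members)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(.model_lines(members[[m]]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a single conformation or rigid body as PDB
#' @param x a `chain_conf`, `rigid_body` or `structure_model`.
#' @param path output file.
#' @export
write_structure <- function(x, path) {
  if (is.null(x$idr_chain)) x$idr_chain <- ""
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(.model_lines(x), con)
  writeLines("END", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# run configuration

.config_defaults <- function() {
  p <- ulk1c_preset()
  # "members" rather than "n": bare n is a YAML 1.1 boolean literal
  list(seed = 1L, members = p$n, replicas = p$replicas, z0 = p$z0,
       d_mem = p$d_mem, d_bind = p$d_bind, plane_tol = p$plane_tol,
       align_tol = p$align_tol, fragment_length = 5L,
       clash_cutoff = 2.5, out_dir = ".",
       core = "fixture:core", kd = "fixture:kd", horma = "fixture:horma",
       pose = "fixture:pose", sequences = "fixture:sequences",
       library = "fixture:library")
}

#' Read and validate a run configuration file
#'
#' A flat YAML key set; unknown keys are errors and all defaults are
#' materialized into the returned object (and hence into the provenance
#' copy written next to every run).  Structure inputs accept file paths
#' or `fixture:` URIs resolving to the packaged synthetic fixtures.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return a named list of validated settings.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$members <- as.integer(cfg$members)
  cfg$replicas <- as.integer(cfg$replicas)
  cfg
}

.resolve_fixtures <- function(cfg) {
  res <- list()
  bp <- NULL
  get_bp <- function() {
    if (is.null(bp)) bp <<- make_bound_pose_fixture()
    bp
  }
  body_of <- function(key, maker) {
    v <- cfg[[key]]
    if (identical(v, paste0("fixture:", key))) return(maker())
    mdl <- read_structure(v, require_backbone = FALSE)[[1]]
    rigid_body(mdl$xyz, mdl$name, mdl$chain, mdl$resno, body_id = key)
  }
  res$core <- body_of("core", make_core_fixture)
  res$kd <- body_of("kd", make_kd_fixture)
  res$horma <- body_of("horma", function() get_bp()$horma)
  res$pose <- body_of("pose", function() get_bp()$pose)
  res
}

#' Write the run summary, distance table and structures of a pipeline run
#'
#' Emits `summary.json` (provenance, per-condition summary statistics),
#' `distances.tsv` (per-member KD distances in nm plus junction RMSD),
#' and one multi-model PDB per condition and replica.
#'
#' @param pair an `ensemble_pair`.
#' @param dir output directory (created if needed).
#' @param write_pdb also write the multi-model structures.
#' @return `dir`, invisibly.
#' @export
write_run_summary <- function(pair, dir, write_pdb = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- distances_table(pair)
  utils::write.table(tab, file.path(dir, "distances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summaries <- lapply(c("unbound", "bound"), function(cond) {
    lapply(seq_along(pair[[cond]]), function(r) {
      s <- summarize_distances(pair[[cond]][[r]], pair$plane, replica = r)
      list(condition = cond, replica = r, n = s$n, mean_nm = s$mean,
           sd_nm = s$sd, max_nm = s$max, breaks = s$breaks,
           counts = s$counts)
    })
  })
  pooled <- split(tab$distance_nm, tab$condition)
  out <- list(provenance = pair$provenance,
              pooled_mean_nm = lapply(pooled, mean),
              pooled_max_nm = lapply(pooled, max),
              per_replica = summaries)
  jsonlite::write_json(out, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (write_pdb) {
    for (cond in c("unbound", "bound"))
      for (r in seq_along(pair[[cond]]))
        write_ensemble(pair[[cond]][[r]],
                       file.path(dir, sprintf("%s_replica%d.pdb", cond, r)))
  }
  invisible(dir)
}
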