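# Ensemble observables: KD-membrane distance distributions, accessible
# volume and local-concentration fold changes for membrane-tethered
# domains.  Distances are reported in nm externally and Angstrom
# internally; the conversion lives here.

.A_PER_NM <- 10

# rows of the kinase-domain selection: ULK1 chain, residues within the KD
# span (rigid body plus grafted overlap), backbone heavy atoms only
.kd_rows <- function(member, kd_chain = "U", kd_max_resno = 283L) {
  which(member$chain == kd_chain & member$resno <= kd_max_resno &
          member$name %in% c("N", "CA", "C", "O"))
}

#' Kinase-domain to membrane distance of one member
#'
#' The distance is the height of the mass-unweighted centre of the KD
#' backbone heavy atoms above the headgroup plane, in nm.
#'
#' @param member a `chain_conf` ensemble member.
#' @param plane a [membrane_plane()].
#' @param kd_selection integer atom rows of the KD, or `NULL` for the
#'   default selection (ULK1 chain, residues up to 283).
#' @return distance in nm.
#' @export
kd_membrane_distance <- function(member, plane, kd_selection = NULL) {
  rows <- if (is.null(kd_selection)) .kd_rows(member) else kd_selection
  if (length(rows) == 0L) stop("empty kinase-domain selection")
  com_z <- mean(member$xyz[rows, 3])
  (com_z - plane$z0) / .A_PER_NM
}

#' Summarize KD-membrane distances over an ensemble
#'
#' @param ensemble a `tether_ensemble`.
#' @param plane a [membrane_plane()]; defaults to the ensemble's plane.
#' @param kd_selection see [kd_membrane_distance()].
#' @param breaks histogram bin edges in nm; the default is 1-nm bins from
#'   0 to `ceiling(max) + 1`.
#' @param condition,replica labels stored in the summary.
#' @return a `distance_summary`: per-member distances (nm), mean, sd,
#'   max, histogram bin edges and counts.
#' @export
summarize_distances <- function(ensemble, plane = NULL, kd_selection = NULL,
                                breaks = NULL, condition = NULL,
                                replica = NA_integer_) {
  if (is.null(plane)) plane <- ensemble$plane
  if (is.null(plane)) stop("no membrane plane available")
  d <- vapply(ensemble$members, kd_membrane_distance, numeric(1),
              plane = plane, kd_selection = kd_selection)
  if (is.null(condition))
    condition <- if (!is.null(ensemble$info$condition))
      ensemble$info$condition[1] else "unlabelled"
  if (is.null(breaks)) breaks <- seq(0, ceiling(max(d)) + 1, by = 1)
  counts <- as.integer(table(cut(d, breaks, include.lowest = TRUE)))
  sdev <- if (length(d) > 1L) stats::sd(d) else 0
  structure(list(distances = d, mean = mean(d), sd = sdev,
                 max = max(d), breaks = breaks, counts = counts,
                 condition = condition, replica = replica,
                 n = length(d)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("<distance_summary> %s (replica %s): n = %d, mean %.2f nm, sd %.2f, max %.2f\n",
              x$condition, x$replica, x$n, x$mean, x$sd, x$max))
  invisible(x)
}

#' Per-member distance table of an ensemble pair
#'
#' @param pair an `ensemble_pair` from [run_ulk1c()].
#' @return data frame with columns condition, replica, member,
#'   distance_nm, and (for bound members) junction RMSD.
#' @export
distances_table <- function(pair) {
  rows <- list()
  for (cond in c("unbound", "bound")) {
    for (r in seq_along(pair[[cond]])) {
      ens <- pair[[cond]][[r]]
      d <- vapply(ens$members, kd_membrane_distance, numeric(1),
                  plane = pair$plane)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, replica = r, member = seq_along(d),
        distance_nm = d,
        junction_rmsd = if (!is.null(ens$info$junction_rmsd))
          ens$info$junction_rmsd else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Accessible volume of a membrane-tethered domain
#'
#' Hemispherical model: a domain tethered at the membrane with maximum
#' extension `r_max` explores the half-space volume V = (2/3) pi r_max^3
#' above the plane.
#'
#' @param r_max maximum membrane-domain separation in nm (> 0).
#' @return a `volume_estimate` with elements `r_max`, `volume` (nm^3) and
#'   `model`.
#' @export
accessible_volume <- function(r_max) {
  if (!is.numeric(r_max) || r_max <= 0) stop("r_max must be positive")
  structure(list(r_max = r_max, volume = 2 / 3 * pi * r_max^3,
                 model = "hemisphere above the membrane plane"),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("<volume_estimate> r_max %.1f nm -> %.3g nm^3 (%s)\n",
              x$r_max, x$volume, x$model))
  invisible(x)
}

#' Fold change of accessible volume (and local concentration)
#'
#' The ratio of accessible volumes for maximum extensions `r1` and `r2`
#' is (r1/r2)^3, independent of the shape prefactor.  The same factor is
#' the fold increase in local concentration near the membrane when the
#' tether shortens from `r1` to `r2`.
#'
#' @param r1,r2 maximum extensions in nm (> 0).
#' @return the fold change (r1/r2)^3.
#' @export
volume_fold_change <- function(r1, r2) {
  if (any(c(r1, r2) <= 0)) stop("extensions must be positive")
  (r1 / r2)^3
}
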