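#' Head-to-head spacing D_HH of a total electron density profile
#'
#' Distance between the two highest local maxima on opposite sides of the
#' bilayer center, read from a symmetrized total electron density profile.
#'
#' @param profile A symmetrized total [density_profile()].
#' @return D_HH in Angstrom.
#' @export
measure_dhh <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  v <- profile$values
  n <- length(v)
  ismax <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  z <- profile$bin_centers[ismax]
  pos <- ismax[z > 0]
  neg <- ismax[z < 0]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("no head-to-head structure: profile lacks maxima on both sides of z = 0")
  }
  # each side's peak: midpoint of all bins attaining the side maximum, so
  # exact plateau ties resolve symmetrically
  side_peak <- function(keep) {
    idx <- which(keep)
    vmax <- max(v[idx])
    mean(range(profile$bin_centers[idx][v[idx] == vmax]))
  }
  side_peak(profile$bin_centers > 0) - side_peak(profile$bin_centers < 0)
}

#' Hydrocarbon thickness 2D_C from a hydrocarbon density profile
#'
#' Operationalized as the distance between the two half-plateau crossings
#' of the (symmetrized) combined hydrocarbon profile. The plateau is the
#' mean density over the central 50% of the region between the crossings,
#' solved self-consistently; for a flat-topped (error-function) slab this
#' reduces to the half-maximum crossing and recovers the generating
#' half-width exactly.
#'
#' @param profile Symmetrized CH2(+CH3) [density_profile()] with an
#'   interior plateau.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return 2D_C in Angstrom.
#' @export
measure_hc_thickness <- function(profile, max_iter = 50L, tol = 1e-9) {
  stopifnot(inherits(profile, "density_profile"))
  z <- profile$bin_centers
  v <- profile$values
  if (all(v == 0)) stop("hydrocarbon profile is identically zero")
  plateau <- max(v)
  cross <- NA_real_
  for (it in seq_len(max_iter)) {
    half <- plateau / 2
    new_cross <- half_crossings(z, v, half)
    new_plateau <- mean(v[abs(z - mean(new_cross)) <=
                            (new_cross[2] - new_cross[1]) / 4])
    if (!is.na(cross[1]) &&
        abs(new_plateau - plateau) <= tol * max(plateau, 1e-12)) {
      cross <- new_cross
      break
    }
    plateau <- new_plateau
    cross <- new_cross
  }
  cross[2] - cross[1]
}

## Outermost crossings of `level`: scan outward from the profile maximum on
## each side, linearly interpolating between the straddling bins.
half_crossings <- function(z, v, level) {
  imax <- which.max(v)
  right <- NA_real_
  for (i in imax:(length(v) - 1L)) {
    if (v[i] >= level && v[i + 1] < level) {
      right <- z[i] + (z[i + 1] - z[i]) * (v[i] - level) / (v[i] - v[i + 1])
      break
    }
  }
  left <- NA_real_
  for (i in imax:2L) {
    if (v[i] >= level && v[i - 1] < level) {
      left <- z[i] - (z[i] - z[i - 1]) * (v[i] - level) / (v[i] - v[i - 1])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("profile does not cross the half-plateau level on both sides")
  }
  c(left, right)
}

#' Hydrocarbon volume per lipid from area and thickness
#'
#' Volume conservation for the chain region: `V_C = A_L * D_C`, with
#' `D_C = 2D_C / 2` the hydrocarbon half-thickness.
#'
#' @param A_L Area per lipid (Angstrom^2, > 0).
#' @param two_dc Hydrocarbon thickness 2D_C (Angstrom, > 0).
#' @return V_C in Angstrom^3.
#' @export
hydrocarbon_volume <- function(A_L, two_dc) {
  if (A_L <= 0 || two_dc <= 0) stop("inputs must be > 0")
  A_L * two_dc / 2
}

#' Time-averaged peptide insertion depths
#'
#' For each peptide molecule, the average over analysis frames of the
#' absolute z of its center of mass after hydrocarbon recentering.
#'
#' @param traj A [toy_trajectory].
#' @param equilibration_fraction Fraction of initial frames discarded.
#' @return Named numeric vector of depths (Angstrom), one per peptide id.
#' @export
peptide_depth <- function(traj, equilibration_fraction = 0.5) {
  stopifnot(inherits(traj, "toy_trajectory"))
  keep <- analysis_frames(length(traj$frames), equilibration_fraction)
  lz <- traj$box[3]
  per_frame <- lapply(traj$frames[keep], function(fr) {
    fr <- recenter_frame(fr, lz)
    pep <- fr[fr$component == "peptide", , drop = FALSE]
    if (nrow(pep) == 0L) stop("trajectory contains no peptide beads")
    vapply(split(pep, pep$molecule),
           function(p) abs(sum(p$mass * p$z) / sum(p$mass)), numeric(1))
  })
  ids <- names(per_frame[[1]])
  out <- vapply(ids, function(id) {
    mean(vapply(per_frame, `[[`, numeric(1), id))
  }, numeric(1))
  names(out) <- ids
  out
}

#' Occupancy of the bilayer core by a bead species
#'
#' Counts, per analysis frame, the beads of the given species whose
#' recentered |z| lies strictly below the threshold, and reports the
#' fraction of frames with at least one such bead.
#'
#' @param traj A [toy_trajectory].
#' @param species Component label (e.g. `"ion"`, `"water"`).
#' @param threshold Core half-width in Angstrom (default 5, strict `<`).
#' @param equilibration_fraction Fraction of initial frames discarded.
#' @return List with `counts` (per retained frame) and `fraction_occupied`.
#' @export
core_occupancy <- function(traj, species = "ion", threshold = 5,
                           equilibration_fraction = 0) {
  stopifnot(inherits(traj, "toy_trajectory"))
  if (threshold <= 0) stop("`threshold` must be > 0")
  keep <- analysis_frames(length(traj$frames), equilibration_fraction)
  lz <- traj$box[3]
  present <- any(vapply(traj$frames[keep],
                        function(fr) species %in% fr$component, logical(1)))
  if (!present) stop(sprintf("unknown species label '%s'", species))
  counts <- vapply(traj$frames[keep], function(fr) {
    fr <- recenter_frame(fr, lz)
    sum(fr$component == species & abs(fr$z) < threshold)
  }, numeric(1))
  list(counts = counts, fraction_occupied = mean(counts >= 1))
}

#' Structural summary of a scored bilayer system
#'
#' Bundles the tabulated structural quantities: head-to-head spacing,
#' hydrocarbon thickness, area per lipid, peptide depth(s), hydrocarbon
#' volume, and peak total electron density.
#'
#' @param total_profile Symmetrized total electron [density_profile()].
#' @param hc_profile Symmetrized hydrocarbon [density_profile()].
#' @param A_L Area per lipid (Angstrom^2).
#' @param z_peptide Peptide depth(s) in Angstrom (optional).
#' @return List of class `structural_summary` with fields `D_HH`,
#'   `twoD_C`, `A_L`, `z_peptide`, `V_C`, `peak_rho`.
#' @export
structural_summary <- function(total_profile, hc_profile, A_L,
                               z_peptide = NULL) {
  dhh <- measure_dhh(total_profile)
  twodc <- measure_hc_thickness(hc_profile)
  structure(
    list(D_HH = dhh, twoD_C = twodc, A_L = A_L,
         z_peptide = z_peptide,
         V_C = hydrocarbon_volume(A_L, twodc),
         peak_rho = peak_density(total_profile)$value),
    class = "structural_summary"
  )
}

#' @export
print.structural_summary <- function(x, ...) {
  cat(sprintf("<structural_summary> D_HH %.2f A, 2D_C %.2f A, A_L %.1f A^2, V_C %.1f A^3, peak rho %.3f e/A^3\n",
              x$D_HH, x$twoD_C, x$A_L, x$V_C, x$peak_rho))
  if (!is.null(x$z_peptide)) {
    cat(sprintf("  peptide depth(s): %s A\n",
                paste(sprintf("%.1f", x$z_peptide), collapse = ", ")))
  }
  invisible(x)
}
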