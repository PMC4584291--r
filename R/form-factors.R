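#' Bilayer form factor |F(qz)|
#'
#' @param qz Strictly ascending scattering vector (1/Angstrom).
#' @param amplitude Modulus of the form factor, >= 0. Units are
#'   e/Angstrom^2 for absolute form factors, or lobe-2-normalized units.
#' @param delta Optional per-point experimental uncertainty (> 0, same
#'   units as `amplitude`).
#' @param scale_status One of `"absolute"`, `"arbitrary"`,
#'   `"lobe2_normalized"`.
#' @return An object of class `form_factor`.
#' @export
form_factor <- function(qz, amplitude, delta = NULL,
                        scale_status = c("absolute", "arbitrary",
                                         "lobe2_normalized")) {
  scale_status <- match.arg(scale_status)
  if (is.unsorted(qz, strictly = TRUE)) stop("`qz` must be strictly ascending")
  stopifnot(length(amplitude) == length(qz))
  if (any(amplitude < 0)) stop("`amplitude` must be >= 0")
  if (!is.null(delta)) {
    stopifnot(length(delta) == length(qz))
    if (any(delta <= 0)) stop("`delta` must be > 0 where present")
  }
  structure(
    list(qz = as.numeric(qz), amplitude = as.numeric(amplitude),
         delta = if (is.null(delta)) NULL else as.numeric(delta),
         scale_status = scale_status),
    class = "form_factor"
  )
}

#' @export
print.form_factor <- function(x, ...) {
  cat(sprintf("<form_factor> %d points, qz [%.3f, %.3f] 1/A, scale %s%s\n",
              length(x$qz), min(x$qz), max(x$qz), x$scale_status,
              if (is.null(x$delta)) "" else ", delta set"))
  invisible(x)
}

#' @export
as.data.frame.form_factor <- function(x, ...) {
  d <- data.frame(qz = x$qz, F = x$amplitude)
  if (!is.null(x$delta)) d$delta <- x$delta
  d
}

#' Default simulation qz grid
#'
#' 0 to 0.8 1/Angstrom in steps of 0.005, covering scattering lobes L1-L4
#' of fluid phosphatidylcholine bilayers.
#' @return Numeric vector.
#' @export
default_qz_grid <- function() seq(0, 0.8, by = 0.005)

#' Default experimental qz grid
#'
#' 0.1 to 0.78 1/Angstrom in steps of 0.005: diffuse-scattering data start
#' above the beamstop cutoff, so the first scattering lobe is truncated at
#' low qz.
#' @return Numeric vector.
#' @export
default_experimental_qz <- function() seq(0.1, 0.78, by = 0.005)

#' Fourier transform of a density profile to a form factor
#'
#' Continuous cosine transform of the water-subtracted electron density,
#' \deqn{F(q_z) = \int (\rho(z) - \rho_W) \cos(q_z z)\, dz,}
#' evaluated by trapezoid quadrature over the profile's grid. The profile
#' should be symmetrized (even in z); the modulus is returned in
#' e/Angstrom^2.
#'
#' @param profile A symmetrized [density_profile()] on a grid even about 0.
#' @param water_density Bulk water electron density (e/Angstrom^3).
#' @param qz Ascending qz grid (1/Angstrom, >= 0).
#' @return A [form_factor()] with `scale_status = "absolute"`.
#' @export
profile_form_factor <- function(profile, water_density,
                                qz = default_qz_grid()) {
  stopifnot(inherits(profile, "density_profile"))
  z <- profile$bin_centers
  if (max(abs(z + rev(z))) > 1e-8 * bin_width_of(profile)) {
    stop("profile grid is not symmetric about z = 0")
  }
  if (any(qz < 0)) stop("`qz` must be >= 0")
  dz <- bin_width_of(profile)
  w <- rep(dz, length(z))
  w[c(1, length(z))] <- dz / 2
  contrast <- (profile$values - water_density) * w
  f <- as.vector(cos(outer(qz, z)) %*% contrast)
  form_factor(qz, abs(f), scale_status = "absolute")
}

#' Locate scattering lobes and minima of a form factor
#'
#' Minima are local minima of |F| whose amplitude falls below
#' `minimum_threshold_fraction` of the global maximum (diffuse experimental
#' data never reach exact zeros). Lobes are the intervals between
#' consecutive minima, numbered from low qz; the leading interval below the
#' first minimum is lobe 1 even when truncated by a low-qz data cutoff.
#'
#' @param ff A [form_factor()].
#' @param minimum_threshold_fraction Fraction of the global maximum below
#'   which a local minimum qualifies (default 0.2).
#' @return A `lobe_structure` list with `minima_qz` and `lobe_intervals`
#'   (list of `c(lo, hi)` qz intervals).
#' @export
find_lobes <- function(ff, minimum_threshold_fraction = 0.2) {
  stopifnot(inherits(ff, "form_factor"))
  a <- ff$amplitude
  n <- length(a)
  if (n < 3L) stop("form factor too short to contain minima")
  is_min <- which(a[2:(n - 1)] <= a[1:(n - 2)] & a[2:(n - 1)] < a[3:n]) + 1L
  qual <- is_min[a[is_min] < minimum_threshold_fraction * max(a)]
  if (length(qual) < 2L) {
    stop(sprintf("found %d qualifying minima; at least 2 required",
                 length(qual)))
  }
  mq <- ff$qz[qual]
  bounds <- c(ff$qz[1], mq, ff$qz[n])
  lobes <- lapply(seq_len(length(bounds) - 1L),
                  function(i) c(bounds[i], bounds[i + 1]))
  structure(list(minima_qz = mq, lobe_intervals = lobes),
            class = "lobe_structure")
}

#' @export
print.lobe_structure <- function(x, ...) {
  cat(sprintf("<lobe_structure> %d lobes; minima at %s 1/A\n",
              length(x$lobe_intervals),
              paste(sprintf("%.3f", x$minima_qz), collapse = ", ")))
  invisible(x)
}

#' Normalize an experimental form factor to its second lobe
#'
#' Scales the amplitudes so the maximum value in lobe 2 equals one, then
#' assigns the per-point uncertainty Delta = 0.05 for qz < 0.6 1/Angstrom
#' and 0.1 for qz >= 0.6 (in lobe-2-normalized units).
#'
#' @param ff A [form_factor()].
#' @param minimum_threshold_fraction Passed to [find_lobes()].
#' @param qz_break,delta_low,delta_high The Delta assignment rule.
#' @return A [form_factor()] with `scale_status = "lobe2_normalized"` and
#'   `delta` populated.
#' @export
normalize_experimental <- function(ff, minimum_threshold_fraction = 0.2,
                                   qz_break = 0.6, delta_low = 0.05,
                                   delta_high = 0.1) {
  lb <- find_lobes(ff, minimum_threshold_fraction)
  if (length(lb$lobe_intervals) < 2L) stop("need at least 2 lobes")
  l2 <- lb$lobe_intervals[[2]]
  in2 <- ff$qz >= l2[1] & ff$qz <= l2[2]
  m2 <- max(ff$amplitude[in2])
  if (m2 <= 0) stop("lobe 2 maximum is zero; cannot normalize")
  form_factor(ff$qz, ff$amplitude / m2,
              delta = ifelse(ff$qz < qz_break, delta_low, delta_high),
              scale_status = "lobe2_normalized")
}

#' Shift of form-factor minima between two lobe structures
#'
#' Compares minima positions up to the shared count. A mean shift to higher
#' qz indicates bilayer thinning; to lower qz, thickening.
#'
#' @param reference,perturbed [find_lobes()] results.
#' @return List with `delta_qz` (per-minimum shift, perturbed - reference)
#'   and `label` (`"thinning"`, `"thickening"`, or `"none"`).
#' @export
minima_shift <- function(reference, perturbed) {
  stopifnot(inherits(reference, "lobe_structure"),
            inherits(perturbed, "lobe_structure"))
  k <- min(length(reference$minima_qz), length(perturbed$minima_qz))
  if (k == 0L) stop("empty lobe structure")
  d <- perturbed$minima_qz[1:k] - reference$minima_qz[1:k]
  m <- mean(d)
  label <- if (m > 0) "thinning" else if (m < 0) "thickening" else "none"
  list(delta_qz = d, label = label)
}
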