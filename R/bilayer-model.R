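#' Gaussian density component of a bilayer model
#'
#' A symmetric pair of Gaussians at `+/-center` describing the water-excess
#' electron density of one molecular group (headgroup, carbonyl-glycerol,
#' terminal methyl, peptide, ...) projected onto the bilayer normal.
#'
#' @param label Component name, e.g. `"PC-head"`, `"PE-head"`, `"CG"`,
#'   `"CH3"`, `"peptide"`.
#' @param center Distance of the Gaussian center from the bilayer midplane
#'   (Angstrom, >= 0). The component is mirrored at `-center` so its density
#'   is an even function of z; a component at `center = 0` contributes both
#'   mirror copies on top of each other.
#' @param width Gaussian sigma (Angstrom, > 0).
#' @param areal_excess Integrated excess electron density per unit area and
#'   per mirror copy (e/Angstrom^2). May be negative for groups less dense
#'   than their surroundings (e.g. the terminal-methyl trough).
#' @return An object of class `component_gaussian`.
#' @export
component_gaussian <- function(label, center, width, areal_excess) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.finite(center) || center < 0) {
    stop("`center` must be >= 0 (components are mirrored at +/-center)")
  }
  if (!is.finite(width) || width <= 0) {
    stop("`width` must be > 0")
  }
  structure(
    list(label = label, center = center, width = width,
         areal_excess = areal_excess),
    class = "component_gaussian"
  )
}

#' Parametric bilayer electron density model
#'
#' Scattering-density-profile style model of a symmetric lipid bilayer:
#' Gaussian component groups riding on a smoothed hydrocarbon slab, embedded
#' in bulk water. The total electron density is
#' \deqn{\rho(z) = \rho_W + \sum_g g(z) + (\rho_{HC} - \rho_W)\, s(z)}
#' where `s(z)` is an error-function slab of half-width `hc_halfwidth`
#' (the hydrocarbon half-thickness D_C) smoothed over `hc_smoothing`, and the
#' Gaussian terms are water-excess densities. Water itself occupies the
#' volume not taken by the hydrocarbon slab, so the density tends to
#' `water_density` far from the bilayer.
#'
#' @param gaussians List of [component_gaussian()] objects.
#' @param hc_plateau Hydrocarbon (CH2) electron density (e/Angstrom^3, >= 0).
#' @param hc_halfwidth Hydrocarbon half-thickness D_C (Angstrom, > 0).
#' @param hc_smoothing Interfacial error-function width sigma (Angstrom,
#'   >= 0; 0 gives a sharp slab).
#' @param water_density Bulk water electron density (e/Angstrom^3);
#'   0.333 e/A^3 is standard for bulk water near physiological temperature.
#' @param box_halfheight Half the box height Lz/2 (Angstrom).
#' @return An object of class `bilayer_model`.
#' @export
bilayer_model <- function(gaussians = list(), hc_plateau = 0,
                          hc_halfwidth = 1, hc_smoothing = 0,
                          water_density = 0.333, box_halfheight = 35) {
  stopifnot(is.list(gaussians))
  for (g in gaussians) {
    if (!inherits(g, "component_gaussian")) {
      stop("`gaussians` must be a list of component_gaussian objects")
    }
  }
  if (hc_plateau < 0) stop("`hc_plateau` must be >= 0")
  if (hc_halfwidth <= 0) stop("`hc_halfwidth` must be > 0")
  if (hc_smoothing < 0) stop("`hc_smoothing` must be >= 0")
  if (box_halfheight <= hc_halfwidth) {
    stop("`box_halfheight` must exceed the hydrocarbon half-width")
  }
  structure(
    list(gaussians = gaussians, hc_plateau = hc_plateau,
         hc_halfwidth = hc_halfwidth, hc_smoothing = hc_smoothing,
         water_density = water_density, box_halfheight = box_halfheight),
    class = "bilayer_model"
  )
}

#' @export
print.bilayer_model <- function(x, ...) {
  cat("<bilayer_model>\n")
  cat(sprintf("  hydrocarbon: plateau %.3f e/A^3, D_C %.2f A, smoothing %.2f A\n",
              x$hc_plateau, x$hc_halfwidth, x$hc_smoothing))
  cat(sprintf("  water: %.3f e/A^3, box half-height %.1f A\n",
              x$water_density, x$box_halfheight))
  for (g in x$gaussians) {
    cat(sprintf("  %-8s center %6.2f A, sigma %.2f A, areal excess %+.3f e/A^2\n",
                g$label, g$center, g$width, g$areal_excess))
  }
  invisible(x)
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

## Occupancy of the hydrocarbon slab: 1 deep in the core, 0 in water,
## error-function interfaces of width `smoothing` at +/-halfwidth.
slab_shape <- function(z, halfwidth, smoothing) {
  if (smoothing == 0) {
    out <- as.numeric(abs(z) < halfwidth)
    out[abs(z) == halfwidth] <- 0.5
    return(out)
  }
  0.5 * (erf((halfwidth - z) / (sqrt(2) * smoothing)) +
         erf((halfwidth + z) / (sqrt(2) * smoothing)))
}

gaussian_pair_density <- function(z, center, width, areal_excess) {
  areal_excess / (width * sqrt(2 * pi)) *
    (exp(-(z - center)^2 / (2 * width^2)) +
     exp(-(z + center)^2 / (2 * width^2)))
}

#' Uniform z grid spanning a model's box
#'
#' @param model A [bilayer_model()].
#' @param bin_width Bin width in Angstrom.
#' @return Numeric vector of bin centers covering
#'   `[-box_halfheight, box_halfheight]`.
#' @export
density_grid <- function(model, bin_width = 0.25) {
  h <- model$box_halfheight
  n_half <- ceiling(h / bin_width + 0.5)
  pos <- (seq_len(n_half) - 0.5) * bin_width
  c(-rev(pos), pos)   # symmetric about 0, covers [-h, h]
}

#' Evaluate a bilayer model's density profiles on a grid
#'
#' Returns per-component electron density profiles plus the water fill and
#' the total. Water occupies the volume left by the hydrocarbon slab
#' (`water_density * (1 - s(z))`), so the per-component profiles sum to the
#' total and the total tends to `water_density` at the box edges.
#'
#' @param model A [bilayer_model()].
#' @param grid Uniform ascending bin centers spanning the model box.
#' @return Named list of [density_profile()] objects (one per Gaussian
#'   component label, `"CH2"` for the slab, `"water"`, and `"total"`).
#' @export
model_density <- function(model, grid) {
  stopifnot(inherits(model, "bilayer_model"))
  check_uniform_grid(grid)
  dz <- grid[2] - grid[1]
  h <- model$box_halfheight
  if (min(grid) > -h + dz || max(grid) < h - dz) {
    stop("`grid` must span the model box [-box_halfheight, box_halfheight]")
  }
  s <- slab_shape(grid, model$hc_halfwidth, model$hc_smoothing)
  comps <- list()
  for (g in model$gaussians) {
    d <- gaussian_pair_density(grid, g$center, g$width, g$areal_excess)
    if (!is.null(comps[[g$label]])) {
      comps[[g$label]] <- comps[[g$label]] + d
    } else {
      comps[[g$label]] <- d
    }
  }
  comps[["CH2"]] <- model$hc_plateau * s
  comps[["water"]] <- model$water_density * (1 - s)
  total <- Reduce(`+`, comps)
  out <- lapply(names(comps), function(nm) {
    density_profile(grid, comps[[nm]], weighting = "electron",
                    component = nm, n_frames = 1L)
  })
  names(out) <- names(comps)
  out[["total"]] <- density_profile(grid, total, weighting = "electron",
                                    component = "total", n_frames = 1L)
  out
}

#' Closed-form form factor of a bilayer model
#'
#' Analytic continuous cosine transform of the water-subtracted total
#' density:
#' \deqn{F(q_z) = \sum_g 2 a_g e^{-\sigma_g^2 q_z^2/2} \cos(q_z c_g)
#'   + 2 (\rho_{HC} - \rho_W) \frac{\sin(q_z D_C)}{q_z}
#'     e^{-\sigma_s^2 q_z^2/2}}
#' The modulus is returned; `F(0)` equals the total areal electron excess.
#'
#' @param model A [bilayer_model()].
#' @param qz Ascending scattering-vector grid (1/Angstrom, >= 0).
#' @return A [form_factor()] with `scale_status = "absolute"` (units
#'   e/Angstrom^2).
#' @export
model_form_factor <- function(model, qz) {
  stopifnot(inherits(model, "bilayer_model"))
  if (any(qz < 0)) stop("`qz` must be >= 0")
  if (is.unsorted(qz, strictly = TRUE)) stop("`qz` must be strictly ascending")
  f <- model_form_factor_signed(model, qz)
  form_factor(qz, abs(f), scale_status = "absolute")
}

model_form_factor_signed <- function(model, qz) {
  f <- numeric(length(qz))
  for (g in model$gaussians) {
    f <- f + 2 * g$areal_excess * exp(-g$width^2 * qz^2 / 2) *
      cos(qz * g$center)
  }
  dc <- model$hc_halfwidth
  contrast <- model$hc_plateau - model$water_density
  sinc <- ifelse(qz == 0, dc, sin(qz * dc) / qz)
  f + 2 * contrast * sinc * exp(-model$hc_smoothing^2 * qz^2 / 2)
}

#' DOPC:DOPE (1:1) style bilayer model family
#'
#' Candidate-model generator used for grid scans: a mixed-PC/PE bilayer
#' parameterized by area per lipid `A_L` and (optionally) the insertion
#' depth of an arginine-rich peptide. The hydrocarbon half-thickness follows
#' volume conservation, `D_C = V_C / A_L` with a fixed hydrocarbon volume
#' per lipid, so compressing the area thickens the bilayer and vice versa.
#' Headgroup Gaussians ride at a fixed offset above the hydrocarbon
#' interface, with the PC peak 2 Angstrom further from the bilayer center
#' than the PE peak.
#'
#' Default component amplitudes are chosen to give a realistic fluid-phase
#' profile: headgroup maxima near 0.42 e/A^3, a methyl trough near
#' 0.20 e/A^3, and head-to-head spacing near 36.7 A at A_L = 66 A^2.
#'
#' @param A_L Area per lipid (Angstrom^2, > 0).
#' @param peptide_z Peptide center-of-mass distance from the bilayer center
#'   (Angstrom) or `NULL` for a neat bilayer.
#' @param n_peptides Total peptides in the (128-lipid equivalent) system;
#'   determines the peptide component amplitude. 2 and 4 peptides per 128
#'   lipids correspond to mole fractions 0.015 and 0.030.
#' @param n_lipids Number of lipids in the reference system.
#' @param hydrocarbon_volume Hydrocarbon volume per lipid V_C (Angstrom^3);
#'   default chosen so A_L = 66 A^2 gives 2D_C = 29.5 A.
#' @param head_offset Distance from the hydrocarbon interface to the
#'   midpoint of the PC/PE headgroup peaks (Angstrom).
#' @param hc_plateau,hc_smoothing,water_density,box_halfheight See
#'   [bilayer_model()].
#' @param ch3_excess Areal excess of the terminal-methyl component
#'   (e/Angstrom^2); negative values carve the usual central trough. Set to
#'   0 for bead-sampling models, where the methyl beads are drawn from the
#'   slab instead.
#' @param peptide_electron_excess Water-excess electrons per peptide.
#' @return A [bilayer_model()].
#' @export
dopc_dope_model <- function(A_L, peptide_z = NULL, n_peptides = 2,
                            n_lipids = 128,
                            hydrocarbon_volume = 973.5,
                            head_offset = 3.95,
                            hc_plateau = 0.303, hc_smoothing = 2.0,
                            water_density = 0.333, box_halfheight = 36,
                            ch3_excess = -0.28,
                            peptide_electron_excess = 200) {
  if (A_L <= 0) stop("`A_L` must be > 0")
  dc <- hydrocarbon_volume / A_L
  mid <- dc + head_offset
  gaussians <- list(
    component_gaussian("PC-head", mid + 1.0, 2.5, 0.30),
    component_gaussian("PE-head", mid - 1.0, 2.5, 0.30),
    component_gaussian("CG", dc + 0.9, 2.2, 0.12)
  )
  if (ch3_excess != 0) {
    gaussians <- c(gaussians,
                   list(component_gaussian("CH3", 0, 2.2, ch3_excess)))
  }
  if (!is.null(peptide_z)) {
    leaflet_area <- (n_lipids / 2) * A_L
    a_pep <- (n_peptides / 2) * peptide_electron_excess / leaflet_area
    gaussians <- c(gaussians,
                   list(component_gaussian("peptide", abs(peptide_z), 3.0,
                                           a_pep)))
  }
  bilayer_model(gaussians, hc_plateau = hc_plateau, hc_halfwidth = dc,
                hc_smoothing = hc_smoothing, water_density = water_density,
                box_halfheight = box_halfheight)
}

check_uniform_grid <- function(grid, tol = 1e-8) {
  if (length(grid) < 2L) stop("grid must have at least two points")
  d <- diff(grid)
  if (any(d <= 0)) stop("grid must be strictly ascending")
  if (max(d) - min(d) > tol * mean(d)) stop("grid must be uniform")
  invisible(grid)
}
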