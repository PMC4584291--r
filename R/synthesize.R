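## Run code with a private, seeded RNG stream; the caller's RNG state is
## untouched. All randomness in the package flows through explicit seeds.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthesize a noisy, arbitrarily scaled "experimental" form factor
#'
#' Emulates a diffuse-scattering experiment on a known model: the model's
#' closed-form |F(qz)| is perturbed by zero-mean Gaussian noise whose
#' standard deviation follows the Delta error model (`delta_low` below
#' `qz_break`, `delta_high` at or above it) expressed in lobe-2-normalized
#' units, floored at zero, and multiplied by an arbitrary overall scale,
#' mimicking the unknown scale of experimental form factors.
#'
#' @param model A [bilayer_model()].
#' @param qz Ascending qz grid (1/Angstrom).
#' @param noise_seed Integer seed; identical seeds give identical output.
#' @param arbitrary_scale Overall scale factor (> 0).
#' @param qz_break,delta_low,delta_high Noise magnitudes in
#'   lobe-2-normalized units; set both deltas to 0 for a noiseless copy.
#' @return A [form_factor()] with `scale_status = "arbitrary"`; `delta`
#'   records the applied noise standard deviation in output units (absent
#'   for noiseless synthesis).
#' @export
synthesize_experiment <- function(model, qz = default_experimental_qz(),
                                  noise_seed = 1L, arbitrary_scale = 1,
                                  qz_break = 0.6, delta_low = 0.05,
                                  delta_high = 0.1) {
  if (arbitrary_scale <= 0) stop("`arbitrary_scale` must be > 0")
  ffm <- model_form_factor(model, qz)
  if (delta_low == 0 && delta_high == 0) {
    return(form_factor(qz, arbitrary_scale * ffm$amplitude,
                       scale_status = "arbitrary"))
  }
  ## Express the Delta noise model in the model's own units via the lobe-2
  ## maximum, so delta_low/delta_high are meaningful normalized magnitudes.
  lb <- find_lobes(ffm)
  l2 <- lb$lobe_intervals[[2]]
  in2 <- ffm$qz >= l2[1] & ffm$qz <= l2[2]
  m2 <- max(ffm$amplitude[in2])
  delta_norm <- ifelse(qz < qz_break, delta_low, delta_high)
  eps <- with_seed(noise_seed, stats::rnorm(length(qz), 0, delta_norm * m2))
  amp <- arbitrary_scale * pmax(0, ffm$amplitude + eps)
  form_factor(qz, amp, delta = arbitrary_scale * delta_norm * m2,
              scale_status = "arbitrary")
}

#' Generate a toy bead trajectory from a bilayer model
#'
#' Stand-in for an MD trajectory of a peptide-bilayer system: each frame
#' independently samples bead positions from the component densities of a
#' [dopc_dope_model()] family member at the requested area per lipid. Lipid
#' beads (PC/PE headgroup, carbonyl-glycerol, CH2, CH3) are drawn from
#' their component distributions per leaflet, water beads fill the volume
#' outside the hydrocarbon slab, and chloride-like ions sample the water
#' distribution. Peptides are bead clusters whose center of mass sits at
#' `+/-peptide_depth_z` with a per-frame Gaussian jitter of 1 Angstrom,
#' emulating a stiff center-of-mass restraint with ~0.1 nm displacement.
#' An optional single-mode undulation `u(x) = A sin(2 pi x / Lx)` is added
#' to all bead z coordinates.
#'
#' The transverse box is fixed at `Lx * Ly = (n_lipids / 2) * A_L`
#' (constant-area ensemble). Bead electron counts are calibrated so that
#' binned profiles reproduce the generating model's densities
#' (water-excess convention for non-water components).
#'
#' @param config List with elements `n_lipids` (default 128), `n_peptides`
#'   (0), `A_L` (68), `peptide_depth_z` (0), `undulation_amplitude` (0),
#'   `n_ions` (0), `n_frames` (20), and optionally `model` (a
#'   [bilayer_model()] with non-negative component excesses; default
#'   `dopc_dope_model(A_L, ch3_excess = 0)`).
#' @param seed Integer seed; identical seed + config give a bit-identical
#'   trajectory.
#' @return An object of class `toy_trajectory`: list with `frames` (one
#'   data frame of beads per frame), `box` (Lx, Ly, Lz), `metadata`.
#' @export
generate_trajectory <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(
    list(n_lipids = 128L, n_peptides = 0L, A_L = 68,
         peptide_depth_z = 0, undulation_amplitude = 0,
         n_ions = 0L, n_frames = 20L, model = NULL),
    config)
  if (cfg$A_L <= 0) stop("`A_L` must be > 0")
  if (cfg$undulation_amplitude < 0) stop("`undulation_amplitude` must be >= 0")
  if (cfg$n_lipids < 2L || cfg$n_lipids %% 2L != 0L) {
    stop("`n_lipids` must be a positive even number")
  }
  if (cfg$n_peptides %% 2L != 0L) {
    stop("`n_peptides` must be even (half per leaflet)")
  }
  model <- cfg$model
  if (is.null(model)) model <- dopc_dope_model(cfg$A_L, ch3_excess = 0)
  for (g in model$gaussians) {
    if (g$areal_excess < 0) {
      stop("bead sampling requires non-negative component excesses; ",
           "use e.g. dopc_dope_model(A_L, ch3_excess = 0)")
    }
  }
  area <- (cfg$n_lipids / 2) * cfg$A_L
  lxy <- sqrt(area)
  lz <- 2 * model$box_halfheight
  half <- cfg$n_lipids / 2L

  ## Electrons per leaflet for each Gaussian component; split over beads.
  lip_per_leaflet <- vapply(model$gaussians, function(g) g$areal_excess * area,
                            numeric(1))
  labels <- vapply(model$gaussians, `[[`, character(1), "label")

  ## Hydrocarbon slab: fine grid for inverse-CDF sampling, kept strictly
  ## inside the box so sampled beads never spill across the periodic edge.
  zg <- density_grid(model, 0.1)
  zg <- zg[abs(zg) <= model$box_halfheight - 0.05 + 1e-9]
  s <- slab_shape(zg, model$hc_halfwidth, model$hc_smoothing)
  slab_e_total <- model$hc_plateau * area * sum(s) * 0.1
  water_w <- model$water_density * (1 - s)
  water_e_total <- area * sum(water_w) * 0.1
  n_water <- max(1L, round(water_e_total / 10))

  sample_from_weights <- function(n, weights, grid, dz) {
    idx <- sample.int(length(grid), n, replace = TRUE, prob = weights)
    grid[idx] + stats::runif(n, -dz / 2, dz / 2)
  }

  pep_per_leaflet <- cfg$n_peptides / 2L
  pep_beads <- 11L
  pep_e <- 200 / pep_beads   # water-excess electrons per peptide bead

  frames <- with_seed(seed, lapply(seq_len(cfg$n_frames), function(fi) {
    bead_x <- c(); bead_y <- c(); bead_z <- c()
    bead_e <- c(); bead_comp <- c(); bead_leaf <- c(); bead_mol <- c()

    add <- function(n, z, e, comp, leaflet, mol = NA_integer_,
                    x = stats::runif(n, 0, lxy), y = stats::runif(n, 0, lxy)) {
      bead_x <<- c(bead_x, x); bead_y <<- c(bead_y, y); bead_z <<- c(bead_z, z)
      bead_e <<- c(bead_e, rep(e, length.out = n))
      bead_comp <<- c(bead_comp, rep(comp, length.out = n))
      bead_leaf <<- c(bead_leaf, rep(leaflet, length.out = n))
      bead_mol <<- c(bead_mol, rep(mol, length.out = n))
    }

    ## Gaussian lipid components: one bead per lipid per component, per
    ## leaflet, at +/-center with the component's sigma. Peptide components
    ## are realized as explicit bead clusters below, not per-lipid beads.
    for (k in seq_along(model$gaussians)) {
      g <- model$gaussians[[k]]
      if (lip_per_leaflet[k] == 0 || g$label == "peptide") next
      for (lf in c("upper", "lower")) {
        sgn <- if (lf == "upper") 1 else -1
        n <- half
        add(n, sgn * g$center + stats::rnorm(n, 0, g$width),
            lip_per_leaflet[k] / n, g$label, lf)
      }
    }
    ## Hydrocarbon slab beads: CH2 carries 85% of the slab electrons and
    ## terminal-methyl (CH3) beads the rest; both sample the slab shape so
    ## the combined hydrocarbon histogram reproduces the model slab.
    n_ch2 <- 8L * cfg$n_lipids
    z_ch2 <- sample_from_weights(n_ch2, s, zg, 0.1)
    add(n_ch2, z_ch2, 0.85 * slab_e_total / n_ch2, "CH2",
        ifelse(z_ch2 >= 0, "upper", "lower"))
    n_ch3 <- cfg$n_lipids
    z_ch3 <- sample_from_weights(n_ch3, s, zg, 0.1)
    add(n_ch3, z_ch3, 0.15 * slab_e_total / n_ch3, "CH3",
        ifelse(z_ch3 >= 0, "upper", "lower"))
    ## Water fill outside the slab.
    z_w <- sample_from_weights(n_water, water_w, zg, 0.1)
    add(n_water, z_w, water_e_total / n_water, "water", "none")
    ## Ions ride the water distribution.
    if (cfg$n_ions > 0L) {
      z_i <- sample_from_weights(cfg$n_ions, water_w, zg, 0.1)
      add(cfg$n_ions, z_i, 18, "ion", "none")
    }
    ## Peptides: per-frame center-of-mass jitter sigma = 1 A about the
    ## restrained depth; bead spread sigma = sqrt(8) A so the time-averaged
    ## cluster density has sigma 3 A, matching the model peptide component.
    if (cfg$n_peptides > 0L) {
      for (p in seq_len(cfg$n_peptides)) {
        lf <- if (p <= pep_per_leaflet) "upper" else "lower"
        sgn <- if (lf == "upper") 1 else -1
        com <- sgn * cfg$peptide_depth_z + stats::rnorm(1, 0, 1)
        cx <- stats::runif(1, 0, lxy); cy <- stats::runif(1, 0, lxy)
        add(pep_beads, com + stats::rnorm(pep_beads, 0, sqrt(8)), pep_e,
            "peptide", lf, mol = p,
            x = (cx + stats::rnorm(pep_beads, 0, 3)) %% lxy,
            y = (cy + stats::rnorm(pep_beads, 0, 3)) %% lxy)
      }
    }
    ## Thermal undulation: one sinusoidal mode along x whose amplitude
    ## fluctuates frame to frame (Gaussian with the configured RMS) with a
    ## random phase, as for a thermally excited bending mode. The resulting
    ## smearing of the density profile is strictly monotone in the RMS
    ## amplitude at every qz.
    if (cfg$undulation_amplitude > 0) {
      a_f <- stats::rnorm(1, 0, cfg$undulation_amplitude)
      phi <- stats::runif(1, 0, 2 * pi)
      bead_z <- bead_z + a_f * sin(2 * pi * bead_x / lxy + phi)
    }
    data.frame(x = bead_x, y = bead_y, z = bead_z, electrons = bead_e,
               mass = 1.8 * bead_e, component = bead_comp,
               leaflet = bead_leaf, molecule = bead_mol,
               stringsAsFactors = FALSE)
  }))

  structure(
    list(frames = frames, box = c(Lx = lxy, Ly = lxy, Lz = lz),
         metadata = list(
           A_L = cfg$A_L, n_lipids = cfg$n_lipids,
           n_peptides = cfg$n_peptides,
           peptide_depth_z = cfg$peptide_depth_z,
           mole_fraction_x = cfg$n_peptides /
             (cfg$n_lipids + cfg$n_peptides),
           undulation_amplitude = cfg$undulation_amplitude,
           n_ions = cfg$n_ions, seed = seed)),
    class = "toy_trajectory"
  )
}

#' @export
print.toy_trajectory <- function(x, ...) {
  m <- x$metadata
  cat(sprintf(paste0("<toy_trajectory> %d frames, %d lipids, %d peptide(s), ",
                     "A_L %.1f A^2, box %.1f x %.1f x %.1f A\n"),
              length(x$frames), m$n_lipids, m$n_peptides, m$A_L,
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}
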