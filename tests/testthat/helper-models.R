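# Shared fixtures: all built in code, deterministic under explicit seeds.

# A single mirrored headgroup Gaussian on a transparent background
# (no slab contrast, no water): F(qz) = 2a exp(-s^2 qz^2 / 2) cos(qz c).
gaussian_pair_model <- function(center = 18, sigma = 3, a = 10,
                                box = 60) {
  bilayer_model(list(component_gaussian("PC-head", center, sigma, a)),
                hc_plateau = 0, hc_halfwidth = 1, hc_smoothing = 0,
                water_density = 0, box_halfheight = box)
}

# A bare hydrocarbon slab (no Gaussians): F(qz) = 2 dp sin(qz Dc)/qz.
slab_model <- function(dc = 14, contrast = -0.1, smoothing = 0,
                       box = 40) {
  bilayer_model(list(), hc_plateau = 0.333 + contrast, hc_halfwidth = dc,
                hc_smoothing = smoothing, water_density = 0.333,
                box_halfheight = box)
}

# Random Gaussian + smoothed-slab models for oracle tests. Components stay
# well inside the box (>= 8 sigma margin) so trapezoid quadrature of the
# smooth profile is accurate far beyond the comparison tolerance.
random_model <- function() {
  n_g <- sample(1:3, 1)
  dc <- runif(1, 10, 16)
  gaussians <- lapply(seq_len(n_g), function(i) {
    component_gaussian(paste0("G", i),
                       center = runif(1, dc, dc + 8),
                       width = runif(1, 1.5, 4),
                       areal_excess = runif(1, 0.05, 0.5))
  })
  if (runif(1) < 0.5) {
    gaussians <- c(gaussians,
                   list(component_gaussian("CH3", 0, runif(1, 1.5, 3),
                                           -runif(1, 0.05, 0.3))))
  }
  bilayer_model(gaussians,
                hc_plateau = runif(1, 0.25, 0.32),
                hc_halfwidth = dc,
                hc_smoothing = runif(1, 1, 3),
                water_density = 0.333,
                box_halfheight = dc + 8 + 8 * 4)
}

# Hand-built trajectory wrapper: frames must carry hydrocarbon beads so
# recentering is defined.
manual_trajectory <- function(frames, lx = 66, ly = 66, lz = 72,
                              metadata = list()) {
  structure(list(frames = frames, box = c(Lx = lx, Ly = ly, Lz = lz),
                 metadata = metadata),
            class = "toy_trajectory")
}

bead_frame <- function(z, electrons = 1, mass = electrons * 1.8,
                       component = "CH2", leaflet = "none",
                       molecule = NA_integer_, x = 0, y = 0) {
  data.frame(x = rep(x, length.out = length(z)),
             y = rep(y, length.out = length(z)), z = z,
             electrons = rep(electrons, length.out = length(z)),
             mass = rep(mass, length.out = length(z)),
             component = rep(component, length.out = length(z)),
             leaflet = rep(leaflet, length.out = length(z)),
             molecule = rep(molecule, length.out = length(z)),
             stringsAsFactors = FALSE)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
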