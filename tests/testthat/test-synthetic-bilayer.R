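test_that("model density reduces to uniform water when contrast vanishes", {
  m <- bilayer_model(list(), hc_plateau = 0.333, hc_halfwidth = 10,
                     hc_smoothing = 0, water_density = 0.333,
                     box_halfheight = 30)
  prof <- model_density(m, density_grid(m, 0.25))
  expect_equal(prof$total$values, rep(0.333, length(prof$total$bin_centers)))
  ff <- model_form_factor(m, default_qz_grid())
  expect_equal(ff$amplitude, rep(0, length(ff$qz)))
})

test_that("a mirrored Gaussian integrates to twice its areal excess and is symmetric", {
  m <- gaussian_pair_model(center = 18, sigma = 3, a = 10)
  g <- density_grid(m, 0.05)
  prof <- model_density(m, g)
  expect_equal(trapz(g, prof$total$values), 20, tolerance = 1e-6)
  pk <- peak_density(prof$total)
  expect_equal(abs(pk$z), 18, tolerance = 0.05)
  # total is even in z for any model
  for (mod in list(m, dopc_dope_model(68, peptide_z = 18))) {
    tot <- model_density(mod, density_grid(mod, 0.25))$total$values
    expect_equal(tot, rev(tot))
  }
})

test_that("per-component profiles sum to the total and far field equals water", {
  m <- dopc_dope_model(66)
  g <- density_grid(m, 0.25)
  prof <- model_density(m, g)
  comps <- prof[setdiff(names(prof), "total")]
  summed <- Reduce(`+`, lapply(comps, `[[`, "values"))
  expect_equal(summed, prof$total$values, tolerance = 1e-12)
  edge <- prof$total$values[c(1, length(g))]
  expect_equal(edge, c(0.333, 0.333), tolerance = 1e-6)
})

test_that("closed-form Gaussian-pair and slab form factors match analytics", {
  qz <- default_qz_grid()
  gp <- model_form_factor(gaussian_pair_model(18, 3, 10), qz)
  expect_equal(gp$amplitude, abs(20 * exp(-4.5 * qz^2) * cos(18 * qz)),
               tolerance = 1e-12)
  sl <- model_form_factor(slab_model(dc = 14, contrast = -0.1), qz)
  expect_equal(sl$amplitude, abs(2 * -0.1 * ifelse(qz == 0, 14,
                                                   sin(14 * qz) / qz)),
               tolerance = 1e-12)
  # F(0) is the total areal electron excess
  m <- dopc_dope_model(68, peptide_z = 18)
  f0 <- model_form_factor(m, c(0, 0.1))$amplitude[1]
  excess <- sum(vapply(m$gaussians, function(g) 2 * g$areal_excess,
                       numeric(1))) +
    2 * m$hc_halfwidth * (m$hc_plateau - m$water_density)
  expect_equal(f0, abs(excess), tolerance = 1e-12)
})

test_that("grid must span the model box", {
  m <- dopc_dope_model(68)
  expect_error(model_density(m, seq(-10, 10, by = 0.25)), "span")
})

test_that("noiseless synthesis at unit scale reproduces the model form factor", {
  m <- dopc_dope_model(68, peptide_z = 18)
  qz <- default_experimental_qz()
  out <- synthesize_experiment(m, qz, noise_seed = 5, arbitrary_scale = 1,
                               delta_low = 0, delta_high = 0)
  expect_equal(out$amplitude, model_form_factor(m, qz)$amplitude)
  expect_null(out$delta)
  expect_error(synthesize_experiment(m, qz, arbitrary_scale = 0), "> 0")
})

test_that("synthesis is seeded and reproducible", {
  m <- dopc_dope_model(68, peptide_z = 18)
  a <- synthesize_experiment(m, noise_seed = 11, arbitrary_scale = 3)
  b <- synthesize_experiment(m, noise_seed = 11, arbitrary_scale = 3)
  c <- synthesize_experiment(m, noise_seed = 12, arbitrary_scale = 3)
  expect_identical(a$amplitude, b$amplitude)
  expect_false(identical(a$amplitude, c$amplitude))
})

test_that("synthesis noise magnitude follows the Delta model", {
  m <- dopc_dope_model(68, peptide_z = 18)
  qz <- seq(0.1, 0.78, length.out = 1000)
  amp_model <- model_form_factor(m, qz)$amplitude
  # pool residuals over realizations; restrict to points far from |F| = 0
  # where the zero floor never clips the Gaussian noise
  res_low <- c(); res_high <- c()
  for (s in 1:5) {
    out <- synthesize_experiment(m, qz, noise_seed = 40 + s,
                                 arbitrary_scale = 2)
    resid <- out$amplitude / 2 - amp_model
    sd_low <- unique(out$delta[qz < 0.6]) / 2
    sd_high <- unique(out$delta[qz >= 0.6]) / 2
    res_low <- c(res_low, resid[qz < 0.6 & amp_model > 3 * sd_low])
    res_high <- c(res_high, resid[qz >= 0.6 & amp_model > 3 * sd_high])
  }
  expect_gt(length(res_low), 1000)
  expect_gt(length(res_high), 200)
  expect_lt(abs(sd(res_low) - sd_low), 0.1 * sd_low)
  expect_lt(abs(sd(res_high) - sd_high), 0.1 * sd_high)
  # the recorded uncertainties themselves follow the 0.6 threshold rule
  expect_equal(sd_high / sd_low, 2)
})

test_that("trajectory metadata honors box-area and mole-fraction invariants", {
  tr <- generate_trajectory(list(n_lipids = 128L, n_peptides = 2L,
                                 A_L = 68, n_frames = 2L), seed = 1)
  expect_equal(tr$box[["Lx"]] * tr$box[["Ly"]], 64 * 68)
  expect_equal(tr$metadata$mole_fraction_x, 2 / 130)
  expect_equal(round(tr$metadata$mole_fraction_x, 3), 0.015)
  tr4 <- generate_trajectory(list(n_lipids = 128L, n_peptides = 4L,
                                  A_L = 68, n_frames = 1L), seed = 1)
  expect_equal(round(tr4$metadata$mole_fraction_x, 3), 0.030)
})

test_that("identical seed and config give a bit-identical trajectory", {
  cfg <- list(n_lipids = 16L, A_L = 68, n_frames = 3L, n_ions = 2L)
  a <- generate_trajectory(cfg, seed = 9)
  b <- generate_trajectory(cfg, seed = 9)
  expect_identical(a, b)
  c <- generate_trajectory(cfg, seed = 10)
  expect_false(identical(a$frames[[1]]$z, c$frames[[1]]$z))
})

test_that("flat trajectories place headgroup peaks at the model centers", {
  model <- dopc_dope_model(68, ch3_excess = 0)
  tr <- generate_trajectory(list(n_lipids = 128L, A_L = 68,
                                 undulation_amplitude = 0,
                                 n_frames = 40L, model = model), seed = 2)
  prof <- bin_density(tr, bin_width = 0.5, equilibration_fraction = 0)
  pc <- symmetrize_profile(prof[["PC-head"]])
  pk <- peak_density(pc)
  expect_equal(abs(pk$z), model$gaussians[[1]]$center, tolerance = 0.5)
})

test_that("trajectory generation rejects invalid configurations", {
  expect_error(generate_trajectory(list(A_L = -1)), "A_L")
  expect_error(generate_trajectory(list(undulation_amplitude = -2)),
               "undulation")
  expect_error(generate_trajectory(list(n_peptides = 3L)), "even")
})

test_that("trajectory histograms converge to the generating model density", {
  model <- dopc_dope_model(68, ch3_excess = 0)
  tr <- generate_trajectory(list(n_lipids = 128L, A_L = 68,
                                 n_frames = 60L, model = model), seed = 4)
  prof <- bin_density(tr, bin_width = 0.5, equilibration_fraction = 0)
  tot <- symmetrize_profile(prof$total)
  ref <- model_density(model, tot$bin_centers)$total
  peak <- max(ref$values)
  expect_lt(max(abs(tot$values - ref$values)), 0.05 * peak)
})
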