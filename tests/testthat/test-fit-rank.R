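aligned_pair <- function(exp_amp, sim_amp, delta = 0.05) {
  qz <- seq(0.1, by = 0.05, length.out = length(exp_amp))
  list(exp = form_factor(qz, exp_amp, delta = rep(delta, length(qz)),
                         scale_status = "lobe2_normalized"),
       sim = form_factor(qz, sim_amp, scale_status = "absolute"))
}

test_that("linear interpolation onto experimental qz is exact where expected", {
  sim <- form_factor(c(0.1, 0.2), c(1.0, 2.0), scale_status = "absolute")
  expect_equal(interpolate_to_experiment(sim, 0.15)$amplitude, 1.5)
  grid <- form_factor(seq(0.1, 0.5, 0.1), c(1, 2, 3, 2, 1),
                      scale_status = "absolute")
  same <- interpolate_to_experiment(grid, grid$qz)
  expect_equal(same$amplitude, grid$amplitude)
  expect_error(interpolate_to_experiment(grid, c(0.3, 0.9)), "0.9")
})

test_that("the weighted scale factor matches hand evaluation", {
  p <- aligned_pair(c(1.0, 0.5), c(0.8, 0.6))
  expect_equal(scale_factor(p$exp, p$sim), 1.1, tolerance = 1e-12)
  expect_equal(scale_factor(p$exp, p$exp), 1)
  double <- aligned_pair(c(1.0, 0.5), c(2.0, 1.0))
  expect_equal(scale_factor(double$exp, double$sim), 0.5)
  zero <- aligned_pair(c(1, 1), c(0, 0))
  expect_error(scale_factor(zero$exp, zero$sim), "zero")
})

test_that("chi-square matches hand evaluation and N-1 scaling", {
  p <- aligned_pair(c(1.0, 0.5), c(0.8, 0.6))
  fit <- chi_squared(p$exp, p$sim)
  expect_equal(fit$a_sim, 1.1, tolerance = 1e-12)
  expect_equal(fit$residuals, c(0.12, -0.16), tolerance = 1e-12)
  expect_equal(fit$chi2, 16, tolerance = 1e-12)
  expect_equal(chi_squared(p$exp, p$sim, variant = "root")$chi2, 4,
               tolerance = 1e-12)
  # duplicating every point rescales chi2 by 2(N-1)/(2N-1)
  pd <- aligned_pair(rep(c(1.0, 0.5), 2), rep(c(0.8, 0.6), 2))
  n <- 2
  expect_equal(chi_squared(pd$exp, pd$sim)$chi2,
               fit$chi2 * 2 * (n - 1) / (2 * n - 1), tolerance = 1e-12)
})

test_that("chi-square is invariant to simulation scale and zero for proportional data", {
  m <- dopc_dope_model(68, peptide_z = 18)
  exp_ff <- normalize_experimental(
    synthesize_experiment(m, noise_seed = 2, arbitrary_scale = 4))
  sim <- interpolate_to_experiment(model_form_factor(m, default_qz_grid()),
                                   exp_ff$qz)
  base <- chi_squared(exp_ff, sim)$chi2
  for (c_ in c(0.1, 10)) {
    scaled <- form_factor(sim$qz, c_ * sim$amplitude,
                          scale_status = "absolute")
    expect_lt(abs(chi_squared(exp_ff, scaled)$chi2 - base) / base, 1e-10)
  }
  prop <- form_factor(exp_ff$qz, 0.37 * exp_ff$amplitude,
                      scale_status = "absolute")
  expect_lt(chi_squared(exp_ff, prop)$chi2, 1e-20)
})

test_that("chi-square is invariant under joint rescaling of experiment and Delta", {
  p <- aligned_pair(c(1.0, 0.5, 0.8), c(0.8, 0.6, 0.7))
  base <- chi_squared(p$exp, p$sim)$chi2
  scaled_exp <- form_factor(p$exp$qz, 3.7 * p$exp$amplitude,
                            delta = 3.7 * p$exp$delta,
                            scale_status = "arbitrary")
  expect_equal(chi_squared(scaled_exp, p$sim)$chi2, base, tolerance = 1e-12)
})

test_that("chi-square agrees with brute-force evaluation on random instances", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(2:10, 1)
    e <- runif(n, 0.1, 2)
    s <- runif(n, 0.1, 2)
    d <- runif(n, 0.01, 0.2)
    qz <- sort(runif(n, 0.05, 0.8))
    while (any(diff(qz) == 0)) qz <- sort(runif(n, 0.05, 0.8))
    exp_ff <- form_factor(qz, e, delta = d, scale_status = "arbitrary")
    sim_ff <- form_factor(qz, s, scale_status = "absolute")
    w <- 1 / d^2
    a <- sum(w * e * s) / sum(w * s^2)
    chi2 <- sum(((e - a * s) / d)^2) / (n - 1)
    fit <- chi_squared(exp_ff, sim_ff)
    expect_equal(fit$a_sim, a, tolerance = 1e-12)
    expect_equal(fit$chi2, chi2, tolerance = 1e-12)
  }
})

test_that("display scaling follows the best-fit convention and preserves chi2", {
  m1 <- dopc_dope_model(68, peptide_z = 18)
  m2 <- dopc_dope_model(72, peptide_z = 8)
  exp_ff <- normalize_experimental(
    synthesize_experiment(m1, noise_seed = 6, arbitrary_scale = 7))
  sims <- lapply(list(m1, m2), function(m) {
    interpolate_to_experiment(model_form_factor(m, default_qz_grid()),
                              exp_ff$qz)
  })
  fits <- lapply(sims, function(s) chi_squared(exp_ff, s))
  disp <- scale_for_display(fits, sims, exp_ff)
  expect_equal(disp$best, 1L)
  # best simulation untouched, experiment divided by its a_sim
  expect_equal(disp$simulations[[1]]$amplitude, sims[[1]]$amplitude)
  expect_equal(disp$experiment$amplitude,
               exp_ff$amplitude / fits[[1]]$a_sim)
  # other simulations multiplied by a_sim / a_sim(best)
  r <- fits[[2]]$a_sim / fits[[1]]$a_sim
  expect_equal(disp$simulations[[2]]$amplitude, r * sims[[2]]$amplitude)
  # chi2 of (rescaled experiment, best sim) with rescaled Delta is unchanged
  refit <- chi_squared(disp$experiment, disp$simulations[[1]])
  expect_equal(refit$chi2, fits[[1]]$chi2, tolerance = 1e-10)
  # single-simulation case
  one <- scale_for_display(fits[1], sims[1], exp_ff)
  expect_equal(one$experiment$amplitude,
               exp_ff$amplitude / fits[[1]]$a_sim)
  expect_equal(one$simulations[[1]]$amplitude, sims[[1]]$amplitude)
})

test_that("repeat summaries report sample statistics with N-1 denominator", {
  s <- summarize_repeats(c(2, 4, 6))
  expect_equal(s[c("mean", "sd", "min", "max", "n")],
               list(mean = 4, sd = 2, min = 2, max = 6, n = 3L))
  expect_equal(summarize_repeats(c(3, 3, 3))$sd, 0)
  one <- summarize_repeats(2.8)
  expect_equal(one$mean, 2.8)
  expect_equal(one$sd, 0)
  expect_equal(one$min, one$max)
  expect_error(summarize_repeats(numeric(0)), "empty")
})

test_that("the scan recovers a self-synthesized experiment exactly", {
  truth <- dopc_dope_model(68, peptide_z = 18, n_peptides = 2)
  exp_ff <- normalize_experimental(
    synthesize_experiment(truth, noise_seed = 1, arbitrary_scale = 3,
                          delta_low = 0, delta_high = 0))
  cand <- candidate_grid(n_peptides = 2,
                         A_L_values = c(64, 68, 72),
                         z_values = c(8, 18))
  scan <- scan_grid(exp_ff, cand)
  expect_equal(scan$best_cell$z, 18)
  expect_equal(scan$best_cell$A_L, 68)
  self <- scan$cells[scan$cells$z == 18 & scan$cells$A_L == 68, ]
  expect_lt(self$chi2, 1e-10)
  expect_error(scan_grid(exp_ff, cand[0, ]), "empty")
})

test_that("the acceptance cutoff is inclusive", {
  truth <- dopc_dope_model(68, peptide_z = 18)
  exp_ff <- normalize_experimental(
    synthesize_experiment(truth, noise_seed = 4, arbitrary_scale = 2))
  cand <- candidate_grid(A_L_values = 68, z_values = 18)
  chi2 <- scan_grid(exp_ff, cand)$cells$chi2[1]
  at <- scan_grid(exp_ff, cand, cutoff = chi2)
  expect_true(at$cells$accepted[1])
  below <- scan_grid(exp_ff, cand, cutoff = chi2 * (1 - 1e-9))
  expect_false(below$cells$accepted[1])
})

test_that("best-cell ties break toward smaller z then smaller A_L", {
  qz <- seq(0.1, 0.5, by = 0.05)
  exp_ff <- form_factor(qz, rep(1, length(qz)),
                        delta = rep(0.05, length(qz)),
                        scale_status = "lobe2_normalized")
  flat <- form_factor(qz, rep(2, length(qz)), scale_status = "absolute")
  cand <- tibble::tibble(z = c(18, 8, 8), A_L = c(68, 72, 62),
                         replicate = 1L, ff = list(flat, flat, flat))
  scan <- scan_grid(exp_ff, cand)
  expect_equal(scan$best_cell$z, 8)
  expect_equal(scan$best_cell$A_L, 62)
})
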