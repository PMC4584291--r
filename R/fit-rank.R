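#' Interpolate a simulation form factor onto experimental qz points
#'
#' Linear interpolation of |F(qz)| so simulation and experiment share the
#' same qz values. Extrapolation is refused.
#'
#' @param sim A [form_factor()].
#' @param exp_qz Target qz values, within the simulation's qz range.
#' @return A [form_factor()] on `exp_qz` (same scale status as `sim`).
#' @export
interpolate_to_experiment <- function(sim, exp_qz) {
  stopifnot(inherits(sim, "form_factor"))
  out_of_range <- exp_qz < min(sim$qz) | exp_qz > max(sim$qz)
  if (any(out_of_range)) {
    stop(sprintf("extrapolation required at qz = %s (simulation range [%g, %g])",
                 paste(format(exp_qz[out_of_range]), collapse = ", "),
                 min(sim$qz), max(sim$qz)))
  }
  amp <- stats::approx(sim$qz, sim$amplitude, xout = exp_qz)$y
  form_factor(exp_qz, amp, scale_status = sim$scale_status)
}

check_aligned <- function(exp, sim) {
  stopifnot(inherits(exp, "form_factor"), inherits(sim, "form_factor"))
  if (length(exp$qz) != length(sim$qz) ||
      max(abs(exp$qz - sim$qz)) > 1e-9) {
    stop("experiment and simulation must share the same qz points; ",
         "use interpolate_to_experiment() first")
  }
  if (is.null(exp$delta)) {
    stop("experimental form factor has no delta; apply normalize_experimental()")
  }
  invisible(TRUE)
}

#' Weighted least-squares scale factor between simulation and experiment
#'
#' The per-simulation scale factor mapping simulated onto experimental
#' amplitudes,
#' \deqn{a^{sim} = \frac{\sum_i w_i |F^{exp}_i| |F^{sim}_i|}
#'                      {\sum_i w_i |F^{sim}_i|^2}, \quad w_i = 1/\Delta_i^2,}
#' i.e. the minimizer of the weighted squared deviation.
#'
#' @param exp Experimental [form_factor()] with `delta` set.
#' @param sim Simulation [form_factor()] on the same qz points.
#' @return The scale factor (dimensionless).
#' @export
scale_factor <- function(exp, sim) {
  check_aligned(exp, sim)
  if (all(sim$amplitude == 0)) stop("all simulation amplitudes are zero")
  w <- 1 / exp$delta^2
  sum(w * exp$amplitude * sim$amplitude) / sum(w * sim$amplitude^2)
}

#' Goodness of fit between experimental and simulated form factors
#'
#' Reduced chi-square with the scale factor from [scale_factor()] absorbed:
#' \deqn{\chi^2 = \frac{1}{N-1} \sum_i
#'   \left(\frac{|F^{exp}_i| - a^{sim} |F^{sim}_i|}{\Delta_i}\right)^2.}
#' `variant = "root"` returns the square root of this quantity instead, as
#' a sensitivity check on the statistic's definition.
#'
#' @param exp Experimental [form_factor()] with `delta` set.
#' @param sim Simulation [form_factor()] on the same qz points.
#' @param variant `"squared"` (default) or `"root"`.
#' @return A `fit_result` list: `a_sim`, `chi2`, `n_points`, `residuals`
#'   (raw, experiment minus scaled simulation) and `weighted_residuals`
#'   (divided by Delta).
#' @export
chi_squared <- function(exp, sim, variant = c("squared", "root")) {
  variant <- match.arg(variant)
  check_aligned(exp, sim)
  n <- length(exp$qz)
  if (n < 2L) stop("need at least 2 points (N - 1 denominator)")
  a <- scale_factor(exp, sim)
  resid <- exp$amplitude - a * sim$amplitude
  wres <- resid / exp$delta
  chi2 <- sum(wres^2) / (n - 1)
  if (variant == "root") chi2 <- sqrt(chi2)
  structure(list(a_sim = a, chi2 = chi2, n_points = n,
                 residuals = resid, weighted_residuals = wres),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> chi^2 = %.4g, a_sim = %.4g, N = %d\n",
              x$chi2, x$a_sim, x$n_points))
  invisible(x)
}

#' Scale form factors for joint display
#'
#' Plotting convention for comparing simulations and experiment on an
#' absolute scale: the best-fitting simulation (lowest chi-square) keeps
#' its absolute units, the experiment is multiplied by `1/a_sim(best)`, and
#' every other simulation by `a_sim/a_sim(best)`.
#'
#' @param fits List of `fit_result` objects (one per simulation).
#' @param sims List of simulation [form_factor()]s, same order.
#' @param exp The experimental [form_factor()].
#' @return List with `experiment` (rescaled, delta rescaled too),
#'   `simulations` (rescaled list), and `best` (index of the best fit).
#' @export
scale_for_display <- function(fits, sims, exp) {
  if (length(fits) == 0L || length(fits) != length(sims)) {
    stop("`fits` and `sims` must be non-empty and of equal length")
  }
  chi2s <- vapply(fits, `[[`, numeric(1), "chi2")
  best <- which.min(chi2s)
  a_best <- fits[[best]]$a_sim
  exp_scaled <- form_factor(exp$qz, exp$amplitude / a_best,
                            delta = if (is.null(exp$delta)) NULL
                                    else exp$delta / a_best,
                            scale_status = "absolute")
  sims_scaled <- lapply(seq_along(sims), function(i) {
    if (i == best) return(sims[[i]])
    r <- fits[[i]]$a_sim / a_best
    form_factor(sims[[i]]$qz, r * sims[[i]]$amplitude,
                scale_status = sims[[i]]$scale_status)
  })
  list(experiment = exp_scaled, simulations = sims_scaled, best = best)
}

#' Summary statistics of chi-square values over repeat simulations
#'
#' @param chi2 Numeric vector of chi-square values (length >= 1).
#' @return List with `mean`, `sd` (sample, N-1 denominator; 0 for a single
#'   value), `min`, `max`, `n`.
#' @export
summarize_repeats <- function(chi2) {
  if (length(chi2) == 0L) stop("empty chi-square list")
  list(mean = mean(chi2),
       sd = if (length(chi2) == 1L) 0 else stats::sd(chi2),
       min = min(chi2), max = max(chi2), n = length(chi2))
}

#' Scan candidate models over the (z, A_L) grid
#'
#' Scores every candidate form factor against the experiment with
#' [chi_squared()], aggregates replicates per (z, A_L) cell, flags cells
#' meeting the chi-square acceptance cutoff (inclusive), and reports the
#' best cell by mean chi-square (ties broken toward smaller z, then
#' smaller A_L).
#'
#' @param exp Experimental [form_factor()] with `delta` set.
#' @param candidates A data frame (or tibble) with columns `z`, `A_L`,
#'   `replicate`, and a list column `ff` of simulation [form_factor()]s
#'   spanning the experimental qz range.
#' @param cutoff Chi-square acceptance threshold (default 3.4); cells with
#'   `chi2 <= cutoff` are flagged accepted.
#' @return A `scan_table` list: `cells` (tibble with z, A_L, replicate,
#'   chi2, a_sim, accepted), `summary` (per-cell repeat statistics),
#'   `best_cell` (list z, A_L, mean_chi2), `cutoff`.
#' @export
scan_grid <- function(exp, candidates, cutoff = 3.4) {
  stopifnot(inherits(exp, "form_factor"))
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop("empty candidate set")
  }
  stopifnot(all(c("z", "A_L", "replicate", "ff") %in% names(candidates)))
  fits <- lapply(candidates$ff, function(ff) {
    chi_squared(exp, interpolate_to_experiment(ff, exp$qz))
  })
  cells <- tibble::tibble(
    z = candidates$z, A_L = candidates$A_L,
    replicate = candidates$replicate,
    chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
    a_sim = vapply(fits, `[[`, numeric(1), "a_sim"))
  cells$accepted <- cells$chi2 <= cutoff
  summary <- dplyr::summarise(
    dplyr::group_by(cells, .data$z, .data$A_L),
    mean_chi2 = mean(.data$chi2),
    sd_chi2 = if (dplyr::n() == 1L) 0 else stats::sd(.data$chi2),
    min_chi2 = min(.data$chi2), max_chi2 = max(.data$chi2),
    n = dplyr::n(), .groups = "drop")
  summary <- dplyr::arrange(summary, .data$mean_chi2, .data$z, .data$A_L)
  best <- summary[1, ]
  structure(
    list(cells = cells, summary = summary,
         best_cell = list(z = best$z, A_L = best$A_L,
                          mean_chi2 = best$mean_chi2),
         cutoff = cutoff),
    class = "scan_table"
  )
}

#' @export
print.scan_table <- function(x, ...) {
  cat(sprintf("<scan_table> %d fits over %d (z, A_L) cells, cutoff %.2f\n",
              nrow(x$cells), nrow(x$summary), x$cutoff))
  cat(sprintf("  best: z = %g A, A_L = %g A^2, mean chi^2 = %.3g\n",
              x$best_cell$z, x$best_cell$A_L, x$best_cell$mean_chi2))
  invisible(x)
}

#' Build the standard candidate grid of the depth/area scan
#'
#' Closed-form candidate form factors from the [dopc_dope_model()] family
#' over the standard grid: A_L in {62, 64, ..., 76} Angstrom^2 and peptide
#' depth z in {0, 5, 8, 10, 12, 14, 16, 18} Angstrom.
#'
#' @param n_peptides Peptides per 128 lipids (2 or 4).
#' @param qz Simulation qz grid.
#' @param A_L_values,z_values Grid values.
#' @param replicates Number of replicates per cell (identical closed-form
#'   candidates unless `jitter_sd > 0`).
#' @param jitter_sd Optional Gaussian amplitude noise per replicate (in
#'   absolute units) emulating finite-sampling differences between repeat
#'   simulations; 0 for deterministic candidates.
#' @param seed Seed used when `jitter_sd > 0`.
#' @return Tibble with columns `z`, `A_L`, `replicate`, `ff`.
#' @export
candidate_grid <- function(n_peptides = 2, qz = default_qz_grid(),
                           A_L_values = seq(62, 76, by = 2),
                           z_values = c(0, 5, 8, 10, 12, 14, 16, 18),
                           replicates = 1L, jitter_sd = 0, seed = 1L) {
  grid <- expand.grid(replicate = seq_len(replicates), A_L = A_L_values,
                      z = z_values)
  ffs <- vector("list", nrow(grid))
  base <- list()
  for (i in seq_len(nrow(grid))) {
    key <- sprintf("%g_%g", grid$z[i], grid$A_L[i])
    if (is.null(base[[key]])) {
      base[[key]] <- model_form_factor(
        dopc_dope_model(grid$A_L[i], peptide_z = grid$z[i],
                        n_peptides = n_peptides), qz)
    }
    ffs[[i]] <- base[[key]]
  }
  if (jitter_sd > 0) {
    ffs <- with_seed(seed, lapply(ffs, function(ff) {
      form_factor(ff$qz,
                  pmax(0, ff$amplitude + stats::rnorm(length(ff$qz), 0,
                                                      jitter_sd)),
                  scale_status = ff$scale_status)
    }))
  }
  tibble::tibble(z = grid$z, A_L = grid$A_L, replicate = grid$replicate,
                 ff = ffs)
}
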