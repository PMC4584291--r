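#' Heatmap of mean chi-square over the (z, A_L) scan grid
#'
#' @param scan A `scan_table` from [scan_grid()].
#' @return A ggplot object: tiles colored by mean chi-square with the value
#'   (and replicate standard deviation, when replicates exist) inset.
#' @export
plot_scan_heatmap <- function(scan) {
  stopifnot(inherits(scan, "scan_table"))
  d <- scan$summary
  d$label <- ifelse(d$n > 1L,
                    sprintf("%.1f\n(%.1f)", d$mean_chi2, d$sd_chi2),
                    sprintf("%.1f", d$mean_chi2))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$A_L), y = factor(.data$z),
                                  fill = .data$mean_chi2)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.6) +
    ggplot2::scale_fill_viridis_c(name = expression(chi^2),
                                  direction = -1) +
    ggplot2::labs(x = expression(A[L] ~ (ring(A)^2)),
                  y = "peptide depth z (Å)") +
    ggplot2::theme_minimal()
}

#' Overlay of experimental and simulated form factors
#'
#' Applies the display-scaling convention ([scale_for_display()]) and plots
#' |F(qz)| for the experiment (points with error bars) and each simulation
#' (lines), on the absolute scale of the best-fitting simulation.
#'
#' @param fits,sims,exp As in [scale_for_display()].
#' @param sim_labels Optional labels for the simulations.
#' @return A ggplot object.
#' @export
plot_formfactor_overlay <- function(fits, sims, exp, sim_labels = NULL) {
  disp <- scale_for_display(fits, sims, exp)
  if (is.null(sim_labels)) {
    sim_labels <- paste0("sim ", seq_along(sims))
  }
  sim_d <- do.call(rbind, lapply(seq_along(disp$simulations), function(i) {
    cbind(as.data.frame(disp$simulations[[i]]), which = sim_labels[i])
  }))
  exp_d <- as.data.frame(disp$experiment)
  p <- ggplot2::ggplot() +
    ggplot2::geom_line(data = sim_d,
                       ggplot2::aes(x = .data$qz, y = .data$F,
                                    color = .data$which)) +
    ggplot2::geom_point(data = exp_d,
                        ggplot2::aes(x = .data$qz, y = .data$F),
                        shape = 1, size = 1)
  if (!is.null(disp$experiment$delta)) {
    p <- p + ggplot2::geom_errorbar(
      data = exp_d,
      ggplot2::aes(x = .data$qz, ymin = pmax(0, .data$F - .data$delta),
                   ymax = .data$F + .data$delta),
      linewidth = 0.2)
  }
  p + ggplot2::labs(x = expression(q[z] ~ (ring(A)^-1)),
                    y = expression("|F(" * q[z] * ")| (e/" * ring(A)^2 * ")"),
                    color = NULL) +
    ggplot2::theme_minimal()
}
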