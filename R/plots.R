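# ggplot2 displays for the main result types.

#' Plot posterior coefficient intervals of a fitted collision model
#'
#' @param object A `collision_fit`.
#' @param ... Unused.
#' @return A ggplot: posterior means and 95% credible intervals of the
#'   four collision coefficients.
#' @method autoplot collision_fit
#' @export
autoplot.collision_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)) +
    ggplot2::labs(
      x = "posterior mean and 95% credible interval", y = NULL,
      title = sprintf("Collision-rate coefficients (%s observation model)", object$model)
    )
}

#' Plot a posterior predictive count-frequency table
#'
#' @param object A `ppc_table` from [posterior_predictive_check()].
#' @param ... Unused.
#' @return A ggplot comparing observed frequencies of carcasses found per
#'   search with the posterior predictive median and 95% interval.
#' @method autoplot ppc_table
#' @export
autoplot.ppc_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$k))) +
    ggplot2::geom_pointrange(
      ggplot2::aes(
        y = .data$predicted_median, ymin = .data$predicted_lower,
        ymax = .data$predicted_upper, colour = "predicted"
      )
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$observed, colour = "observed"),
      shape = 4, size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(observed = "black", predicted = "steelblue")) +
    ggplot2::labs(
      x = "carcasses found per search", y = "number of searches", colour = NULL,
      title = "Posterior predictive check"
    )
}

#' Plot estimated-to-true mortality ratios
#'
#' Box plot of the per-turbine estimated/true collision ratios from a
#' simulation study, on a log scale so equal proportional over- and
#' under-estimation look symmetric.  Zero-truth turbines are dropped.
#'
#' @param ratios Output of [bias_ratios()], optionally with a grouping
#'   column `estimator`.
#' @return A ggplot.
#' @export
plot_bias_ratios <- function(ratios) {
  ratios <- filter(ratios, !is.na(.data$ratio))
  grouping <- if ("estimator" %in% names(ratios)) "estimator" else NULL
  p <- ggplot2::ggplot(ratios, ggplot2::aes(
    x = if (is.null(grouping)) "" else .data$estimator, y = .data$ratio
  )) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "estimated / true collisions")
  p
}

#' Plot model vs corrected-count estimates per turbine
#'
#' @param model_estimates Per-turbine `mortality_summary(fit, "turbine")`.
#' @param corrected Per-turbine corrected-count estimates
#'   ([estimate_corrected_per_turbine()] with `mode = "per_turbine"`).
#' @return A ggplot with 95% interval segments and the identity line.
#' @export
plot_model_vs_corrected <- function(model_estimates, corrected) {
  both <- left_join(
    rename(model_estimates,
      model_mean = "mean", model_lower = "lower", model_upper = "upper"
    ),
    rename(corrected,
      cc_mean = "mean", cc_lower = "lower", cc_upper = "upper"
    ),
    by = "turbine"
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$cc_mean, y = .data$model_mean)) +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$model_lower, ymax = .data$model_upper),
      width = 0, colour = "grey60"
    ) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$cc_lower, xmax = .data$cc_upper),
      height = 0, colour = "grey60"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "corrected count (mean, 95% interval)",
      y = "model estimate (mean, 95% interval)"
    )
}
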