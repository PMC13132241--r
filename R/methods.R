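# print / tidy / glance / autoplot for fitted agreement objects

#' @export
print.hr_agreement <- function(x, ...) {
  cat("Repeated-measures Bland-Altman agreement model",
      if (x$with_ar1) "(AR(1) residuals)" else "", "\n", sep = "")
  cat(sprintf("  %d paired epochs from %d participants\n", x$n_epochs, x$n_participants))
  cat(sprintf("  mean bias          %8.3f beats/min  (95%% CI %.3f to %.3f)\n",
              x$mu, x$mu_ci[1], x$mu_ci[2]))
  cat(sprintf("  tau2 (between)     %8.3f   sigma2 (within) %8.3f\n", x$tau2, x$sigma2))
  if (isTRUE(is.finite(x$phi))) cat(sprintf("  phi (AR1)          %8.3f\n", x$phi))
  cat(sprintf("  total SD           %8.3f beats/min\n", x$total_sd))
  cat(sprintf("  95%% LoA            %8.3f to %.3f beats/min\n", x$loa_lower, x$loa_upper))
  if (all(is.finite(x$loa_lower_ci))) {
    cat(sprintf("    lower LoA 95%% CI %8.3f to %.3f\n", x$loa_lower_ci[1], x$loa_lower_ci[2]))
    cat(sprintf("    upper LoA 95%% CI %8.3f to %.3f\n", x$loa_upper_ci[1], x$loa_upper_ci[2]))
  }
  if (x$degenerate) cat("  NOTE: degenerate fit (all differences identical)\n")
  if (x$tau2_truncated) cat("  NOTE: tau2 truncated at zero\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an agreement fit
#'
#' One row per reported quantity (`mean_bias`, `tau2`, `sigma2`, `phi`,
#' `total_sd`, `loa_lower`, `loa_upper`) with the estimate and, where
#' available, 95% confidence bounds.
#'
#' @param x An `hr_agreement` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`, `conf.high`.
#' @method tidy hr_agreement
#' @export
tidy.hr_agreement <- function(x, ...) {
  tibble::tibble(
    term = c("mean_bias", "tau2", "sigma2", "phi", "total_sd",
             "loa_lower", "loa_upper"),
    estimate = c(x$mu, x$tau2, x$sigma2, x$phi, x$total_sd,
                 x$loa_lower, x$loa_upper),
    conf.low = c(x$mu_ci[1], NA, NA, NA, NA, x$loa_lower_ci[1], x$loa_upper_ci[1]),
    conf.high = c(x$mu_ci[2], NA, NA, NA, NA, x$loa_lower_ci[2], x$loa_upper_ci[2])
  ) |>
    dplyr::filter(!(term == "phi" & is.na(.data$estimate)))
}

#' Glance at an agreement fit
#' @param x An `hr_agreement` object.
#' @param ... Unused.
#' @return A one-row tibble of fit-level summaries.
#' @method glance hr_agreement
#' @export
glance.hr_agreement <- function(x, ...) {
  tibble::tibble(
    n_epochs = x$n_epochs,
    n_participants = x$n_participants,
    logLik = x$logLik,
    with_ar1 = x$with_ar1,
    degenerate = x$degenerate,
    tau2_truncated = x$tau2_truncated
  )
}

#' Bland-Altman plot of an agreement fit
#'
#' Scatter of epoch differences against pair means, with a solid line at
#' the mean bias and dashed lines at the limits of agreement.
#'
#' @param object An `hr_agreement` object (it carries its fitting data).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hr_agreement
#' @export
autoplot.hr_agreement <- function(object, ...) {
  plot_bland_altman(object$data, object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot from a paired-epoch table and a fit
#'
#' @param table Paired-epoch tibble with `hr_index`, `hr_criterion`,
#'   `difference`.
#' @param fit An `hr_agreement` object supplying the bias and LoA lines.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(table, fit) {
  if (nrow(table) == 0L) rlang::abort("cannot plot an empty table", class = "hragree_render_error")
  df <- dplyr::mutate(table, pair_mean = (.data$hr_index + .data$hr_criterion) / 2)
  many <- length(unique(df$participant_id)) > 1L
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_mean, y = .data$difference))
  p <- if (many) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$participant_id),
                            alpha = 0.3, size = 0.6, show.legend = FALSE)
  } else {
    p + ggplot2::geom_point(alpha = 0.3, size = 0.6)
  }
  p +
    ggplot2::geom_hline(yintercept = fit$mu, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(fit$loa_lower, fit$loa_upper),
                        linetype = "dashed", linewidth = 0.6) +
    ggplot2::labs(
      x = "Pair mean heart rate (beats/min)",
      y = "Difference, index - criterion (beats/min)"
    ) +
    ggplot2::theme_minimal()
}
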