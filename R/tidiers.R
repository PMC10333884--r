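#' Tidy an FP fit
#'
#' @param x An `fp_fit` object.
#' @param ... Unused.
#' @return Tibble of parameter estimates with standard errors.
#' @exportS3Method generics::tidy
tidy.fp_fit <- function(x, ...) x$estimates

#' One-row summary of an FP fit
#'
#' @param x An `fp_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `kind`, the headline parameter (`kd`, `ic50`
#'   or `active_fraction`), residual standard deviation, number of
#'   observations and the no-binding flag.
#' @exportS3Method generics::glance
glance.fp_fit <- function(x, ...) {
  headline <- switch(x$kind,
                     saturation = c(kd = x$kd),
                     displacement = c(ic50 = x$ic50),
                     active_fraction = c(active_fraction = x$active_fraction))
  tibble(
    kind = x$kind,
    !!!headline,
    sigma = if (is.null(x$fit)) NA_real_ else summary(x$fit)$sigma,
    nobs = nrow(x$data),
    no_binding = isTRUE(x$no_binding)
  )
}

#' Tidy a concordance analysis
#'
#' @param x A `concordance` object.
#' @param ... Unused.
#' @return The per-record verdict tibble.
#' @exportS3Method generics::tidy
tidy.concordance <- function(x, ...) x$verdicts

#' One-row summary of a concordance analysis
#'
#' @param x A `concordance` object.
#' @param ... Unused.
#' @return One-row tibble: `n_tested`, `n_pass`, `n_agree`,
#'   `agreement_fraction`.
#' @exportS3Method generics::glance
glance.concordance <- function(x, ...) {
  tibble(n_tested = x$n_tested, n_pass = x$n_pass, n_agree = x$n_agree,
         agreement_fraction = x$agreement_fraction)
}

#' Volcano-style plot of PES results
#'
#' PES on the x axis, -log10 Mann-Whitney p on the y axis, points
#' coloured by classification.
#'
#' @param object A `pes_results` tibble from [pes_scores()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pes_results <- function(object, ...) {
  cut <- attr(object, "cutoffs") %||% list(pes_min = 2, p_max = 0.01)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pes,
                               y = -log10(.data$p_value),
                               colour = .data$classification)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-cut$pes_min, cut$pes_min),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(cut$p_max),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(
      enabling = "#E69F00", disabling = "#0072B2",
      not_significant = "grey70")) +
    ggplot2::labs(x = "phosphomimetic enrichment score (PES)",
                  y = expression(-log[10] ~ italic(p)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an FP fit with its data
#'
#' @param object An `fp_fit` object.
#' @param n_curve Number of points on the fitted curve (default 200).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fp_fit <- function(object, n_curve = 200, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$concentration,
                                    y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (µM)", y = "polarization (mP)") +
    ggplot2::theme_minimal()
  if (!is.null(object$fit)) {
    pos <- object$data$concentration[object$data$concentration > 0]
    grid <- tibble(concentration = exp(seq(log(min(pos)), log(max(pos)),
                                           length.out = n_curve)))
    grid$signal <- as.numeric(stats::predict(object$fit, newdata = grid))
    p <- p + ggplot2::geom_line(data = grid, colour = "#0072B2")
  }
  p
}

#' Plot the library-design coverage histogram
#'
#' @param object A `library_stats` object from [compute_library_stats()].
#' @param ... Unused.
#' @return A ggplot object (tiles covering each phosphosite).
#' @exportS3Method ggplot2::autoplot
autoplot.library_stats <- function(object, ...) {
  ggplot2::ggplot(object$site_coverage,
                  ggplot2::aes(x = factor(.data$n_tiles),
                               y = .data$n_sites)) +
    ggplot2::geom_col(fill = "#0072B2") +
    ggplot2::labs(x = "overlapping peptides per phosphosite",
                  y = "phosphosites") +
    ggplot2::theme_minimal()
}
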