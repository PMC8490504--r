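#' Volcano plot of moderated differential-abundance results
#'
#' @param object A `kp_moderated` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kp_moderated
#' @export
autoplot.kp_moderated <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2_fc,
                                    y = -log10(.data$p_value),
                                    colour = .data$significant)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$analyte),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "log2 fold change (tumor vs control)",
                  y = "-log10 p", colour = paste0("p < ", object$alpha)) +
    ggplot2::theme_minimal()
}

#' Fold change against enzymatic distance from Trp
#'
#' @param object A `kp_gradient` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kp_gradient
#' @export
autoplot.kp_gradient <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pathway_distance,
                                    y = .data$log2_fc)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$analyte),
                       vjust = -0.9, size = 3) +
    ggplot2::labs(
      x = "enzymatic steps away from Trp",
      y = "log2 fold change (tumor vs control)",
      subtitle = sprintf("Spearman rho(|log2FC|, distance) = %.2f, permutation p = %.2g",
                         object$rho, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of mean ratios with confidence intervals
#'
#' @param object A `kp_associations` tibble (from [regress_on_covariate()]
#'   or [survival_associations()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kp_associations
#' @export
autoplot.kp_associations <- function(object, ...) {
  lab_col <- setdiff(names(object), c("b", "se_b", "mr", "ci_lo", "ci_hi",
                                      "p_value", "n", "n_events"))[1]
  if (is.na(lab_col)) {
    object$term <- "level"
    lab_col <- "term"
  }
  object$sig <- object$ci_lo > 1 | object$ci_hi < 1
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mr, y = .data[[lab_col]],
                               colour = .data$sig)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "grey40"),
                                 guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of simulated cohort concentrations (mean +/- SEM)
#'
#' @param object A `kp_cohort_comparison` tibble from [compare_cohorts()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kp_cohort_comparison
#' @export
autoplot.kp_cohort_comparison <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, species = .data$species,
                     group = .data$group_1, mean = .data$mean_1,
                     sem = .data$sem_1),
    dplyr::transmute(object, species = .data$species,
                     group = .data$group_2, mean = .data$mean_2,
                     sem = .data$sem_2)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species, y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "simulated concentration (mM)") +
    ggplot2::theme_minimal()
}

#' Boxplot of log2 sample/reference ratios by class
#'
#' @param ratios Long ratio tibble with `class` metadata.
#' @return A ggplot.
#' @export
plot_ratio_boxplot <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(x = .data$analyte,
                                       y = .data$log_ratio,
                                       fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "log2 (sample / reference)") +
    ggplot2::theme_minimal()
}
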