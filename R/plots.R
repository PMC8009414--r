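#' Plot a derived allele-frequency spectrum
#'
#' @param object An `afs_summary` from [derived_afs()], or a row-bound
#'   collection of several (their `step`/`group` labels colour the lines).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.afs_summary <- function(object, ...) {
  df <- as_tibble(object)
  has_label <- !all(is.na(df$step)) || !all(is.na(df$group))
  df$label <- ifelse(is.na(df$step), df$group,
                     ifelse(is.na(df$group), df$step,
                            paste(df$group, df$step, sep = " / ")))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$density))
  if (has_label) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$label)) +
      ggplot2::labs(colour = NULL)
  } else {
    p <- p + ggplot2::geom_col(width = df$hi[1] - df$lo[1])
  }
  p + ggplot2::labs(x = "derived allele frequency",
                    y = "proportion of loci") +
    ggplot2::theme_minimal()
}

#' Plot OHE by design step and population group
#'
#' @param object An `ohe_table` (possibly with a `replicate` column) as
#'   returned by [ohe_table()] or found in a `sweep_result`'s `$ohe`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ohe_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$ohe,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "overestimation of H_exp (OHE)",
                  fill = "population group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot estimated marginal means of an OHE contrast fit
#'
#' @param object An `ohe_contrast` from [ohe_group_model()].
#' @param ... Unused.
#' @return A ggplot with LSMEANS and their confidence intervals.
#' @export
autoplot.ohe_contrast <- function(object, ...) {
  df <- object$lsmeans
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.15) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "population group", y = "LSMEAN of OHE") +
    ggplot2::theme_minimal()
}

#' Plot per-step SNP counts of a design
#'
#' @param design An `array_design`.
#' @return A ggplot of the SNP count retained after each design step.
#' @export
plot_step_counts <- function(design) {
  if (!inherits(design, "array_design")) {
    abort_config("`design` must be an <array_design>")
  }
  df <- design$counts %>%
    mutate(step = factor(.data$step, levels = .data$step))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "SNPs retained") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
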