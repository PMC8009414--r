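#' Mixed-model contrasts of OHE between population groups
#'
#' Fits `OHE ~ group + (1 | replicate)` by REML: a fixed population-group
#' effect (discovery, validation, application, outgroup) and a random
#' intercept for the repetition of the random grouping. Estimated marginal
#' means (LSMEANS) per group and all pairwise group differences with Tukey
#' multiplicity adjustment are extracted with \pkg{emmeans}. When the
#' replicate variance estimate is singular (zero), the model falls back to a
#' fixed-effects fit `OHE ~ group`, flagged in the result; with balanced data
#' the LSMEANS then equal the raw group means.
#'
#' @param data A `sweep_result` or a data frame with columns `ohe`, `group`,
#'   `replicate` and (if `step` is given) `step`.
#' @param step Optional design-step label to subset to.
#' @return An object of class `ohe_contrast` with elements `lsmeans`
#'   (group, estimate, se, df, lower, upper), `contrasts` (contrast,
#'   estimate, se, df, t_ratio, p_adj), `varcomp` (named: replicate,
#'   residual), `fallback_fixed`, `model` and `n_obs`. Use [tidy()] and
#'   [glance()] for tibble views.
#' @export
ohe_group_model <- function(data, step = NULL) {
  if (inherits(data, "sweep_result")) data <- data$ohe
  data <- as_tibble(data)
  if (!all(c("ohe", "group", "replicate") %in% names(data))) {
    abort_config("`data` needs columns ohe, group, replicate")
  }
  if (!is.null(step)) {
    data <- data[data$step == step, ]
  }
  if (nrow(data) == 0) abort_config("no rows to fit after subsetting")
  if (length(unique(data$group)) < 2) abort_config("need at least two groups")
  if (length(unique(data$replicate)) < 2) {
    abort_config("need at least two replicates")
  }
  data$group <- droplevels(factor(data$group))
  data$replicate <- factor(data$replicate)

  fit <- suppressMessages(
    lme4::lmer(ohe ~ group + (1 | replicate), data = data, REML = TRUE)
  )
  singular <- lme4::isSingular(fit, tol = 1e-6)
  if (singular) {
    fit <- stats::lm(ohe ~ group, data = data)
    varcomp <- c(replicate = 0, residual = stats::sigma(fit)^2)
  } else {
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- c(replicate = vc$vcov[vc$grp == "replicate"],
                 residual = vc$vcov[vc$grp == "Residual"])
  }
  emm <- emmeans::emmeans(fit, ~ group)
  emm_df <- as.data.frame(emm)
  ctr_df <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                            adjust = "tukey"))
  structure(list(
    lsmeans = tibble(group = as.character(emm_df$group),
                     estimate = emm_df$emmean, se = emm_df$SE,
                     df = emm_df$df,
                     lower = emm_df[[ncol(emm_df) - 1L]],
                     upper = emm_df[[ncol(emm_df)]]),
    contrasts = tibble(contrast = as.character(ctr_df$contrast),
                       estimate = ctr_df$estimate, se = ctr_df$SE,
                       df = ctr_df$df, t_ratio = ctr_df$t.ratio,
                       p_adj = ctr_df$p.value),
    varcomp = varcomp,
    fallback_fixed = singular,
    model = fit,
    n_obs = nrow(data),
    step = step
  ), class = "ohe_contrast")
}

#' @export
print.ohe_contrast <- function(x, ...) {
  cat(sprintf("<ohe_contrast>%s%s\n",
              if (!is.null(x$step)) paste0(" step '", x$step, "'") else "",
              if (x$fallback_fixed) " [fixed-effects fallback]" else ""))
  cat("LSMEANS:\n")
  print(as.data.frame(x$lsmeans), row.names = FALSE, digits = 4)
  cat("Tukey-adjusted pairwise contrasts:\n")
  print(as.data.frame(x$contrasts), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy an OHE contrast fit
#'
#' @param x An `ohe_contrast`.
#' @param effects `"contrasts"` (default) for the Tukey-adjusted pairwise
#'   group differences or `"lsmeans"` for the estimated marginal means.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ohe_contrast <- function(x, effects = c("contrasts", "lsmeans"), ...) {
  effects <- match.arg(effects)
  if (effects == "contrasts") x$contrasts else x$lsmeans
}

#' One-row model summary of an OHE contrast fit
#'
#' @param x An `ohe_contrast`.
#' @param ... Unused.
#' @return A tibble with variance components and bookkeeping.
#' @export
glance.ohe_contrast <- function(x, ...) {
  tibble(
    sigma2_replicate = unname(x$varcomp["replicate"]),
    sigma2_residual = unname(x$varcomp["residual"]),
    n_obs = x$n_obs,
    n_groups = nrow(x$lsmeans),
    fallback_fixed = x$fallback_fixed
  )
}
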