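# Group comparison layer: per-group summaries and control-referenced
# multiple comparisons (one-way ANOVA followed by Dunnett's many-to-one
# test), the standard analysis for treatment-vs-control imaging readouts.

STAR_CUTOFFS <- c(`****` = 1e-04, `***` = 2e-04, `**` = 0.0021, `*` = 0.0332)

p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    for (s in names(STAR_CUTOFFS)) if (pi < STAR_CUTOFFS[[s]]) return(s)
    "ns"
  }, character(1))
}

#' Per-group summary statistics
#'
#' Mean, SD (n - 1 denominator) and n per group. Groups with a single
#' observation get `NA` SD and are flagged.
#'
#' @param data A data frame of observations.
#' @param value,group Columns holding the metric and the group label
#'   (tidy-eval).
#' @return A tibble with `group`, `n`, `mean`, `sd`, `flag`.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 4, 5, 6))
#' group_summary(df, y, g)
group_summary <- function(data, value, group) {
  data |>
    dplyr::group_by(group = {{ group }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sd = if (dplyr::n() >= 2) sd({{ value }}) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(flag = ifelse(.data$n < 2, "single_observation", ""))
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Fits `value ~ group` by one-way ANOVA (homoscedastic) and compares every
#' treatment group against the control with Dunnett's test, which adjusts
#' the family of comparisons through the joint multivariate-t distribution
#' of the test statistics (via [multcomp::glht()]). Significance stars are
#' assigned on the four-tier scale `* < 0.0332`, `** < 0.0021`,
#' `*** < 0.0002`, `**** < 0.0001`; the tiers are presentation only and
#' decoupled from `alpha`.
#'
#' If every observation is identical the F statistic is undefined and the
#' fit is returned as non-significant by construction (all p `NA`,
#' `significant = FALSE`).
#'
#' @param data A data frame of observations.
#' @param value,group Metric and group columns (tidy-eval).
#' @param control Control group label (the reference of every comparison).
#' @param alpha Testing level used for the `significant` flag (default
#'   0.05).
#' @param seed Seed for the multivariate-t quadrature, which is randomised
#'   internally; fixing it makes adjusted p-values reproducible.
#' @return A `dunnett_fit` with [tidy()] (per-comparison table: estimate,
#'   unadjusted and adjusted p, stars, significance) and [glance()]
#'   (F statistic, p, degrees of freedom) methods.
#' @export
#' @examples
#' df <- data.frame(
#'   g = rep(c("ctrl", "t1", "t2"), each = 4),
#'   y = c(rnorm(4, 10), rnorm(4, 12), rnorm(4, 10))
#' )
#' fit <- dunnett_test(df, y, g, control = "ctrl")
#' tidy(fit)
#' glance(fit)
dunnett_test <- function(data, value, group, control, alpha = 0.05, seed = 1L) {
  df <- tibble(
    value = dplyr::pull(data, {{ value }}),
    group = as.character(dplyr::pull(data, {{ group }}))
  )
  groups <- unique(df$group)
  if (!control %in% groups) abort(sprintf("Control group '%s' is absent.", control))
  if (length(groups) < 2) abort("At least two groups (control + one) are required.")
  counts <- table(df$group)
  if (any(counts < 2)) abort("Every group needs at least two observations.")
  df$group <- factor(df$group, levels = c(control, sort(setdiff(groups, control))))

  treatments <- levels(df$group)[-1]
  degenerate <- stats::var(df$value) == 0
  if (degenerate) {
    comparisons <- tibble(
      comparison = paste(treatments, "-", control),
      group = treatments,
      estimate = 0, statistic = NA_real_,
      p_unadjusted = NA_real_, p_adjusted = NA_real_,
      stars = NA_character_, significant = FALSE
    )
    fit <- list(
      comparisons = comparisons,
      anova = tibble(statistic = NA_real_, p_value = NA_real_,
                     df_between = length(treatments), df_within = nrow(df) - length(levels(df$group))),
      control = control, alpha = alpha, degenerate = TRUE,
      method = "dunnett (multivariate t)"
    )
    return(structure(fit, class = "dunnett_fit"))
  }

  fit_aov <- aov(value ~ group, data = df)
  an <- summary(fit_aov)[[1]]
  glht_fit <- multcomp::glht(fit_aov, linfct = multcomp::mcp(group = "Dunnett"))
  with_seed(seed, {
    adj <- summary(glht_fit, test = multcomp::adjusted("single-step"))
    unadj <- summary(glht_fit, test = multcomp::adjusted("none"))
  })
  comparisons <- tibble(
    comparison = rownames(adj$linfct),
    group = treatments,
    estimate = as.numeric(adj$test$coefficients),
    statistic = as.numeric(adj$test$tstat),
    p_unadjusted = as.numeric(unadj$test$pvalues),
    p_adjusted = as.numeric(adj$test$pvalues)
  ) |>
    dplyr::mutate(
      stars = p_stars(.data$p_adjusted),
      significant = .data$p_adjusted < alpha
    )
  fit <- list(
    comparisons = comparisons,
    anova = tibble(
      statistic = an$`F value`[1],
      p_value = an$`Pr(>F)`[1],
      df_between = an$Df[1],
      df_within = an$Df[2]
    ),
    control = control, alpha = alpha, degenerate = FALSE,
    method = "dunnett (multivariate t)"
  )
  structure(fit, class = "dunnett_fit")
}

#' @export
print.dunnett_fit <- function(x, ...) {
  cat(sprintf("Dunnett many-to-one comparisons vs '%s' (%s)\n",
              x$control, x$method))
  if (x$degenerate) {
    cat("  Degenerate input (zero variance): non-significant by construction.\n")
  } else {
    cat(sprintf("  One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
                x$anova$df_between, x$anova$df_within,
                x$anova$statistic, x$anova$p_value))
  }
  print(x$comparisons)
  invisible(x)
}

#' @export
tidy.dunnett_fit <- function(x, ...) x$comparisons

#' @export
glance.dunnett_fit <- function(x, ...) x$anova
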