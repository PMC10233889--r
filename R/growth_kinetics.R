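# Live-cell confluence kinetics: per-well normalization to initial
# confluence, log2 transform, log-linear slope fits and a Wald test on the
# slope difference between two conditions.

#' Normalize confluence to each well's initial value and log2 transform
#'
#' `y(well, t) = log2(confluence(t) / confluence(t0))` with `t0` the earliest
#' measured time point of the well, so `y(t0) = 0` exactly. For exponential
#' growth y is linear in time with slope equal to the growth rate in
#' doublings per hour.
#'
#' @param raw a `growth_table`.
#' @return the table with an added `log2_rel` column.
#' @export
normalize_confluence <- function(raw) {
  stopifnot(inherits(raw, "growth_table"))
  key <- paste(raw$condition, raw$well, sep = "\r")
  raw$log2_rel <- NA_real_
  for (k in unique(key)) {
    idx <- which(key == k)
    t0 <- idx[which.min(raw$time_h[idx])]
    ref <- raw$confluence_pct[t0]
    if (!is.finite(ref) || ref <= 0)
      stopf("well '%s' (%s) has non-positive initial confluence",
            raw$well[t0], raw$condition[t0])
    raw$log2_rel[idx] <- log2(raw$confluence_pct[idx] / ref)
  }
  raw
}

# pooled OLS slope fit for one condition
fit_slope <- function(tbl, condition) {
  sub <- tbl[tbl$condition == condition, , drop = FALSE]
  if (!nrow(sub)) stopf("condition '%s' absent from growth table", condition)
  if (length(unique(sub$time_h)) < 2)
    stopf("condition '%s' has a singular design (one time point)", condition)
  fit <- lm(log2_rel ~ time_h, data = sub)
  s <- summary(fit)
  data.frame(condition = condition,
             slope = unname(coef(fit)["time_h"]),
             intercept = unname(coef(fit)["(Intercept)"]),
             slope_se = s$coefficients["time_h", "Std. Error"],
             n = nrow(sub),
             residual_var = s$sigma^2,
             stringsAsFactors = FALSE)
}

#' Compare growth slopes between two conditions with a Wald test
#'
#' Fits one Gaussian linear model `log2_rel ~ time * condition` over the
#' pooled well-level observations of both conditions (wells enter as
#' independent observations). The slope difference is the interaction
#' coefficient; the Wald statistic `z = delta / SE(delta)` is referred to
#' the standard normal (two-sided) by default.
#'
#' @param transformed output of [normalize_confluence()].
#' @param conditions character pair; the difference reported is
#'   `slope(conditions[1]) - slope(conditions[2])`.
#' @param t_reference use the model's residual-t reference instead of the
#'   normal (default FALSE).
#' @param cluster_wells use a well-clustered (CR) robust standard error for
#'   the Wald test (default FALSE).
#' @return list with `fits` (two-row per-condition slope table) and
#'   `comparison` (one-row data.frame: condition_1, condition_2, delta_slope,
#'   se, z, p).
#' @export
compare_slopes <- function(transformed, conditions, t_reference = FALSE,
                           cluster_wells = FALSE) {
  stopifnot(length(conditions) == 2)
  if (is.null(transformed$log2_rel))
    stopf("run normalize_confluence() first")
  sub <- transformed[transformed$condition %in% conditions, , drop = FALSE]
  for (cond in conditions) {
    s <- sub[sub$condition == cond, ]
    if (!nrow(s)) stopf("condition '%s' absent from growth table", cond)
    if (length(unique(s$time_h)) < 3 || length(unique(s$well)) < 2)
      stopf("condition '%s' needs >=3 time points and >=2 wells", cond)
  }
  # reference level = conditions[2], so the interaction term is
  # slope(conditions[1]) - slope(conditions[2])
  sub$condition <- factor(sub$condition, levels = rev(conditions))
  fit <- glm(log2_rel ~ time_h * condition, family = gaussian(), data = sub)
  term <- paste0("time_h:condition", conditions[1])
  delta <- unname(coef(fit)[term])
  vc <- if (cluster_wells)
    sandwich::vcovCL(fit, cluster = interaction(sub$condition, sub$well))
  else vcov(fit)
  se <- sqrt(vc[term, term])
  z <- if (se > 0) delta / se else sign(delta) * Inf
  p <- if (t_reference)
    2 * pt(-abs(z), df = fit$df.residual)
  else
    2 * pnorm(-abs(z))
  if (se == 0 && delta == 0) { z <- 0; p <- 1 }
  list(fits = rbind(fit_slope(sub, conditions[1]),
                    fit_slope(sub, conditions[2])),
       comparison = data.frame(condition_1 = conditions[1],
                               condition_2 = conditions[2],
                               delta_slope = delta, se = se, z = z, p = p,
                               stringsAsFactors = FALSE))
}
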