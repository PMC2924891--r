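#' One-way analysis of variance
#'
#' Standard fixed-effects decomposition via `lm`/`anova`; returned as a
#' tidy one-row tibble with group means attached. Degenerate inputs with
#' zero residual variance return F = 0, p = 1 when the group means are
#' equal, and F = Inf, p = 0 otherwise.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups, each with >= 2 observations).
#' @return Tibble: `F`, `df1`, `df2`, `p_value`, plus `mean_<level>`
#'   columns.
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3)) # F = 13.5
#' @export
one_way_anova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) abort("Need >= 2 groups.")
  if (any(table(groups) < 2)) abort("Every group needs >= 2 observations.")
  fit <- lm(values ~ groups)
  av <- anova(fit)
  Fv <- av$`F value`[1]; p <- av$`Pr(>F)`[1]
  if (!is.finite(Fv)) {  # zero residual variance
    gm <- tapply(values, groups, mean)
    if (max(gm) - min(gm) < 1e-12) { Fv <- 0; p <- 1 } else { Fv <- Inf; p <- 0 }
  }
  means <- tapply(values, groups, mean)
  out <- tibble::tibble(F = Fv, df1 = av$Df[1], df2 = av$Df[2], p_value = p)
  for (l in names(means)) out[[paste0("mean_", l)]] <- unname(means[l])
  out
}

#' Proportional difference between reserve and control means
#'
#' Reserve-effect size as a percent difference, under either convention:
#' `baseline = "outside"` gives 100 (in - out) / out ("X% greater inside
#' than outside"); `baseline = "inside"` gives 100 (in - out) / in. Both
#' appear in published reserve contrasts, so downstream reports always
#' carry both.
#'
#' @param mean_in,mean_out zone means; the baseline mean must be positive.
#' @param baseline "outside" (default) or "inside".
#' @return Percent difference (sign = sign of in - out).
#' @examples
#' proportional_difference(150, 100)                      # +50
#' proportional_difference(14.9, 17.4, "inside")          # about -17
#' @export
proportional_difference <- function(mean_in, mean_out,
                                    baseline = c("outside", "inside")) {
  baseline <- match.arg(baseline)
  base <- if (baseline == "outside") mean_out else mean_in
  if (any(base <= 0)) abort("Baseline mean must be positive.")
  100 * (mean_in - mean_out) / base
}
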