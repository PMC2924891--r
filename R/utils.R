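#' @importFrom rlang abort warn inform %||%
#' @importFrom stats anova as.dist complete.cases cor cutree dist hclust lm
#'   pf prcomp quantile rbinom rlnorm rmultinom rnorm rpois runif sd setNames var
#' @importFrom utils head modifyList
NULL

# Derive a reproducible 32-bit child seed for a named pipeline stage from the
# global seed, so stages can be re-run independently with identical draws.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + offs * 104729) %% (.Machine$integer.max - 1L)) + 1L
}

with_stage_seed <- function(seed, stage, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(seed, stage))
  force(code)
}

row_mins <- function(m) do.call(pmin, as.data.frame(m))

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    abort(sprintf("`%s` must be positive and finite.", name))
  invisible(x)
}

assert_fraction <- function(x, name, closed = TRUE) {
  ok <- if (closed) x >= 0 & x <= 1 else x > 0 & x < 1
  if (any(!is.finite(x)) || any(!ok))
    abort(sprintf("`%s` must lie in %s.", name, if (closed) "[0, 1]" else "(0, 1)"))
  invisible(x)
}
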