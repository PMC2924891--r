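#' Canonical correspondence analysis
#'
#' Constrained ordination of a nonnegative community table on environmental
#' variables via the classical chi-square algorithm: the table is converted
#' to relative abundances P with row/column weight vectors r and c, the
#' standardized residual matrix Q = (P - r c') / sqrt(r c') is projected by
#' weighted least squares onto the environmental matrix (columns centred
#' with row weights, rows scaled by sqrt(r)), and the fitted matrix is
#' decomposed by SVD. Eigenvalues are squared singular values; the total
#' inertia sum(Q^2) equals the chi-square statistic of the table divided by
#' its grand total; the pseudo-F is (constrained/k) / (residual/(n-k-1)).
#'
#' Applying CCA to a handful of summary response variables (richness,
#' biomass, cover) rather than a full species table is unusual but follows
#' the assessment design this package implements.
#'
#' @param Y community matrix or tibble (sites x responses), nonnegative,
#'   positive row sums; a `site_id` column is used as row names. All-zero
#'   columns are dropped with a warning; rank-deficient `X` fails naming
#'   the aliased columns.
#' @param X environmental matrix/tibble (sites x variables).
#' @return A `cca_fit`: `eig`, `total_inertia`, `constrained_inertia`,
#'   `residual_inertia`, `prop_axis1` (first-axis share of total inertia),
#'   `pseudo_F`, `rank`, `coefficients` (env x axes), species scores `v`,
#'   weighted site scores, row/column weights.
#' @examples
#' Y <- rbind(c(10, 2, 1), c(8, 3, 2), c(1, 9, 4), c(2, 7, 5))
#' X <- cbind(grad = c(-1, -1, 1, 1))
#' cca_fit(Y, X)$eig
#' @export
cca_fit <- function(Y, X) {
  Y <- community_matrix(Y)
  X <- env_matrix(X, nrow(Y))
  if (any(Y < 0)) abort("Community matrix must be nonnegative.")
  if (any(rowSums(Y) <= 0)) abort("Every site needs a positive row sum.")
  zero_col <- colSums(Y) == 0
  if (any(zero_col)) {
    warn(paste("Dropping all-zero response column(s):",
               paste(colnames(Y)[zero_col], collapse = ", ")))
    Y <- Y[, !zero_col, drop = FALSE]
  }
  n <- nrow(Y)
  # the F denominator needs n > k + 1; the saturated case k = n - 1 is
  # allowed for the correspondence-analysis equivalence (F is then Inf)
  if (n <= ncol(X))
    abort("Need more sites than environmental variables.")
  P <- Y / sum(Y)
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  Q <- (P - E) / sqrt(E)
  tot <- sum(Q^2)
  Xw <- weighted_env(X, r)
  qrx <- qr(Xw)
  if (qrx$rank < ncol(Xw)) {
    aliased <- colnames(Xw)[qrx$pivot[(qrx$rank + 1):ncol(Xw)]]
    abort(paste("Rank-deficient environmental matrix; aliased:",
                paste(aliased, collapse = ", ")))
  }
  Qhat <- qr.fitted(qrx, Q)
  sv <- svd(Qhat)
  keep <- sv$d^2 > max(1e-12, 1e-10 * max(sv$d^2, 1e-300))
  eig <- sv$d[keep]^2
  constrained <- sum(Qhat^2)
  resid <- max(tot - constrained, 0)
  k <- qrx$rank
  pseudo_F <- if (resid > 0 && n - k - 1 > 0)
    (constrained / k) / (resid / (n - k - 1)) else Inf
  u <- sv$u[, keep, drop = FALSE]
  coef <- if (any(keep)) qr.coef(qrx, u) else matrix(0, ncol(Xw), 0)
  structure(list(
    eig = eig, total_inertia = tot, constrained_inertia = constrained,
    residual_inertia = resid,
    prop_axis1 = if (length(eig) && tot > 0) eig[1] / tot else 0,
    pseudo_F = pseudo_F, rank = k, n_sites = n,
    coefficients = coef,
    species_scores = sv$v[, keep, drop = FALSE],
    site_scores = u / sqrt(r),
    row_weights = r, col_weights = cc),
    class = "cca_fit")
}

community_matrix <- function(Y) {
  if (is.data.frame(Y)) {
    ids <- if ("site_id" %in% names(Y)) Y$site_id else NULL
    Y <- as.matrix(Y[setdiff(names(Y), "site_id")])
    if (!is.null(ids)) rownames(Y) <- ids
  }
  storage.mode(Y) <- "double"
  if (is.null(colnames(Y))) colnames(Y) <- paste0("resp", seq_len(ncol(Y)))
  Y
}

env_matrix <- function(X, n) {
  if (is.data.frame(X)) X <- as.matrix(X[setdiff(names(X), "site_id")])
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("env", seq_len(ncol(X)))
  if (nrow(X) != n) abort("Y and X must have matching rows.")
  X
}

weighted_env <- function(X, r) {
  wmean <- colSums(X * r)
  sweep(X, 2, wmean) * sqrt(r)
}

#' Monte Carlo permutation test for a CCA model
#'
#' Rows of the environmental matrix are permuted jointly (simple
#' permutation, exact under exchangeability of sites); the observed
#' pseudo-F is compared to the permutation distribution and
#' p = (1 + #\{F_perm >= F_obs\}) / (n_perm + 1), so the smallest
#' attainable p with 999 permutations is 0.001.
#'
#' @inheritParams cca_fit
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return The `cca_fit` with `p_value`, `n_perm` and `seed` added
#'   (class `cca_perm`).
#' @export
cca_permutation_test <- function(Y, X, n_perm = 999, seed = 1L) {
  fit <- cca_fit(Y, X)
  Xm <- env_matrix(X, fit$n_sites)
  Ym <- community_matrix(Y)
  Ym <- Ym[, colSums(Ym) > 0, drop = FALSE]
  P <- Ym / sum(Ym)
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  Q <- (P - E) / sqrt(E)
  tot <- sum(Q^2)
  n <- nrow(Ym); k <- fit$rank
  stat <- function(Xp) {
    Xw <- weighted_env(Xp, r)
    Qhat <- qr.fitted(qr(Xw), Q)
    con <- sum(Qhat^2)
    (con / k) / (max(tot - con, 1e-300) / (n - k - 1))
  }
  ge <- with_stage_seed(seed, "cca_perm", {
    sum(vapply(seq_len(n_perm), function(i)
      stat(Xm[sample.int(n), , drop = FALSE]) >= fit$pseudo_F - 1e-12, TRUE))
  })
  fit$p_value <- (1 + ge) / (n_perm + 1)
  fit$n_perm <- n_perm
  fit$seed <- seed
  class(fit) <- c("cca_perm", class(fit))
  fit
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf(
    "<cca_fit> n=%d, k=%d | inertia: total %.4f, constrained %.4f (axis1 %.1f%% of total) | pseudo-F %.3f\n",
    x$n_sites, x$rank, x$total_inertia, x$constrained_inertia,
    100 * x$prop_axis1, x$pseudo_F))
  if (!is.null(x$p_value))
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$p_value, x$n_perm))
  invisible(x)
}

#' Forward model selection for constrained ordination by AIC
#'
#' Greedy forward selection over candidate environmental columns. Because
#' no canonical AIC exists for CCA, the criterion is the residual-inertia
#' surrogate AIC = n * ln(residual inertia / n) + 2 (k + 1), with k the
#' number of selected variables; selection stops when no addition lowers
#' the criterion. Candidates whose addition makes the model rank-deficient
#' (e.g. duplicates of a selected column) are skipped. The final model is
#' refit and permutation-tested.
#'
#' @inheritParams cca_permutation_test
#' @param X tibble/matrix of candidate columns.
#' @return A `cca_select`: `selected` (column names, possibly empty),
#'   `trace` tibble (step, candidate added, AIC), and `fit` (a `cca_perm`
#'   for the selected model, or NULL if none selected).
#' @export
aic_forward_select <- function(Y, X, n_perm = 999, seed = 1L) {
  Ym <- community_matrix(Y)
  Xm <- env_matrix(X, nrow(Ym))
  if (ncol(Xm) < 1) abort("Need at least one candidate column.")
  n <- nrow(Ym)
  Yk <- Ym[, colSums(Ym) > 0, drop = FALSE]
  P <- Yk / sum(Yk)
  E <- outer(rowSums(P), colSums(P))
  tot <- sum((P - E)^2 / E)
  aic_of <- function(resid, k) n * log(max(resid, 1e-300) / n) + 2 * (k + 1)
  selected <- character(0)
  current_aic <- aic_of(tot, 0)
  trace <- list(tibble::tibble(step = 0L, added = NA_character_,
                               aic = current_aic, residual_inertia = tot))
  repeat {
    remaining <- setdiff(colnames(Xm), selected)
    if (!length(remaining)) break
    cand <- vapply(remaining, function(cn) {
      f <- tryCatch(
        suppressWarnings(cca_fit(Ym, Xm[, c(selected, cn), drop = FALSE])),
        error = function(e) NULL)
      if (is.null(f)) return(NA_real_)
      aic_of(f$residual_inertia, length(selected) + 1)
    }, 0)
    if (all(is.na(cand))) break
    best <- names(which.min(cand))
    if (cand[best] >= current_aic - 1e-9) break
    selected <- c(selected, best)
    current_aic <- cand[best]
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = length(selected), added = best, aic = current_aic,
      residual_inertia = n * exp((current_aic - 2 * (length(selected) + 1)) / n))
  }
  fit <- if (length(selected))
    cca_permutation_test(Ym, Xm[, selected, drop = FALSE],
                         n_perm = n_perm, seed = seed) else NULL
  structure(list(selected = selected, trace = dplyr::bind_rows(trace),
                 fit = fit, total_inertia = tot),
            class = "cca_select")
}

#' @export
print.cca_select <- function(x, ...) {
  cat("<cca_select>",
      if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "(intercept only)", "\n")
  if (!is.null(x$fit))
    cat(sprintf("  pseudo-F %.3f, p = %.4g\n", x$fit$pseudo_F, x$fit$p_value))
  invisible(x)
}
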