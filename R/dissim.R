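#' Bray-Curtis dissimilarity on (transformed) abundances
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), computed on fourth-root
#' transformed abundances by default to damp the contribution of dominant
#' species. Values lie in [0, 1]; the index is a semimetric (the triangle
#' inequality can fail) so no metric property is asserted. A pair of
#' all-zero rows has an undefined dissimilarity and is set to 0 with a
#' warning.
#'
#' @param x sites x species abundance matrix or tibble (optional `site_id`
#'   column used for labels); entries must be nonnegative.
#' @param pre_transform "fourth_root" (default) or "none".
#' @return A `dist` object over sites.
#' @examples
#' bray_curtis(rbind(c(6, 2), c(2, 2)), pre_transform = "none") # 1/3
#' @export
bray_curtis <- function(x, pre_transform = c("fourth_root", "none")) {
  pre_transform <- match.arg(pre_transform)
  m <- community_matrix(x)
  if (any(m < 0)) abort("Abundances must be nonnegative.")
  if (pre_transform == "fourth_root") m <- m^0.25
  n <- nrow(m)
  rs <- rowSums(m)
  d <- matrix(0, n, n)
  warned <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom <- rs[i] + rs[j]
    if (denom == 0) {
      if (!warned) { warn("All-zero site pair; dissimilarity set to 0."); warned <- TRUE }
      d[i, j] <- d[j, i] <- 0
    } else {
      d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / denom
    }
  }
  rownames(d) <- colnames(d) <- rownames(m)
  as.dist(d)
}

#' Analysis of similarities (one-way and two-way crossed)
#'
#' Clarke's rank-based ANOSIM on a dissimilarity matrix. One-way: R =
#' (mean between-group rank - mean within-group rank) / (M/4) with M =
#' n(n-1)/2, tested by permuting group labels. Two-way crossed: for the
#' factor of interest, dissimilarities are re-ranked within each level of
#' the other factor, an R statistic is computed per level and averaged,
#' and permutations shuffle labels only within levels of the other factor.
#' R is near 0 under the null and 1 at complete separation. p = (1 +
#' #\{R_perm >= R_obs\}) / (n_perm + 1); with `exact = TRUE` (one-way,
#' two groups) all distinct label assignments are enumerated instead and
#' p = #\{R_perm >= R_obs\} / #assignments.
#'
#' @param d a `dist` or square symmetric matrix.
#' @param grouping factor of interest (one level per site).
#' @param block optional crossing factor; every `grouping` x `block` cell
#'   must be non-empty.
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @param exact enumerate all assignments (one-way, 2 groups only).
#' @return An `anosim_result` tibble: one row per tested factor with `R`,
#'   `p_value`, `n_perm`.
#' @export
anosim <- function(d, grouping, block = NULL, n_perm = 999, seed = 1L,
                   exact = FALSE) {
  D <- as.matrix(d)
  n <- nrow(D)
  grouping <- as.factor(grouping)
  stopifnot(length(grouping) == n)
  if (nlevels(droplevels(grouping)) < 2)
    abort("`grouping` needs at least two levels.")
  if (!is.null(block)) {
    block <- as.factor(block)
    stopifnot(length(block) == n)
    tab <- table(grouping, block)
    if (any(tab == 0)) {
      empt <- which(tab == 0, arr.ind = TRUE)
      abort(sprintf("Empty cell(s) in the crossed design: %s",
                    paste(sprintf("%s x %s", rownames(tab)[empt[, 1]],
                                  colnames(tab)[empt[, 2]]), collapse = "; ")))
    }
  }
  res <- list(anosim_one_factor(D, grouping, block, n_perm, seed, exact,
                                factor_name = "grouping"))
  if (!is.null(block) && nlevels(droplevels(block)) >= 2)
    res[[2]] <- anosim_one_factor(D, block, grouping, n_perm,
                                  child_seed(seed, "factorB"), FALSE,
                                  factor_name = "block")
  out <- dplyr::bind_rows(res)
  structure(out, class = c("anosim_result", class(out)), seed = seed)
}

anosim_r_blocked <- function(D, g, blk) {
  vals <- c()
  for (b in levels(blk)) {
    sel <- which(blk == b)
    if (length(sel) < 2) next
    sub <- D[sel, sel, drop = FALSE]
    gg <- g[sel]
    iu <- which(upper.tri(sub))
    rk <- rank(sub[iu])
    same <- outer(gg, gg, "==")[iu]
    if (all(same) || !any(same)) next  # no between or no within pairs
    m <- length(iu)
    vals <- c(vals, (mean(rk[!same]) - mean(rk[same])) / (m / 2))
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

anosim_one_factor <- function(D, g, blk, n_perm, seed, exact, factor_name) {
  n <- nrow(D)
  blk <- if (is.null(blk)) factor(rep("all", n)) else droplevels(blk)
  g <- droplevels(g)
  r_obs <- anosim_r_blocked(D, g, blk)
  if (exact) {
    if (nlevels(blk) > 1 || nlevels(g) != 2)
      abort("`exact` enumeration supports the one-way two-group case only.")
    lev <- levels(g)
    n1 <- sum(g == lev[1])
    combos <- utils::combn(n, n1)
    rs <- apply(combos, 2, function(idx) {
      gp <- factor(ifelse(seq_len(n) %in% idx, lev[1], lev[2]), levels = lev)
      anosim_r_blocked(D, gp, blk)
    })
    p <- mean(rs >= r_obs - 1e-12)
    n_used <- ncol(combos)
  } else {
    ge <- with_stage_seed(seed, paste0("anosim_", factor_name), {
      sum(vapply(seq_len(n_perm), function(i) {
        gp <- g
        for (b in levels(blk)) {
          sel <- which(blk == b)
          gp[sel] <- gp[sel][sample.int(length(sel))]
        }
        anosim_r_blocked(D, gp, blk) >= r_obs - 1e-12
      }, TRUE))
    })
    p <- (1 + ge) / (n_perm + 1)
    n_used <- n_perm
  }
  tibble::tibble(factor = factor_name, R = r_obs, p_value = p,
                 n_perm = n_used)
}
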