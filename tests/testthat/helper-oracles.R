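# Independent brute-force oracles used to validate the spatial metrics,
# plus small fixture builders. Everything here is deliberately naive.

# recursive/stack flood fill over a logical matrix; returns a label matrix
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 8)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        rr <- cur[1] + offs[k, 1]; cc <- cur[2] + offs[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# exposed-edge perimeter by scanning all four sides of every cell
perimeter_oracle <- function(mask, cell_size) {
  nr <- nrow(mask); nc <- ncol(mask)
  edges <- 0L
  for (r in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r, c0]) next
    if (r == 1 || !mask[r - 1, c0]) edges <- edges + 1L
    if (r == nr || !mask[r + 1, c0]) edges <- edges + 1L
    if (c0 == 1 || !mask[r, c0 - 1]) edges <- edges + 1L
    if (c0 == nc || !mask[r, c0 + 1]) edges <- edges + 1L
  }
  edges * cell_size
}

# O(n^2) nearest neighbor scan
nn_oracle <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) if (j != i)
      best <- min(best, sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2))
    out[i] <- best
  }
  out
}

# brute-force buffer reef area: distance from every reef cell centre to
# every focal patch cell centre
buffer_oracle <- function(cells, habitat, radius, include_self = FALSE) {
  mask <- habitat$values == habitat$class_map[["reef"]]
  nr <- nrow(mask); cs <- habitat$cell_size_m
  pr <- ((cells - 1) %% nr) + 1; pc <- ((cells - 1) %/% nr) + 1
  reef <- which(mask)
  if (!include_self) reef <- setdiff(reef, cells)
  count <- 0L
  for (idx in reef) {
    r <- ((idx - 1) %% nr) + 1; c0 <- ((idx - 1) %/% nr) + 1
    dmin <- min(sqrt((pr - r)^2 + (pc - c0)^2)) * cs
    if (dmin <= radius) count <- count + 1L
  }
  count * cs^2
}

# random habitat raster with reef blobs, for oracle comparisons
random_habitat <- function(nr, nc, p_reef = 0.12, cell_size = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(1L, nr, nc)
    m[matrix(runif(nr * nc) < p_reef, nr, nc)] <- 3L
    habitat_raster(m, cell_size)
  })
}

# one-row "scene" wrapper so metric helpers can be exercised in isolation
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(lagoon_width_m = 600, lagoon_height_m = 600, n_patches = 15,
         type1_channel_buffer_m = 250,
         type1_min_spacing_m = 50,
         type2_channel_annulus_m = c(60, 200),
         type1_area_range_m2 = c(500, 4000),
         type2_area_range_m2 = c(20, 400),
         n_sites = 12, rng_seed = 11),
    list(...))
  do.call(sim_config, args)
}

# naive one-way ANOSIM R from first principles (ranks of the full
# dissimilarity vector, Clarke's divisor n(n-1)/4)
anosim_r_oracle <- function(D, g) {
  D <- as.matrix(D)
  n <- nrow(D)
  iu <- which(upper.tri(D))
  rk <- rank(D[iu])
  same <- outer(g, g, "==")[iu]
  (mean(rk[!same]) - mean(rk[same])) / (n * (n - 1) / 4)
}
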