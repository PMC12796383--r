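# Independent oracles, deliberately written without reusing any package
# code path they are meant to check.

# Brute-force logistic least squares: coarse grid over the parameter box,
# then Nelder-Mead polish of the raw SSE.
oracle_logistic_sse <- function(t, v,
                                asym_range = c(max(v), 3 * max(v)),
                                tmid_range = c(60, 130),
                                scal_range = c(1, 40),
                                n_grid = 24) {
  sse <- function(p) {
    pred <- p[1] / (1 + exp((p[2] - t) / p[3]))
    sum((v - pred)^2)
  }
  grid <- expand.grid(
    Asym = seq(asym_range[1], asym_range[2], length.out = n_grid),
    tmid = seq(tmid_range[1], tmid_range[2], length.out = n_grid),
    scal = seq(scal_range[1], scal_range[2], length.out = n_grid))
  vals <- apply(grid, 1, sse)
  best <- as.numeric(grid[which.min(vals), ])
  pol <- optim(best, sse, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  pol <- optim(pol$par, sse, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  list(par = pol$par, sse = pol$value)
}

# Ward.D2 agglomeration by direct Lance-Williams recursion on unsquared
# Euclidean distances; returns the merge-height sequence.
oracle_ward_d2_heights <- function(mat) {
  n <- nrow(mat)
  d <- as.matrix(dist(mat, method = "euclidean"))
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestd <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      i <- active[a]; j <- active[b]
      if (d[i, j] < bestd) { bestd <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bestd)
    for (k in setdiff(active, c(i, j))) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      dn <- sqrt(((ni + nk) * d[i, k]^2 + (nj + nk) * d[j, k]^2 -
                    nk * d[i, j]^2) / (ni + nj + nk))
      d[i, k] <- d[k, i] <- dn
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  heights
}

# Hypergeometric upper tail P(X >= ov) by exhaustive enumeration.
oracle_hyper_tail <- function(ov, set_size, list_size, universe) {
  js <- ov:min(set_size, list_size)
  if (ov > min(set_size, list_size)) return(0)
  sum(choose(set_size, js) * choose(universe - set_size, list_size - js)) /
    choose(universe, list_size)
}

# Pearson r straight from the sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Default planted truths shared across tests: growth-curve parameters that
# decelerate from ~9%/h at 72 h to ~2%/h at 118 h, and a sensor with
# breakpoint 17.09% O2 and 4-fold range.
planted_growth <- list(Asym = 21.5, tmid = 104, scal = 10.6)
planted_sensor <- list(m = -3 / 12.09, k = 4 - 5 * (-3 / 12.09), c = 1)
# responsive levels of the default oxygen design that lie strictly below
# the planted breakpoint (the 18% level sits on the plateau)
sensor_linear_range <- c(5, 15)

planted_rate <- function(t, p = planted_growth) {
  v <- p$Asym / (1 + exp((p$tmid - t) / p$scal))
  (1 / p$scal) * (1 - v / p$Asym)
}
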