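# Fixtures are built in code. tiny_env() is a hand-written 5-patch,
# 2-stretch stream over `n_days` days with uniform geometry and constant
# series, small enough that every scheduler test runs in well under a
# second; small_synth_spec() scales the generator down for fast
# integration tests.

tiny_env <- function(n_days = 4, discharge = 1, prey = 5, pred_small = 0,
                     pred_large = 0, flowing = c(1, 1, 0, 1, 1),
                     temperature = 16) {
  np <- 5L
  patches <- data.frame(
    patch_id = 1:np, stretch_id = c(1, 1, 1, 2, 2),
    area = 30, upstream = c(NA, 1:4), downstream = c(2:5, NA),
    flowing_fraction = flowing, width = 5, slope = 0.001,
    n_base = 0.035, k_veg = 1, k_slack = 0
  )
  days <- 0:n_days
  global_series <- data.frame(
    day = days, temperature = temperature, discharge = discharge,
    sunrise = 6, sunset = 18
  )
  rows <- list()
  for (s in 1:2) {
    for (c in 1:10) {
      rows[[length(rows) + 1L]] <- data.frame(
        day = c(0, n_days), stretch_id = s, series = paste0("prey_", c),
        value = prey / 10
      )
    }
    rows[[length(rows) + 1L]] <- data.frame(
      day = c(0, n_days), stretch_id = s, series = "pred_small",
      value = pred_small
    )
    rows[[length(rows) + 1L]] <- data.frame(
      day = c(0, n_days), stretch_id = s, series = "pred_large",
      value = pred_large
    )
  }
  veg <- do.call(rbind, lapply(1:np, function(j) {
    data.frame(day = c(0, n_days), patch_id = j, cover = 0)
  }))
  env <- structure(list(
    patches = patches,
    global_series = global_series,
    stretch_series = do.call(rbind, rows),
    prey_categories = prey_categories_default(anchors_aquatic = c(1, 1, 1)),
    vegetation_series = veg
  ), class = "stream_env")
  validate_environment(env)
  env
}

tiny_init <- function(n_salmon = 4, n_trout1p = 2) {
  data.frame(
    stretch_id = c(1, 2),
    species = c("salmon", "trout"),
    cohort = c("YOY", "1+"),
    count = c(n_salmon, n_trout1p),
    mass_mean = c(3.5, 30), mass_sd = c(0.5, 5),
    tagged = c(2, 1)
  )
}

small_synth_spec <- function(seed = 11, ...) {
  synth_spec(
    n_stretches = 3, n_patches = 12, nf_days = 4, mlf_days = 2,
    init_per_stretch = data.frame(
      species = c("salmon", "trout"), cohort = c("YOY", "1+"),
      count = c(4, 2), mass_mean = c(3.5, 30), mass_sd = c(1, 6),
      tagged = c(2, 1)
    ),
    seed = seed, ...
  )
}

# independent piecewise-linear evaluator (test oracle for interpolation)
pw_linear_oracle <- function(times, values, t) {
  sapply(t, function(x) {
    if (x <= times[1]) return(values[1])
    n <- length(times)
    if (x >= times[n]) return(values[n])
    i <- max(which(times <= x))
    if (times[i] == x) return(values[i])
    values[i] + (values[i + 1] - values[i]) * (x - times[i]) /
      (times[i + 1] - times[i])
  })
}

# brute-force bisection solver of the Manning balance (hydrology oracle)
manning_bisection_oracle <- function(Q, w, S, n_eff, tol = 1e-10) {
  if (Q == 0) return(list(depth = 0, velocity = 0))
  f <- function(d) (w * sqrt(S) / n_eff) * d^(5 / 3) - Q
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  d <- (lo + hi) / 2
  list(depth = d, velocity = Q / (w * d))
}

# exhaustive-enumeration oracle for patch selection: the set of candidate
# indices a rule may legally return (ties are a set, not a draw)
select_patch_oracle <- function(potential, ratio, cmax, rule) {
  argmax <- function(x) which(x == max(x))
  argmin <- function(x) which(x == min(x))
  switch(rule,
    RANDOM = seq_along(potential),
    MCR = argmax(potential),
    MPR = argmin(ratio),
    CR_GT_PR = {
      reach <- which(potential >= cmax & cmax > 0)
      if (length(reach) == 0) {
        argmax(potential)
      } else {
        t1 <- reach[ratio[reach] == min(ratio[reach])]
        t1[potential[t1] == max(potential[t1])]
      }
    }
  )
}

# grid-search oracle for the feed/rest split: best achievable net energy
allocate_time_oracle <- function(potential, cmax, sc_feed, sc_rest,
                                 sda = 0.14, loss_frac = 0.31, rs = 0,
                                 rmax = Inf, grid = seq(0, 1, by = 0.01)) {
  net <- function(f) {
    gei <- min(f * potential, cmax)
    r <- min(rs + f * sc_feed + (1 - f) * sc_rest + sda * gei, rmax)
    (1 - loss_frac) * gei - r
  }
  vals <- sapply(grid, net)
  list(f = grid[which.max(vals)], net = max(vals), net_fun = net)
}
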