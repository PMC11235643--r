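# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are deliberately naive (explicit loops) so they share
# no code path with the implementation they check.

quiet_profile <- function(...) {
  athlete_profile(noise_sd_sr = 0, noise_sd_hr = 0, noise_sd_v = 0,
                  noise_sd_lactate = 0, noise_sd_step_hr = 0, ...)
}

flat_template <- function(duration = 300, sr = 20, intensity = 0.2, ...) {
  session_template(data.frame(duration_s = duration, target_sr = sr,
                              intensity = intensity), artifact_rate = 0, ...)
}

quiet_zone_model <- function(profile = quiet_profile()) {
  zone_model_from_test(generate_step_test(profile))
}

oracle_band <- function(x, lo, hi) {
  vapply(x, function(v) is.finite(v) && v >= lo && v <= hi, logical(1))
}

oracle_trailing_mean <- function(v, w) {
  vapply(seq_along(v), function(i) mean(v[max(1, i - w + 1):i]), numeric(1))
}

oracle_gradient <- function(time_s, sr, vel, sr_delta = 1.5, sr_lag = 5,
                            vel_delta = 0.2, vel_lag = 3,
                            connective = "and") {
  keep <- logical(length(time_s))
  for (i in seq_along(time_s)) {
    j <- which(time_s == time_s[i] - sr_lag)
    k <- which(time_s == time_s[i] - vel_lag)
    c1 <- length(j) == 1 && abs(sr[i] - sr[j]) >= sr_delta
    c2 <- length(k) == 1 && abs(vel[i] - vel[k]) >= vel_delta
    rm <- if (connective == "and") c1 && c2 else c1 || c2
    keep[i] <- !rm
  }
  keep
}

oracle_min_run <- function(labels, min_run = 15) {
  n <- length(labels)
  keep <- logical(n)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && labels[j + 1] == labels[i]) j <- j + 1
    keep[i:j] <- (j - i + 1) >= min_run
    i <- j + 1
  }
  keep
}

# Pearson r from the raw covariance formula.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# First-crossing and D-max argmax by exhaustive scan over a fitted curve.
oracle_lt1_scan <- function(curve, rise = 0.4, step = 0.1) {
  grid <- seq(curve$range[1], curve$range[2], by = step)
  thr <- curve$predict(curve$range[1]) + rise
  grid[which(curve$predict(grid) >= thr)[1]]
}

oracle_lt2_scan <- function(curve, lt1_power, step = 0.1) {
  pn <- curve$range[2]
  grid <- seq(lt1_power, pn, by = step)
  if (grid[length(grid)] < pn) grid <- c(grid, pn)
  x1 <- lt1_power; y1 <- curve$predict(lt1_power)
  x2 <- pn; y2 <- curve$predict(pn)
  best_d <- -Inf; best_p <- NA
  for (p in grid) {
    la <- curve$predict(p)
    d <- abs((y2 - y1) * p - (x2 - x1) * la + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
    if (d > best_d + 1e-12) { best_d <- d; best_p <- p }
  }
  best_p
}

# Random 600 s raw fixture with steady spells, spikes and gaps.
random_fixture <- function(seed) {
  set.seed(seed)
  n <- 600
  time_s <- sort(sample(0:799, n))
  sr <- runif(n, 5, 55)
  vel <- runif(n, 0, 8)
  hr <- runif(n, 90, 205)
  zones <- sample(paste0("T", 1:5), n, replace = TRUE,
                  prob = c(0.4, 0.25, 0.15, 0.1, 0.1))
  # inject steady runs so the min-run filter sees both outcomes
  for (k in 1:5) {
    i <- sample(1:(n - 30), 1)
    zones[i:(i + sample(5:25, 1))] <- sample(paste0("T", 1:5), 1)
  }
  list(time_s = time_s, sr = sr, vel = vel, hr = hr, zones = zones)
}
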