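# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: raw loops, text scans and closed forms.

# brute-force outcome scan over raw event-log text lines
oracle_outcomes_from_lines <- function(lines) {
  t_ms <- as.numeric(sub('.*"t_ms":([-0-9.]+).*', "\\1", lines))
  kind <- sub('.*"kind":"([A-Z_]+)".*', "\\1", lines)
  trial <- suppressWarnings(
    as.integer(sub('.*"trial_index":([0-9]+|null)\\}', "\\1", lines)))
  ids <- sort(unique(trial[kind == "PERT_OFF" & !is.na(trial)]))
  res <- lapply(ids, function(i) {
    off <- t_ms[kind == "PERT_OFF" & !is.na(trial) & trial == i]
    rew <- t_ms[kind == "REWARD" & !is.na(trial) & trial == i]
    data.frame(trial_index = i, success = any(rew > off),
               droplets = length(rew))
  })
  do.call(rbind, res)
}

# numeric-integration oracle for the truncated exponential mean
oracle_trunc_exp_mean <- function(m, lo, hi) {
  f <- function(x) exp(-x / m) / m
  z <- stats::integrate(f, lo, hi)$value
  stats::integrate(function(x) x * f(x) / z, lo, hi)$value
}

# per-frame hand computation of nose-spout distance
oracle_frame_distances <- function(pose) {
  out <- numeric(nrow(pose))
  for (i in seq_len(nrow(pose))) {
    dx <- pose$nose_x[i] - pose$spout_x[i]
    dy <- pose$nose_y[i] - pose$spout_y[i]
    out[i] <- sqrt(dx * dx + dy * dy)
  }
  out
}

# simple loop oracle for a centered (trailing-on-even) moving proportion
oracle_sliding <- function(x, w) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - floor(w / 2))
    hi <- min(n, i + floor((w - 1) / 2))
    out[i] <- mean(x[lo:hi])
  }
  out
}

# a minimal synthetic pose frame builder on the 5-ms grid
make_pose <- function(t_ms, dist_px, spout = c(400, 150),
                      lik = rep(1, length(t_ms))) {
  u <- c(1, 0)
  data.frame(frame = seq_along(t_ms) - 1L, t_ms = t_ms,
             nose_x = spout[1] + u[1] * dist_px,
             nose_y = spout[2] + u[2] * dist_px,
             nose_likelihood = lik,
             spout_x = spout[1], spout_y = spout[2],
             spout_likelihood = 1)
}
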