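# Independent oracles used across the test files. These deliberately use
# naive direct computation (loops, closed forms) so they share no code with
# the implementation paths they check.

# direct mask-aware normalized 2-D convolution of one frame
oracle_conv2d <- function(img, kern) {
  ny <- nrow(img); nx <- ncol(img)
  h <- (nrow(kern) - 1L) %/% 2L
  out <- img * NA_real_
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (!is.finite(img[i, j])) next
    acc <- 0; wsum <- 0
    for (di in -h:h) for (dj in -h:h) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > ny || jj < 1 || jj > nx) next
      if (!is.finite(img[ii, jj])) next
      w <- kern[di + h + 1L, dj + h + 1L]
      acc <- acc + w * img[ii, jj]
      wsum <- wsum + w
    }
    out[i, j] <- acc / wsum
  }
  out
}

# closed-form simple linear regression
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  ss_res <- sum((y - a - b * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = a, slope = b, r2 = 1 - ss_res / ss_tot)
}

# exhaustive integer-lag normalized cross-correlation argmax
oracle_best_lag <- function(a, b, max_lag) {
  a <- a - mean(a); b <- b - mean(b)
  n <- length(a)
  best <- -Inf; best_lag <- 0L
  for (lag in -max_lag:max_lag) {
    ia <- max(1, 1 - lag):min(n, n - lag)
    cc <- sum(a[ia] * b[ia + lag])
    if (cc > best) { best <- cc; best_lag <- lag }
  }
  best_lag
}

# per-second majority behavior label over [t0, t1)
oracle_dominant <- function(track, t0, t1, step = 0.25) {
  mids <- seq(t0 + step / 2, t1 - step / 2, by = step)
  labs <- vapply(mids, function(m) {
    i <- which(track$start <= m & track$end > m)
    if (length(i)) track$label[i[1]] else NA_character_
  }, character(1))
  tab <- sort(table(labs), decreasing = TRUE)
  names(tab)[1]
}

# connected components of cross-channel interval overlaps (>= min_ov)
oracle_bilateral_components <- function(left, right, min_ov) {
  left$ch <- rep("L", nrow(left)); right$ch <- rep("R", nrow(right))
  ev <- rbind(left, right)
  n <- nrow(ev)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || ev$ch[i] == ev$ch[j]) next
    ov <- min(ev$offset[i], ev$offset[j]) - max(ev$onset[i], ev$onset[j])
    if (ov >= min_ov) adj[i, j] <- TRUE
  }
  comp <- rep(NA_integer_, n); cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  split(ev, comp)
}

# small noiseless scene shared by several tests
tiny_scene <- function(seed = 1L, noise = 0, nx = 32, ny = 32,
                       duration = 80, rate = 2) {
  scene_config(nx = nx, ny = ny, frame_rate = rate, duration = duration,
               noise_sigma = rep(noise, 4), seed = seed)
}
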