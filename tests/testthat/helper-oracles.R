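# Independent brute-force oracles. These deliberately use naive loops and
# direct definitions, sharing no code with the package internals.

# population z-score; NULL if degenerate
oracle_norm <- function(x) {
  mu <- mean(x); s <- sqrt(mean((x - mu)^2))
  if (s == 0) return(NULL)
  (x - mu) / s
}

# zero-lag correlation by direct sum
oracle_sci <- function(x1, x2) {
  z1 <- oracle_norm(x1); z2 <- oracle_norm(x2)
  if (is.null(z1) || is.null(z2)) return(NA_real_)
  s <- 0
  for (i in seq_along(z1)) s <- s + z1[i] * z2[i]
  s / length(z1)
}

# PSP by explicit lag loop + direct DFT (no fft)
oracle_psp <- function(x1, x2) {
  z1 <- oracle_norm(x1); z2 <- oracle_norm(x2)
  if (is.null(z1) || is.null(z2)) return(NA_real_)
  N <- length(z1)
  lags <- -(N - 1):(N - 1)
  cc <- numeric(length(lags))
  for (li in seq_along(lags)) {
    k <- lags[li]; acc <- 0; cnt <- 0
    for (n in 1:N) {
      m <- n + k
      if (m >= 1 && m <= N) { acc <- acc + z1[n] * z2[m]; cnt <- cnt + 1 }
    }
    cc[li] <- acc / cnt
  }
  M <- length(cc)
  best <- -Inf
  for (j in 1:(M %/% 2)) {          # positive frequencies, DC excluded
    re <- 0; im <- 0
    for (k in 1:M) {
      ang <- -2 * pi * j * (k - 1) / M
      re <- re + cc[k] * cos(ang)
      im <- im + cc[k] * sin(ang)
    }
    p <- 2 * (re^2 + im^2) / M^2
    if (p > best) best <- p
  }
  best
}

# motion flags by per-sample exhaustive window scan + dilation
oracle_motion_flags <- function(d, fs, tMotion = 1, tMask = 1,
                                stdev_thresh = 15, amp_thresh = 0.4) {
  n <- length(d)
  w <- round(tMotion * fs)
  dd <- diff(d)
  sd_diff <- sqrt(mean((dd - mean(dd))^2))
  det <- rep(FALSE, n)
  for (i in 1:n) {
    for (j in max(1, i - w + 1):min(i, n - w + 1)) {
      if (j < 1 || j + w - 1 > n) next
      win <- d[j:(j + w - 1)]
      rng <- max(win) - min(win)
      if (rng > amp_thresh || rng > stdev_thresh * sd_diff) {
        det[i] <- TRUE; break
      }
    }
  }
  m <- round(tMask * fs)
  out <- rep(FALSE, n)
  for (i in which(det)) out[max(1, i - m):min(n, i + m)] <- TRUE
  out
}

# small two-wavelength recording from explicit per-wavelength matrices
make_recording <- function(w1, w2, fs = 10, metadata = list()) {
  stopifnot(all(dim(w1) == dim(w2)))
  I <- array(0, dim = c(nrow(w1), ncol(w1), 2))
  I[, , 1] <- w1; I[, , 2] <- w2
  raw_recording(I, fs, c(780, 850), metadata)
}

# constant-plus-cardiac channel matrix: ns samples x nc channels
cardiac_matrix <- function(ns, nc, fs = 10, f = 2, amp = 0.02, base = 1) {
  t <- (seq_len(ns) - 1) / fs
  matrix(rep(base * (1 + amp * sin(2 * pi * f * t)), nc), ncol = nc)
}

# numeric vector with prescribed population mean and sd (two-point signal)
signal_with_cv <- function(mu, cv, n = 100) {
  s <- cv * abs(mu)
  mu + s * rep(c(-1, 1), length.out = n)
}
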