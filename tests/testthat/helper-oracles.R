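# Independent oracles used across tests. These deliberately reimplement the
# quantities by brute force / closed form, without touching the package's own
# code paths.

# Exact one-tailed rank-sum p by full enumeration of all C(n, nx) rank
# assignments (no ties assumed).
enumerate_ranksum_p <- function(x, y, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  w_obs <- sum(rank(pooled)[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  w_all <- colSums(matrix(seq_len(nx + ny)[combos], nrow = nx))
  if (direction == "less") mean(w_all <= w_obs) else mean(w_all >= w_obs)
}

# Brute-force Benjamini-Hochberg step-up: find the largest k with
# p_(k) <= k q / n and flag everything at or below p_(k).
bruteforce_bh <- function(p, q = 0.05) {
  n <- length(p)
  if (n == 0L) return(logical(0))
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in seq_len(n)) if (ps[i] <= i * q / n) k <- i
  flags <- logical(n)
  if (k > 0L) flags[o[seq_len(k)]] <- TRUE
  flags
}

# Dense spherical-spline CSD oracle: build G and H from pracma's Legendre
# functions and solve the constrained system per sample with an augmented
# dense solve (independent of the package's precomputed-operator path).
oracle_csd <- function(positions, v, m = 4, lambda = 1e-5, nterms = 50) {
  n <- nrow(positions)
  cosang <- tcrossprod(positions)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  G <- matrix(0, n, n); H <- matrix(0, n, n)
  for (l in seq_len(nterms)) {
    Pl <- matrix(pracma::legendre(l, as.vector(cosang))[1L, ], n, n)
    G <- G + (2 * l + 1) / (l * (l + 1))^m * Pl / (4 * pi)
    H <- H + (2 * l + 1) / (l * (l + 1))^(m - 1) * Pl / (4 * pi)
  }
  A <- rbind(cbind(G + diag(lambda, n), rep(1, n)), c(rep(1, n), 0))
  sol <- solve(A, c(v, 0))
  as.vector(H %*% sol[seq_len(n)])
}

# Wrap-then-map psi oracle via the complex argument.
oracle_psi <- function(theta1, theta2)
  1 - abs(Arg(exp(1i * (theta1 - theta2)))) / pi

# Minimal phase_series constructor for statistic-level tests.
make_phase_series <- function(values, fs = 10, channel = "X",
                              carrier_band = "theta",
                              envelope_band = "infraslow",
                              valid = rep(TRUE, length(values))) {
  structure(list(values = values, fs = fs, valid = valid,
                 low_amp = rep(FALSE, length(values)), t0 = 0,
                 channel = channel, carrier_band = carrier_band,
                 envelope_band = envelope_band),
            class = "phase_series")
}

# Small deterministic recording with alternating conditions.
make_test_recording <- function(nch = 2, duration = 60, fs = 500,
                                freq = 10, seed = 1) {
  set.seed(seed)
  t <- (seq_len(duration * fs) - 1) / fs
  data <- t(vapply(seq_len(nch), function(i)
    sin(2 * pi * freq * t + i) + 0.1 * rnorm(length(t)), numeric(length(t))))
  n_seg <- max(2, floor(duration / 30))
  seg <- duration / n_seg
  iv <- data.frame(start = seg * (seq_len(n_seg) - 1),
                   end = seg * seq_len(n_seg),
                   condition = rep(c("eyes_closed", "eyes_open"),
                                   length.out = n_seg))
  recording(data, fs, paste0("CH", seq_len(nch)), intervals = iv)
}

# Uniform random phases in (-pi, pi]
runif_phase <- function(n) stats::runif(n, -pi, pi)
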