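test_that("psi maps phase differences onto [0, 1] with the stated boundaries", {
  n <- 500
  th <- make_phase_series(runif_phase(n))
  expect_equal(psi(th, th)$values, rep(1, n))

  th2 <- make_phase_series(Arg(exp(1i * (th$values + pi))))
  expect_equal(psi(th, th2)$values, rep(0, n), tolerance = 1e-12)

  a <- make_phase_series(rep(0, 4))
  b <- make_phase_series(rep(pi / 2, 4))
  expect_equal(psi(a, b)$values, rep(0.5, 4))

  # wrap-around: theta1 = -3, theta2 = +3 -> delta = 2 pi - 6
  w1 <- make_phase_series(rep(-3, 3))
  w2 <- make_phase_series(rep(3, 3))
  expect_equal(psi(w1, w2)$values, rep(1 - (2 * pi - 6) / pi, 3),
               tolerance = 1e-12)
  expect_equal(psi(w1, w2)$values, oracle_psi(w1$values, w2$values),
               tolerance = 1e-12)
})

test_that("psi is symmetric, offset-invariant and validates inputs", {
  set.seed(11)
  a <- make_phase_series(runif_phase(300))
  b <- make_phase_series(runif_phase(300))
  expect_identical(psi(a, b)$values, psi(b, a)$values)
  # adding a common offset (with wrapping) leaves psi unchanged
  off <- 2.1
  a2 <- make_phase_series(Arg(exp(1i * (a$values + off))))
  b2 <- make_phase_series(Arg(exp(1i * (b$values + off))))
  expect_equal(psi(a2, b2)$values, psi(a, b)$values, tolerance = 1e-12)
  # psi against the independent oracle on random draws
  expect_equal(psi(a, b)$values, oracle_psi(a$values, b$values),
               tolerance = 1e-12)
  short <- make_phase_series(runif_phase(10))
  expect_error(psi(a, short), "length")
  slowband <- make_phase_series(runif_phase(300), envelope_band = "slow")
  expect_error(psi(a, slowband), "envelope band")
})

test_that("m_psi takes the per-condition median with the even-length convention", {
  iv <- data.frame(start = 0, end = 1, condition = "eyes_closed")
  p3 <- structure(list(values = c(0.2, 0.4, 0.9), valid = rep(TRUE, 3),
                       fs = 10, t0 = 0, pair = c("A", "B"),
                       carrier_band = "theta", envelope_band = "infraslow"),
                  class = "psi_series")
  expect_equal(m_psi(p3, iv, "eyes_closed")$m_psi, 0.4)
  p4 <- p3; p4$values <- c(0.2, 0.4, 0.9, 1.0); p4$valid <- rep(TRUE, 4)
  expect_equal(m_psi(p4, iv, "eyes_closed")$m_psi, 0.65)
  expect_equal(m_psi(p4, iv, "eyes_closed")$n_samples, 4)
  expect_error(m_psi(p4, iv, "eyes_open"), "no valid psi samples")
})

test_that("null psi medians approach one half for independent uniform phases", {
  # 600 s at the decimated 10 Hz rate; phases as slow independent walks
  set.seed(21)
  meds <- replicate(12, {
    w1 <- Arg(exp(1i * cumsum(c(runif(1, -pi, pi), rnorm(5999, 0, 0.07)))))
    w2 <- Arg(exp(1i * cumsum(c(runif(1, -pi, pi), rnorm(5999, 0, 0.07)))))
    iv <- data.frame(start = 0, end = 600, condition = "eyes_closed")
    m_psi(psi(make_phase_series(w1), make_phase_series(w2)), iv,
          "eyes_closed")$m_psi
  })
  expect_equal(median(meds), 0.5, tolerance = 0.1)
})

test_that("pairwise M-psi tables are complete and validated", {
  set.seed(31)
  n <- 400
  vals <- matrix(runif_phase(4 * n), 4, n,
                 dimnames = list(paste0("CH", 1:4), NULL))
  ph <- structure(list(values = vals, fs = 10,
                       valid = matrix(TRUE, 4, n), low_amp = matrix(FALSE, 4, n),
                       t0 = 0, channel = NA, carrier_band = "theta",
                       envelope_band = "infraslow"),
                  class = "phase_series")
  phases <- list(theta = list(infraslow = ph))
  iv <- data.frame(start = c(0, 20), end = c(20, 40),
                   condition = c("eyes_closed", "eyes_open"))
  tab <- pairwise_mpsi(phases, intervals = iv, participant = "s1")
  expect_equal(nrow(tab), 6 * 2)    # 4C2 pairs x 2 conditions
  expect_true(all(tab$m_psi >= 0 & tab$m_psi <= 1))
  expect_true(all(tab$n_samples > 0))
  bad <- data.frame(channel_a = "CH1", channel_b = "CH1")
  expect_error(pairwise_mpsi(phases, pairs = bad, intervals = iv),
               "duplicated channel")
  ghost <- data.frame(channel_a = "CH1", channel_b = "CH9")
  expect_error(pairwise_mpsi(phases, pairs = ghost, intervals = iv),
               "no phases for")
})

test_that("a 60-channel table has one row per pair, band and condition", {
  set.seed(32)
  labels <- analysis_channels()
  n <- 200
  vals <- matrix(runif_phase(60 * n), 60, n, dimnames = list(labels, NULL))
  ph <- structure(list(values = vals, fs = 10,
                       valid = matrix(TRUE, 60, n),
                       low_amp = matrix(FALSE, 60, n),
                       t0 = 0, channel = NA, carrier_band = "alpha",
                       envelope_band = "infraslow"),
                  class = "phase_series")
  iv <- data.frame(start = 0, end = 20, condition = "eyes_open")
  tab <- pairwise_mpsi(list(alpha = list(infraslow = ph)), intervals = iv,
                       conditions = "eyes_open")
  expect_equal(nrow(tab), 1770)
  expect_equal(anyDuplicated(tab[, c("channel_a", "channel_b")]), 0)
})

test_that("M-psi tables round-trip through CSV with fixed column order", {
  tab <- data.frame(participant = "s1", channel_a = "A", channel_b = "B",
                    carrier_band = "theta", envelope_band = "infraslow",
                    condition = "eyes_closed", m_psi = 0.5, n_samples = 10L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_mpsi(tab, f)
  expect_equal(readLines(f)[1],
               "participant,channel_a,channel_b,carrier_band,envelope_band,condition,m_psi,n_samples")
  expect_equal(read_mpsi(f)$m_psi, 0.5)
})
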