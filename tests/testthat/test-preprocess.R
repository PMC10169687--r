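test_that("edge trimming shifts data and intervals consistently", {
  rec <- make_test_recording(nch = 2, duration = 300, fs = 100)
  tr <- trim_edges(rec, 10)
  expect_equal(ncol(tr$data) / tr$fs, 280)
  # an interval (5, 15) becomes (0, 5) after a 10 s trim
  rec2 <- recording(matrix(rnorm(3000), 1, 3000), 100, "A",
                    intervals = data.frame(start = 5, end = 15,
                                           condition = "eyes_open"))
  tr2 <- trim_edges(rec2, 10)
  expect_equal(tr2$intervals$start, 0)
  expect_equal(tr2$intervals$end, 5)
  short <- recording(matrix(rnorm(1500), 1, 1500), 100, "A")
  expect_error(trim_edges(short, 10), "too short")
})

test_that("band-pass design follows the order rule and is linear phase", {
  spec <- design_bandpass(3, 7, 500)
  expect_equal(spec$n_taps, 1163)
  expect_equal(design_bandpass(0.05, 0.1, 500)$n_taps, 70001)
  expect_equal(design_bandpass(0.05, 0.1, 10)$n_taps, 1401)
  # palindromic coefficients = exactly linear phase
  expect_equal(spec$b, rev(spec$b))
  # magnitude about 1 at the geometric band centre, strong stop-band
  f_geo <- sqrt(3 * 7)
  expect_equal(Mod(fir_response(spec, f_geo)), 1, tolerance = 0.05)
  expect_lt(20 * log10(Mod(fir_response(spec, 1.5))), -20)
  expect_error(design_bandpass(0, 7, 500), "f_lo")
  expect_error(design_bandpass(3, 250, 500), "Nyquist")
  expect_error(design_bandpass(7, 3, 500), "f_lo < f_hi")
})

test_that("zero-phase filtering preserves in-band sinusoids without lag", {
  fs <- 500
  t <- (0:(fs * 20 - 1)) / fs
  spec <- design_bandpass(3, 7, fs)
  y5 <- filtfilt_zero_phase(sin(2 * pi * 5 * t), spec)
  i <- 3000:7000
  expect_equal(max(abs(y5[i])), 1, tolerance = 0.02)
  cc <- stats::ccf(y5[i], sin(2 * pi * 5 * t)[i], lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # stop-band sinusoid annihilated
  y20 <- filtfilt_zero_phase(sin(2 * pi * 20 * t), spec)
  expect_lt(max(abs(y20[i])), 0.01)
  # DC maps to ~0 through any band-pass
  ydc <- filtfilt_zero_phase(rep(1, length(t)), spec)
  expect_lt(max(abs(ydc[i])), 1e-4)
  expect_error(filtfilt_zero_phase(rnorm(100), spec), "longer than the filter")
})

test_that("anti-aliased decimation preserves infraslow content", {
  fs <- 500
  t <- (0:(fs * 300 - 1)) / fs
  x <- cos(2 * pi * 0.07 * t) + 0.3 * sin(2 * pi * 40 * t)
  dec <- decimate_signal(x, fs, 10)
  expect_equal(dec$fs, 10)
  expect_equal(length(dec$values), length(x) / 50)
  td <- (seq_along(dec$values) - 1) / 10
  i <- (dec$n_edge + 50):(length(dec$values) - dec$n_edge - 50)
  expect_equal(dec$values[i], cos(2 * pi * 0.07 * td)[i], tolerance = 0.01)
  expect_error(decimate_signal(x, 500, 7), "integer multiple")
})

test_that("surface Laplacian annihilates constants and is linear and equivariant", {
  m <- standard_montage()
  rec <- recording(matrix(1, 60, 50), 500, rownames(m$positions))
  out <- surface_laplacian(rec, m)
  expect_lt(max(abs(out$data)), 1e-8)

  set.seed(4)
  x <- matrix(rnorm(60 * 20), 60, 20)
  y <- matrix(rnorm(60 * 20), 60, 20)
  recx <- recording(x, 500, rownames(m$positions))
  recy <- recording(y, 500, rownames(m$positions))
  reczy <- recording(2 * x - 3 * y, 500, rownames(m$positions))
  lx <- surface_laplacian(recx, m)$data
  ly <- surface_laplacian(recy, m)$data
  lzy <- surface_laplacian(reczy, m)$data
  expect_equal(lzy, 2 * lx - 3 * ly, tolerance = 1e-9)

  # permuting channel order permutes the result
  perm <- sample(60)
  recp <- recording(x[perm, ], 500, rownames(m$positions)[perm])
  lp <- surface_laplacian(recp, m)$data
  expect_equal(lp, lx[perm, ], tolerance = 1e-9)

  # coincident electrodes are rejected
  pos <- m$positions
  pos[2, ] <- pos[1, ]
  expect_error(csd_transform_matrix(pos), "coincident")
})

test_that("surface Laplacian reproduces a low-degree spherical-harmonic eigenpattern", {
  m <- standard_montage()
  z <- m$positions[, 3]
  v <- 0.5 * (5 * z^3 - 3 * z)        # degree-3 zonal harmonic
  got <- as.vector(csd_transform_matrix(m$positions) %*% v)
  cosine <- sum(got * v) / sqrt(sum(got^2) * sum(v^2))
  expect_gt(cosine, 0.99)
  # and agrees with an independent dense-solve oracle
  # the regularised system is ill-conditioned, so the two solve routes agree
  # to ~1e-6 relative, not machine precision
  want <- oracle_csd(m$positions, v)
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("amplitude spectrum locates spectral peaks", {
  fs <- 500
  t <- (0:(fs * 10 - 1)) / fs
  sp <- amplitude_spectrum(sin(2 * pi * 10 * t), fs)
  expect_equal(sp$freq[which.max(sp$magnitude)], 10)
  sp2 <- amplitude_spectrum(sin(2 * pi * 5 * t) + sin(2 * pi * 10 * t), fs)
  top2 <- sort(sp2$freq[order(sp2$magnitude, decreasing = TRUE)[1:2]])
  expect_equal(top2, c(5, 10))
  expect_error(amplitude_spectrum(1, fs), "at least 2")
})

test_that("band peak check compares central and peripheral frequencies", {
  fs <- 500
  t <- (0:(fs * 20 - 1)) / fs
  set.seed(9)
  x <- 3 * sin(2 * pi * 10 * t) + rnorm(length(t))
  sp <- amplitude_spectrum(x, fs)
  expect_true(band_peak_check(sp$freq, sp$magnitude, "alpha"))
  # analytically flat spectrum fails the strict inequality
  flat <- list(freq = seq(0, 30, by = 0.5), magnitude = rep(1, 61))
  expect_false(band_peak_check(flat$freq, flat$magnitude, "alpha"))
  expect_error(band_peak_check(c(0, 1), c(1, 1), "alpha"), "cover")
  # white noise: the check is a coin flip in the long run
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    sp <- amplitude_spectrum(rnorm(fs * 4), fs)
    band_peak_check(sp$freq, sp$magnitude, "alpha")
  }, logical(1))
  expect_gt(mean(hits), 0.25)
  expect_lt(mean(hits), 0.75)
})
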