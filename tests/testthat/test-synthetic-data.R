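test_that("configuration invariants are enforced", {
  expect_error(simulation_config(modulation_depth = 1), "modulation_depth")
  expect_error(simulation_config(condition_schedule = rep(10, 2)),
               "fewer than 3 modulation cycles")
  expect_error(simulation_config(kappa_base = -1), "kappa_base")
  expect_error(coupling_rule("theta", -1, channels = "CZ"), "kappa")
  expect_error(coupling_rule("theta", 1), "regions")
  expect_warning(
    cohort_config(c(Control = 2, cMDD = 0),
                  base_config = simulation_config(),
                  effect_map = list(cMDD = list(
                    coupling_rule("theta", 0, channels = "CZ")))),
    "empty group")
  expect_error(cohort_config(c(Control = 2, Banana = 2)), "unknown group")
})

test_that("generation is deterministic and condition intervals tile the duration", {
  cfg <- simulation_config(channel_labels = c("A", "B", "C"),
                           bands = carrier_bands()["theta"],
                           condition_schedule = rep(15, 4), seed = 5)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$data, r2$data)
  r3 <- generate_recording(cfg, seed = 6)
  expect_false(identical(r1$data, r3$data))
  iv <- r1$intervals
  expect_equal(iv$start[1], 0)
  expect_equal(iv$end[nrow(iv)], 60)
  expect_equal(iv$start[-1], iv$end[-nrow(iv)])
  expect_equal(rec_duration(r1), 60)
  expect_equal(r1$channel_labels, c("A", "B", "C"))
})

test_that("cohort bookkeeping matches the requested design", {
  co <- suppressWarnings(default_cohort_config(
    c(Control = 4, cMDD = 3, pMDD = 3), seed = 2))
  pt <- cohort_participants(co)
  expect_equal(nrow(pt), 10)
  expect_equal(as.vector(table(pt$group)[c("Control", "cMDD", "pMDD")]),
               c(4, 3, 3))
  expect_false(any(duplicated(pt$participant_id)))
  expect_false(any(duplicated(pt$seed)))
  # BDI scores respect the grouping thresholds
  expect_true(all(pt$bdi[pt$group == "Control"] <= 7))
  expect_true(all(pt$bdi[pt$group != "Control"] >= 13))
  derived <- classify_participant(pt$bdi, pt$clinical)
  expect_true(all(derived[pt$group == "Control"] == "Control"))
  expect_true(all(derived[pt$group == "cMDD"] == "Depressive-cMDD"))
  # pure function of the configuration
  expect_identical(pt, cohort_participants(co))
  rec1 <- generate_participant_recording(co, 1)
  expect_identical(rec1$data, generate_participant_recording(co, pt[1, ])$data)
})

test_that("group effect rules override the base coupling", {
  co <- suppressWarnings(default_cohort_config(c(Control = 1, cMDD = 1)))
  base <- co$base_config
  eff <- eegpsi:::apply_effect(base, co$effect_map$cMDD)
  K_ctl <- eegpsi:::resolve_kappa(base, "theta")
  K_pat <- eegpsi:::resolve_kappa(eff, "theta")
  expect_equal(K_ctl["FC1", "eyes_closed"], 10)
  expect_equal(K_pat["FC1", "eyes_closed"], 0)
  expect_equal(K_pat["FC1", "eyes_open"], 10)    # deficit is eyes-closed only
  expect_equal(K_pat["PZ", "eyes_closed"], 1)    # baseline untouched
  K_alpha <- eegpsi:::resolve_kappa(eff, "alpha")
  expect_equal(K_alpha["O1", "eyes_open"], 10)   # other band untouched
})

test_that("generated envelopes fluctuate inside the infraslow band", {
  cfg <- simulation_config(channel_labels = "A",
                           bands = carrier_bands()["alpha"],
                           coupling = list(coupling_rule("alpha", 50,
                                                         channels = "A")),
                           noise_scale = 0.1,
                           condition_schedule = rep(30, 10), seed = 3)
  rec <- generate_recording(cfg)
  spec <- design_bandpass(8, 12, rec$fs)
  env <- analytic_envelope(filtfilt_zero_phase(rec$data[1, ], spec), rec$fs)
  dec <- decimate_signal(env$values, rec$fs, 10)
  fl <- dec$values - mean(dec$values)
  sp <- amplitude_spectrum(fl, 10)
  keep <- sp$freq > 0.02 & sp$freq < 1
  peak <- sp$freq[keep][which.max(sp$magnitude[keep])]
  expect_gte(peak, 0.05)
  expect_lte(peak, 0.1)
})

test_that("downstream M-psi increases monotonically with the coupling kappa", {
  kappas <- c(0, 1, 5, 20)
  mean_mpsi <- matrix(NA_real_, 2, length(kappas))
  for (s in 1:2) for (k in seq_along(kappas)) {
    cfg <- simulation_config(
      channel_labels = paste0("CH", 1:4),
      bands = carrier_bands()["theta"],
      coupling = list(coupling_rule("theta", kappas[k],
                                    channels = paste0("CH", 1:4))),
      kappa_base = 0, condition_schedule = rep(30, 20), seed = 60 + s)
    mm <- compute_mpsi(generate_recording(cfg), bands = "theta",
                       env_bands = "infraslow", csd = FALSE)
    mean_mpsi[s, k] <- mean(mm$m_psi)
  }
  for (s in 1:2) {
    rho <- cor(kappas, mean_mpsi[s, ], method = "spearman")
    expect_gt(rho, 0.9)
    expect_true(all(diff(mean_mpsi[s, ]) > -0.02))
  }
})

test_that("extreme coupling forces near-perfect spatial correlation", {
  cfg <- simulation_config(
    channel_labels = paste0("CH", 1:3),
    bands = carrier_bands()["theta"],
    coupling = list(coupling_rule("theta", 1000, channels = paste0("CH", 1:3))),
    modulation_depth = 0.5, noise_scale = 0,
    condition_schedule = rep(30, 12), seed = 8)
  mm <- compute_mpsi(generate_recording(cfg), bands = "theta",
                     env_bands = "infraslow", csd = FALSE)
  expect_true(all(mm$m_psi > 0.95))
})
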