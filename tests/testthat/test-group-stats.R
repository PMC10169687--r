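test_that("one-tailed rank-sum p equals full enumeration for small samples", {
  expect_equal(ranksum_one_tailed(c(1, 2), c(3, 4), "less"), 1 / 6,
               tolerance = 1e-12)
  set.seed(41)
  for (nx in 1:5) for (ny in seq_len(10 - nx)) {
    x <- rnorm(nx); y <- rnorm(ny)
    for (dir in c("less", "greater")) {
      expect_equal(ranksum_one_tailed(x, y, dir),
                   enumerate_ranksum_p(x, y, dir),
                   tolerance = 1e-12,
                   info = sprintf("nx=%d ny=%d %s", nx, ny, dir))
    }
  }
})

test_that("rank-sum handles nulls, ties and degenerate samples", {
  expect_warning(p <- ranksum_one_tailed(rep(1, 5), rep(1, 4)), "degenerate")
  expect_equal(p, 0.5)
  # under the null the mean one-tailed p is about one half
  set.seed(42)
  base <- rnorm(40)
  ps <- replicate(100, {
    sh <- sample(base)
    ranksum_one_tailed(sh[1:20], sh[21:40], "less")
  })
  expect_equal(mean(ps), 0.5, tolerance = 0.05)
  # a one-s.d. downward shift at n = 30 is detected most of the time
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    ranksum_one_tailed(rnorm(30, -1), rnorm(30), "less") < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  expect_error(ranksum_one_tailed(numeric(0), 1:3), "non-empty")
})

test_that("BH flags match hand computations and a brute-force oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.04)), rep(TRUE, 3))
  expect_equal(fdr_bh(c(0.01, 0.2, 0.9)), c(TRUE, FALSE, FALSE))
  expect_equal(fdr_bh(0.9), FALSE)
  expect_equal(fdr_bh(numeric(0)), logical(0))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  grid <- c(0.001, 0.011, 0.024, 0.049, 0.051, 0.2, 0.6, 0.97)
  for (len in 1:3) {
    combos <- expand.grid(rep(list(grid), len))
    for (i in seq_len(nrow(combos))) {
      p <- as.numeric(combos[i, ])
      expect_equal(fdr_bh(p), bruteforce_bh(p),
                   info = paste(p, collapse = ","))
    }
  }
  set.seed(43)
  for (i in 1:50) {
    p <- runif(sample(4:6, 1))
    expect_equal(fdr_bh(p), bruteforce_bh(p))
  }
  # flags are monotone in the p-value ranks
  set.seed(44)
  p <- runif(20)
  fl <- fdr_bh(p)
  if (any(fl)) expect_true(all(p[fl] <= max(p[fl])) &&
                             !any(fl[order(p)] & !rev(cummax(rev(fl[order(p)])))))
})

# build a synthetic M-psi table at the statistic level: every cross-region
# pair for every participant, with optional per-cell group shifts
make_mpsi_table <- function(participants, montage, shift_rules = list(),
                            bands = c("theta", "alpha"),
                            conditions = c("eyes_closed", "eyes_open"),
                            sd = 0.05, seed = 1) {
  set.seed(seed)
  regs <- names(montage$regions)
  rp <- utils::combn(regs, 2)
  pairs <- unique(do.call(rbind, lapply(seq_len(ncol(rp)), function(j)
    region_channel_pairs(montage, rp[1, j], rp[2, j]))))
  out <- list()
  for (i in seq_len(nrow(participants))) for (bd in bands) for (cd in conditions) {
    mu <- rep(0.6, nrow(pairs))
    for (r in shift_rules) {
      if (r$band != bd || r$condition != cd) next
      if (participants$group[i] != r$group) next
      sel <- (pairs$channel_a %in% r$channels_a & pairs$channel_b %in% r$channels_b) |
        (pairs$channel_a %in% r$channels_b & pairs$channel_b %in% r$channels_a)
      mu[sel] <- mu[sel] + r$shift
    }
    out[[length(out) + 1L]] <- data.frame(
      participant = participants$participant_id[i],
      channel_a = pairs$channel_a, channel_b = pairs$channel_b,
      carrier_band = bd, envelope_band = "infraslow", condition = cd,
      m_psi = pmin(pmax(mu + rnorm(nrow(pairs), 0, sd), 0), 1),
      n_samples = 100L, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

test_that("region-pair screen localises a known group deficit", {
  m <- standard_montage()
  participants <- data.frame(
    participant_id = sprintf("s%02d", 1:16),
    group = rep(c("cMDD", "Control"), each = 8))
  rule <- list(group = "cMDD", band = "theta", condition = "eyes_closed",
               channels_a = m$regions$left_frontal,
               channels_b = m$regions$left_temporal, shift = -0.25)
  tab <- make_mpsi_table(participants, m, shift_rules = list(rule))
  scr <- region_pair_screen(tab, participants, m, c("cMDD", "Control"))
  expect_s3_class(scr, "psi_screen")
  # fractions are flagged counts over pair counts
  expect_equal(scr$cells$frac_lower,
               scr$cells$n_sig_lower / scr$cells$n_pairs)
  top <- scr$cells[order(-scr$cells$frac_lower, scr$cells$min_p_lower), ][1, ]
  expect_equal(top$region_pair, "left_frontal|left_temporal")
  expect_equal(top$carrier_band, "theta")
  expect_equal(top$condition, "eyes_closed")
  expect_equal(top$n_pairs, 27)
  bm <- select_biomarker(scr)
  expect_true(bm$found)
  expect_equal(bm$region_pair, "left_frontal|left_temporal")
  pr <- region_channel_pairs(m, "left_frontal", "left_temporal")
  expect_true(paste(sort(bm$channel_pair), collapse = "-") %in%
                paste(pmin(pr$channel_a, pr$channel_b),
                      pmax(pr$channel_a, pr$channel_b), sep = "-"))
  # the screen refuses groups that are too small
  tiny <- participants[c(1, 9:16), ]
  expect_error(region_pair_screen(tab, tiny, m, c("cMDD", "Control")),
               ">= 2")
})

test_that("null M-psi tables yield near-zero flagged fractions", {
  m <- standard_montage()
  participants <- data.frame(
    participant_id = sprintf("s%02d", 1:16),
    group = rep(c("cMDD", "Control"), each = 8))
  fracs <- vapply(1:20, function(s) {
    tab <- make_mpsi_table(participants, m, bands = "theta",
                           conditions = "eyes_closed", seed = 100 + s)
    scr <- region_pair_screen(tab, participants, m, c("cMDD", "Control"),
                              bands = "theta", conditions = "eyes_closed")
    mean(c(scr$cells$frac_lower, scr$cells$frac_higher))
  }, numeric(1))
  expect_lte(mean(fracs), 0.10)
  expect_lt(mean(fracs), 0.07)
})

test_that("biomarker selection follows the fraction-then-min-p tie rules", {
  fake_screen <- function(cells, pairs)
    structure(list(cells = cells, pairs = pairs,
                   contrast = c("cMDD", "Control"), q = 0.05,
                   family = "region_pair", envelope_band = "infraslow"),
              class = "psi_screen")
  pairs <- data.frame(
    region_pair = rep(c("ra|rb", "rc|rd"), each = 2),
    carrier_band = "theta", condition = "eyes_closed",
    channel_a = c("A1", "A2", "C1", "C2"),
    channel_b = c("B1", "B2", "D1", "D2"),
    p_lower = c(0.04, 0.3, 0.002, 0.01), p_higher = 0.9,
    sig_lower = c(TRUE, FALSE, TRUE, TRUE), sig_higher = FALSE)
  cells <- data.frame(
    region_pair = c("ra|rb", "rc|rd"), carrier_band = "theta",
    condition = "eyes_closed", n_pairs = c(2L, 2L),
    n_sig_lower = c(1L, 2L), frac_lower = c(0.2, 0.8),
    n_sig_higher = 0L, frac_higher = 0,
    min_p_lower = c(0.04, 0.002), min_p_higher = 0.9)
  bm <- select_biomarker(fake_screen(cells, pairs))
  expect_equal(bm$region_pair, "rc|rd")
  expect_equal(bm$channel_pair, c("C1", "D1"))
  expect_equal(bm$p_value, 0.002)
  # tie on fraction: smaller minimum p wins
  cells2 <- cells
  cells2$frac_lower <- c(0.8, 0.8); cells2$n_sig_lower <- c(2L, 2L)
  cells2$min_p_lower <- c(0.001, 0.01)
  bm2 <- select_biomarker(fake_screen(cells2, pairs))
  expect_equal(bm2$region_pair, "ra|rb")
  # nothing flagged anywhere: explicit no-biomarker result
  cells3 <- cells
  cells3$n_sig_lower <- 0L; cells3$frac_lower <- 0
  bm3 <- select_biomarker(fake_screen(cells3, pairs))
  expect_false(bm3$found)
})
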