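make_exponential_series <- function(plateau, depth, tau, n_pre = 5,
                                    n_frames = 100, dt = 6.15,
                                    decay_rate = 0, scale = 1000, bg = 0,
                                    cell_id = "cell") {
  t_total <- (seq_len(n_frames) - 1) * dt
  t_post <- pmax(0, t_total - n_pre * dt)
  i_gt <- ifelse(seq_len(n_frames) <= n_pre, 1,
                 plateau - (plateau - depth) * exp(-t_post / tau))
  decay <- exp(-decay_rate * t_total)
  frap_series(times = t_total, chromo_raw = i_gt * decay * scale + bg,
              nucleus_raw = 0.5 * scale * decay + bg,
              background_raw = rep(bg, n_frames), n_pre = n_pre,
              cell_id = cell_id)
}

test_that("correction is exact for any shared multiplicative decay", {
  with_seed_helper(201, {
    for (i in 1:10) {
      n <- 60
      decay <- exp(-cumsum(runif(n, 0, 0.02)))   # arbitrary decay curve
      signal <- c(rep(1, 5), 0.5 + 0.4 * (1 - exp(-(1:(n - 5)) / 10)))
      s <- frap_series(times = (0:(n - 1)) * 6.15,
                       chromo_raw = signal * decay * 800 + 50,
                       nucleus_raw = 600 * decay + 50,
                       background_raw = rep(50, n), n_pre = 5)
      cc <- correct_series(s)
      expect_equal(cc$curve, signal, tolerance = 1e-10)
    }
  })
})

test_that("a flat series corrects to a flat curve at 1", {
  s <- frap_series(times = 0:19, chromo_raw = rep(500, 20),
                   nucleus_raw = rep(300, 20), background_raw = rep(40, 20),
                   n_pre = 5)
  expect_equal(correct_series(s)$curve, rep(1, 20))
})

test_that("correction is idempotent (pre-bleach mean 1 is preserved)", {
  s <- make_exponential_series(0.92, 0.45, 26 / log(2))
  c1 <- correct_series(s)
  s2 <- frap_series(times = s$times, chromo_raw = c1$curve,
                    nucleus_raw = rep(1, length(c1$curve)),
                    background_raw = rep(0, length(c1$curve)), n_pre = 5)
  c2 <- correct_series(s2)
  expect_equal(c2$curve, c1$curve, tolerance = 1e-12)
})

test_that("cells with nonpositive corrected nuclear signal are excluded", {
  s <- make_exponential_series(0.92, 0.45, 30, bg = 0)
  s$nucleus_raw[40] <- -1
  cc <- correct_series(s)
  expect_false(cc$ok)
  good <- correct_series(make_exponential_series(0.92, 0.45, 30))
  fit <- average_and_summarize(list(cc, good))
  expect_equal(fit$n_cells, 1L)
  expect_equal(fit$n_excluded, 1L)
  expect_error(average_and_summarize(list(cc)), "no usable curve")
})

test_that("t_half equals tau * log(2) on noiseless exponentials", {
  for (tau in c(5, 10, 26 / log(2), 60, 100)) {
    s <- make_exponential_series(0.95, 0.4, tau)
    fit <- average_and_summarize(list(correct_series(s)))
    expect_lt(abs(fit$summary["t_half"] - tau * log(2)), 6.15)
    expect_equal(unname(fit$summary["i_min"]), 0.4 +
                   (0.95 - 0.4) * (1 - exp(0)), tolerance = 1e-9)
  }
})

test_that("an instantaneous jump to the plateau gives t_half = 0", {
  n <- 40
  curve <- c(rep(1, 5), rep(0.9, n - 5))
  s <- frap_series(times = (0:(n - 1)) * 6.15, chromo_raw = curve * 100,
                   nucleus_raw = rep(100, n), background_raw = rep(0, n),
                   n_pre = 5)
  fit <- average_and_summarize(list(correct_series(s)))
  expect_equal(unname(fit$summary["t_half"]), 0)
})

test_that("noisy ensembles recover the preset FRAP summaries", {
  for (nm in c("WT", "G118E")) {
    p <- preset(nm)
    fs <- simulate_frap(p$frap, n_cells = 23, seed = 211)
    fit <- average_and_summarize(lapply(fs$series, correct_series))
    expect_lt(abs(fit$summary["t_half"] - p$frap$tau * log(2)), 2)
    expect_lt(abs(fit$summary["i_max"] - p$frap$plateau), 0.02)
    expect_lt(abs(fit$summary["i_min"] - p$frap$depth), 0.02)
  }
})

test_that("project_and_measure recovers series from a rendered stack", {
  # uniform stack: all three series constant at v * n_z
  u <- array(7, dim = c(10, 10, 3, 4))
  m1 <- matrix(FALSE, 10, 10); m1[3:5, 3:5] <- TRUE
  m2 <- matrix(TRUE, 10, 10)
  m3 <- matrix(FALSE, 10, 10); m3[9:10, 9:10] <- TRUE
  s <- project_and_measure(u, m1, m2, m3, n_pre = 2)
  expect_equal(s$chromo_raw, rep(21, 4))
  expect_equal(s$nucleus_raw, rep(21, 4))
  expect_equal(s$background_raw, rep(21, 4))
  bad <- matrix(FALSE, 10, 10)
  expect_error(project_and_measure(u, bad, m2, m3), "empty mask")
  expect_error(project_and_measure(u, m1[1:5, ], m2, m3), "XY shape")
  # round trip through the toy renderer (no drift: the union ROI is the disk)
  kin <- frap_kinetics(0.92, 0.45, 26 / log(2), noise_cv = 0)
  fs <- simulate_frap(kin, n_cells = 1, seed = 221)
  toy <- render_frap_movie(fs$series[[1]], drift = 0)
  meas <- project_and_measure(toy$stack, toy$chromo_mask, toy$nucleus_mask,
                              toy$background_mask)
  cc_direct <- correct_series(fs$series[[1]])
  cc_movie <- correct_series(meas)
  expect_gt(stats::cor(cc_movie$curve, cc_direct$curve), 0.999)
  # the nucleus mask covers the chromocenter too, so the correction mixes a
  # little recovery signal into the nuclear reference; tolerance reflects it
  expect_equal(cc_movie$curve[6:100], cc_direct$curve[6:100],
               tolerance = 0.05)
})

test_that("Mann-Whitney comparison matches exact enumeration and detects
           the simulated genotype difference", {
  # identical groups: one-sided p ~ 0.5
  s <- lapply(1:6, function(i)
    make_exponential_series(0.9, 0.45, 30, cell_id = paste0("c", i)))
  grp <- lapply(s, correct_series)
  res <- compare_recovery(grp, grp, alternative = "less")
  expect_gt(res$p_value, 0.3)
  # exact p for separated groups equals the enumeration oracle
  mk_scaled <- function(depth, id)
    correct_series(make_exponential_series(0.92, depth, 30, cell_id = id))
  ga <- lapply(seq(0.30, 0.38, length.out = 5), mk_scaled, id = "a")
  gb <- lapply(seq(0.55, 0.63, length.out = 5), mk_scaled, id = "b")
  res2 <- compare_recovery(ga, gb, alternative = "less")
  oracle <- enumerate_mw_p(res2$scalars_a, res2$scalars_b, "less")
  expect_equal(res2$p_value, oracle, tolerance = 1e-12)
  expect_equal(oracle, 1 / choose(10, 5), tolerance = 1e-12)
  # and for a random non-separated case
  with_seed_helper(231, {
    xa <- rnorm(7); xb <- rnorm(6) + 0.5
  })
  p_pkg <- stats::wilcox.test(xa, xb, alternative = "less",
                              exact = TRUE)$p.value
  expect_equal(p_pkg, enumerate_mw_p(xa, xb, "less"), tolerance = 1e-12)
  # WT recovers less than G118E early after the bleach
  wt <- simulate_frap(preset("WT")$frap, n_cells = 23, seed = 241)
  mut <- simulate_frap(preset("G118E")$frap, n_cells = 23, seed = 242)
  res3 <- compare_recovery(lapply(wt$series, correct_series),
                           lapply(mut$series, correct_series),
                           alternative = "less")
  expect_lt(res3$p_value, 0.05)
})
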