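test_that("deterministic limit: D = 0 molecule at the focus gives a strictly periodic burst train", {
  m <- default_models()
  frozen <- diffusion_model(D = 0, v = 0)
  # "perfect detection": an extremely bright emitter with no background so
  # photon-statistics timing jitter is far below one bin
  bright <- beam_model(F = 1e8, B = 0)
  kernel <- wss_kernel(sigma_t = bright$w0 / (2 * m$stage$v_trans),
                       threshold = 1e4)
  set.seed(41)
  run <- run_experiment(frozen, bright, m$stage, m$control, kernel = kernel,
                        duration = 1.5, store_truth = FALSE)
  cy <- run$cycles
  expect_identical(sum(cy$missed), 0L)
  gaps <- diff(cy$tw)
  # period delta_t within one bin
  expect_true(all(abs(gaps - m$control$delta_t) <= 1e-5 + 1e-12))
  # cycle spacing is exactly delta_t in the scheduler
  expect_equal(diff(cy$tp), rep(m$control$delta_t, nrow(cy) - 1))
})

test_that("transit-time distribution is unimodal and approximately Gaussian", {
  m <- default_models()
  set.seed(42)
  run <- run_experiment(m$diff, m$beam, m$stage, m$control, duration = 6,
                        store_truth = FALSE)
  tt <- with(run$cycles[!run$cycles$missed & !run$cycles$rebound, ], tw - tp)
  tt <- tt[tt > 0 & tt < 4.58e-3]
  h <- hist(tt, breaks = seq(0, 4.7e-3, by = 2.5e-4), plot = FALSE)
  # single dominant mode near the nominal transit time Xt / v_trans
  expect_lt(abs(h$mids[which.max(h$counts)] - 4.58e-6 / m$stage$v_trans),
            7.5e-4)
  # rough symmetry: skewness small
  sk <- mean((tt - mean(tt))^3) / sd(tt)^3
  expect_lt(abs(sk), 1)
  # and a Gaussian fit of the histogram succeeds with sigma near
  # sqrt(2 D delta_t) / v (diffusion between recycles dominates the width)
  ff <- filter_cycles(run$cycles, censor_at = 4.58e-3)
  expect_identical(ff$method, "gaussian")
  sig_th <- sqrt(2 * 5e-11 * 0.03) / m$stage$v_trans
  expect_lt(abs(ff$sigma - sig_th) / sig_th, 0.5)
})

test_that("photobleaching ends molecular bursts; controller enters the missed path", {
  m <- default_models()
  set.seed(43)
  run <- run_experiment(m$diff, m$beam, m$stage, m$control, duration = 3,
                        bleach_photons = 2e3, store_truth = FALSE)
  expect_false(is.na(run$bleach_time))
  after <- run$cycles$tp > run$bleach_time + 2 * m$control$delta_t
  expect_true(all(run$cycles$missed[after]))
  expect_gt(sum(after), 0)
})

test_that("second-molecule intrusions add extra events but tracking survives", {
  m <- default_models()
  set.seed(77)
  run <- run_experiment(m$diff, m$beam, m$stage, m$control, duration = 6,
                        intruder_rate = 0.5, store_truth = FALSE)
  # intruders show up as extra in-window events, not as the bound burst
  expect_gt(sum(run$cycles$n_extra), 10)
  # the loop tolerates the invaders: most cycles still detected
  expect_gt(mean(!run$cycles$missed), 0.9)
})

test_that("simulator output is bit-reproducible given the seed", {
  m <- default_models()
  set.seed(44)
  r1 <- run_experiment(m$diff, m$beam, m$stage, m$control, duration = 0.3)
  set.seed(44)
  r2 <- run_experiment(m$diff, m$beam, m$stage, m$control, duration = 0.3)
  expect_identical(r1$photons$ticks, r2$photons$ticks)
  expect_identical(r1$photons$bin_counts, r2$photons$bin_counts)
  expect_identical(r1$cycles, r2$cycles)
  expect_identical(r1$truth, r2$truth)
})

test_that("ground truth is consistent: grid, frames and photon placement", {
  m <- default_models()
  set.seed(45)
  run <- run_experiment(m$diff, m$beam, m$stage, m$control, duration = 0.3)
  tr <- run$truth
  expect_equal(nrow(tr), length(run$photons$bin_counts))
  expect_equal(diff(tr$time), rep(1e-5, nrow(tr) - 1), tolerance = 1e-9)
  # stage is piecewise linear at |slope| <= v_trans
  slopes <- abs(diff(tr$x_stage)) / 1e-5
  expect_lt(max(slopes), m$stage$v_trans * (1 + 1e-9))
})

test_that("immobilized bead: Gaussian temporal profile with sigma_t = w0/(2 v)", {
  beam <- beam_model(F = 1e6, B = 0)
  stage <- stage_model()
  set.seed(46)
  ph <- simulate_immobilized_bead(beam, stage, passes = 200)
  # fold all passes onto one cycle and fit a Gaussian to the mean profile
  nb <- round(0.03 / 1e-5)
  prof <- rowSums(matrix(ph$bin_counts, nrow = nb))
  tmid <- (seq_len(nb) - 1) * 1e-5
  d <- data.frame(t = tmid[1:600], y = prof[1:600])
  fit <- nls(y ~ a * exp(-(t - mu)^2 / (2 * s^2)), data = d,
             start = list(a = max(d$y), mu = tmid[which.max(prof)], s = 2e-4))
  s_hat <- abs(coef(fit)[["s"]])
  expect_equal(s_hat, beam$w0 / (2 * stage$v_trans), tolerance = 0.05)
  # bead far from the scan path with no background: silence
  quiet <- emit_photons(rep(1, 1000), beam_model(F = 1e6, B = 0), dt = 1e-5)
  expect_identical(sum(quiet$bin_counts), 0)
})
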