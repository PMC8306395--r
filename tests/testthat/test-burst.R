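test_that("kernel samples the Gaussian template with amplitude A at the mode", {
  k <- wss_kernel(sigma_t = 0.47e-3, dtw = 1e-5, A = 128, span = 3)
  expect_equal(max(k$weights), 128)
  expect_identical(which.max(k$weights), k$half + 1L)
  # one sigma from the mode: A * exp(-1/2)
  j1 <- k$half + 1L + round(k$sigma_t / k$dtw)
  expect_equal(k$weights[j1], 128 * exp(-0.5), tolerance = 1e-4)
  # symmetric about its mode
  expect_equal(k$weights, rev(k$weights), tolerance = 1e-12)
  # sample count: floor(2 * span * sigma_t / dtw) + 1 (rounded up to odd)
  n_exp <- floor(2 * 3 * 0.47e-3 / 1e-5) + 1
  expect_identical(length(k$weights), as.integer(n_exp + (n_exp %% 2 == 0)))
  expect_true(all(k$weights > 0 & k$weights <= 128))
  expect_error(wss_kernel(sigma_t = 5e-6, dtw = 1e-5), "unresolvable")
})

test_that("wss equals the brute-force double-loop sum exactly", {
  k <- wss_kernel(sigma_t = 5e-5, dtw = 1e-5, span = 2)
  set.seed(21)
  counts <- rpois(200, 0.5)
  expect_identical(wss(counts, k), brute_wss(counts, k$weights, k$half))
  # all-zero counts
  expect_identical(wss(numeric(60), k), numeric(60))
  # impulse response: single photon reproduces the kernel shape, peak A
  x <- numeric(101); x[51] <- 1
  w <- wss(x, k)
  expect_equal(max(w), k$A)
  expect_identical(which.max(w), 51L)
  expect_equal(w[(51 - k$half):(51 + k$half)], rev(k$weights))
})

test_that("wss is linear and shift-equivariant", {
  k <- wss_kernel(sigma_t = 6e-5, dtw = 1e-5)
  set.seed(22)
  for (rep in 1:5) {
    a <- rpois(300, 1); b <- rpois(300, 2)
    expect_equal(wss(a + b, k), wss(a, k) + wss(b, k))
    sft <- 17L
    ash <- c(numeric(sft), a[1:(300 - sft)])
    ev_a <- detect_bursts(wss(a, k), threshold = 50, dtw = k$dtw)
    ev_s <- detect_bursts(wss(ash, k), threshold = 50, dtw = k$dtw)
    inner <- ev_a$t_peak < (300 - sft - k$half) * k$dtw
    expect_equal(ev_s$t_peak[seq_len(sum(inner))],
                 ev_a$t_peak[inner] + sft * k$dtw)
  }
})

test_that("detect_bursts segments above-threshold runs, one event per run", {
  expect_identical(nrow(detect_bursts(rep(0.5, 100), 1)), 0L)
  # synthetic Gaussian burst, peak 3000, threshold 1000: one event at the
  # true peak bin (argmax verified by brute force)
  tgrid <- seq(-50, 50)
  w <- 3000 * exp(-tgrid^2 / (2 * 10^2))
  ev <- detect_bursts(w, 1000, dtw = 1e-5)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$t_peak, (which.max(w) - 1) * 1e-5)
  expect_equal(ev$wss_peak, 3000)
  # two bursts separated by a below-threshold gap: two ordered events
  w2 <- c(w, numeric(30), 0.8 * w)
  ev2 <- detect_bursts(w2, 1000, dtw = 1e-5)
  expect_identical(nrow(ev2), 2L)
  expect_true(ev2$t_peak[1] < ev2$t_peak[2])
  # ties resolved to the earliest bin
  wt <- c(0, 5, 9, 9, 5, 0)
  evt <- detect_bursts(wt, 4, dtw = 1e-5)
  expect_equal(evt$t_peak, 2e-5)
  # run truncated by the end of data is still emitted, flagged
  we <- c(numeric(10), seq(0, 20, length.out = 10))
  eve <- detect_bursts(we, 5, dtw = 1e-5)
  expect_identical(nrow(eve), 1L)
  expect_true(eve$edge)
})

test_that("streaming detector reproduces the offline pass exactly", {
  k <- wss_kernel(sigma_t = 6e-5, dtw = 1e-5)
  set.seed(23)
  counts <- rpois(3000, 0.3)
  counts[800:820] <- counts[800:820] + rpois(21, 10)
  counts[2990:3000] <- counts[2990:3000] + rpois(11, 10)  # edge run
  w <- wss(counts, k)
  off <- detect_bursts(w, 200, dtw = 1e-5)
  st <- smrkit:::wss_stream_new(200, 1e-5)
  for (chunk in split(w, ceiling(seq_along(w) / 37))[unique(ceiling(seq_along(w) / 37))]) {
    st <- smrkit:::wss_stream_feed(st, chunk)
  }
  st <- smrkit:::wss_stream_end(st)
  stream <- smrkit:::wss_stream_events(st, n_total = length(w))
  expect_equal(stream, off)
})

test_that("matched filter localises transits to within 2 bins at high SNR", {
  # simulated constant-velocity transits at the design velocity; a bright
  # emitter with F/B = 50 (timing precision scales as sigma_t/sqrt(N))
  beam <- beam_model(w0 = 1e-6, F = 5e6, B = 1e5)
  stage <- stage_model()
  sigma_t <- beam$w0 / (2 * stage$v_trans)
  k <- wss_kernel(sigma_t = sigma_t)
  thr <- default_threshold(k, beam$B)
  set.seed(24)
  n_trials <- 300
  hits <- 0
  nb <- 600
  t_true <- 300L  # crossing at bin 300 (0-based 299)
  for (tr in seq_len(n_trials)) {
    offs <- (seq_len(nb) - t_true) * 1e-5 * stage$v_trans
    ph <- emit_photons(offs, beam, dt = 1e-5)
    ev <- detect_bursts(wss(ph, k), thr, dtw = 1e-5)
    if (nrow(ev) >= 1 &&
        abs(ev$t_peak[which.max(ev$wss_peak)] - (t_true - 1) * 1e-5) <= 2e-5)
      hits <- hits + 1
  }
  expect_gte(hits / n_trials, 0.99)
})
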