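test_that("ml_single maximizes the single-displacement likelihood", {
  expect_identical(ml_single(0, 0.03), 0)
  # inverse of sigma(T) = sqrt(2 D T) at D = 5e-11, T = 30 ms
  expect_equal(ml_single(sqrt(3e-12), 0.03), 5e-11)
  expect_error(ml_single(1e-6, 0), "T > 0")
  # brute-force likelihood scan oracle: argmax of
  # L(D) = exp(-dx^2/(4 D T)) / sqrt(4 pi D T) over a fine grid
  set.seed(61)
  for (k in 1:20) {
    dx <- runif(1, 1e-7, 5e-6)
    T <- runif(1, 5e-3, 0.1)
    D_hat <- ml_single(dx, T)
    grid <- D_hat * seq(0.5, 2, length.out = 4001)
    logL <- -dx^2 / (4 * grid * T) - 0.5 * log(4 * pi * grid * T)
    expect_equal(grid[which.max(logL)], D_hat,
                 tolerance = 2 * diff(grid[1:2]) / D_hat)
  }
})

test_that("position reconstruction matches the simulator ground truth", {
  m <- default_models()
  set.seed(62)
  run <- run_experiment(m$diff, m$beam, m$stage, m$control, duration = 3)
  cy <- run$cycles
  pos <- reconstruct_positions(cy[!cy$rebound, ], v = m$stage$v_trans,
                               censor = TRUE)
  tw <- cy$tw[match(pos$i, cy$i)]
  x_true <- run$truth$x_mol[round(tw / 1e-5) + 1]
  tt <- tw - cy$tp[match(pos$i, cy$i)]
  core <- tt > 5e-4 & tt < 4e-3        # clean mid-translation transits
  # detection timing jitter translates to ~v * sigma_t/sqrt(N) position
  # noise; require agreement within 0.5 um for clean transits
  expect_gt(sum(core), 50)
  expect_lt(stats::quantile(abs(pos$Xm - x_true)[core], 0.9), 5e-7)
  expect_lt(abs(mean((pos$Xm - x_true)[core])), 1e-7)
})

test_that("reconstruction algebra: steady state, linearity, parity checks", {
  # D = 0 steady state: identical cycles give constant Xm and zero
  # displacements
  cyc <- data.frame(i = 1:10, tp = (0:9) * 0.03,
                    tw = (0:9) * 0.03 + 2.29e-3,
                    X = rep(500, 10), direction = rep(c(1, -1), 5),
                    missed = FALSE)
  class(cyc) <- c("smr_cycles", "data.frame")
  pos <- reconstruct_positions(cyc, v = 2e-3)
  expect_equal(diff(pos$Xm), rep(0, 9), tolerance = 1e-18)
  expect_equal(displacements(pos)$delta, rep(0, 9), tolerance = 1e-18)
  # doubling v doubles only the (tw - tp) * v term
  pos2 <- reconstruct_positions(cyc, v = 4e-3)
  expect_equal(pos2$Xm - pos$Xm,
               cyc$direction * 2e-3 * (cyc$tw - cyc$tp))
  # inconsistent parity is rejected
  bad <- cyc; bad$direction[3] <- bad$direction[2]
  expect_error(reconstruct_positions(bad, v = 2e-3), "parity")
})

test_that("displacement identity: differences equal the raw-record expression to 1e-12", {
  set.seed(63)
  for (rep in 1:5) {
    n <- 100
    cyc <- data.frame(i = 1:n, tp = (0:(n - 1)) * 0.03,
                      tw = (0:(n - 1)) * 0.03 + runif(n, 5e-4, 4.5e-3),
                      X = cumsum(rnorm(n, 0, 2000)),
                      direction = rep(c(1, -1), n / 2), missed = FALSE)
    class(cyc) <- c("smr_cycles", "data.frame")
    us <- 4.58e-10; v <- 2e-3; Xt <- 4.58e-6
    pos <- reconstruct_positions(cyc, v = v)
    dd <- displacements(pos)
    # identity: Xm(i+1) - Xm(i) =
    #   (X(i+1) - X(i)) * us - dir(i) * (dX(i+1) + dX(i) - 2 Xt)
    dX <- v * (cyc$tw - cyc$tp)
    rhs <- diff(cyc$X) * us -
      cyc$direction[-n] * (dX[-1] + dX[-n] - 2 * Xt)
    expect_equal(dd$delta, rhs, tolerance = 1e-12)
  }
})

test_that("displacement bookkeeping drops intervals spanning a gap", {
  cyc <- data.frame(i = 1:8, tp = (0:7) * 0.03, tw = (0:7) * 0.03 + 2e-3,
                    X = 0, direction = rep(c(1, -1), 4),
                    missed = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                               TRUE, FALSE))
  class(cyc) <- c("smr_cycles", "data.frame")
  pos <- reconstruct_positions(cyc, v = 2e-3)
  dd <- displacements(pos)
  # kept intervals: (1,2), (4,5), (5,6); those across cycles 3 and 7 drop
  expect_identical(dd$i, c(1L, 4L, 5L))
})

test_that("filter_cycles: 3-sigma retention, contamination rejection, preconditions", {
  set.seed(64)
  n <- 2000
  tt <- rnorm(n, 2.5e-3, 4e-4)
  cyc <- data.frame(i = 1:n, tp = (0:(n - 1)) * 0.03,
                    tw = (0:(n - 1)) * 0.03 + tt,
                    X = 0, direction = rep(c(1, -1), n / 2), missed = FALSE)
  class(cyc) <- c("smr_cycles", "data.frame")
  ff <- filter_cycles(cyc)
  expect_identical(ff$method, "gaussian")
  expect_equal(ff$center, 2.5e-3, tolerance = 0.05)
  expect_equal(ff$sigma, 4e-4, tolerance = 0.15)
  # ~99.7% of a pure Gaussian sample is retained
  expect_gt(nrow(ff$cycles) / n, 0.985)
  # 5% gross outliers at 10x the centre are all rejected
  out <- cyc
  oi <- sample(n, n / 20)
  out$tw[oi] <- out$tp[oi] + 2.5e-2
  ffo <- filter_cycles(out)
  expect_true(all(!oi %in% ffo$cycles$i))
  expect_gte(ffo$n_rejected, length(oi))
  # precondition: at least 20 usable cycles
  expect_error(filter_cycles(cyc[1:15, ]), "at least 20")
})

test_that("ml_pooled: pooling, precision law and worked numbers", {
  expect_equal(ml_pooled(rep(2e-6, 5), T = 0.03)$D_hat, (2e-6)^2 / 0.06)
  r <- ml_pooled(rnorm(200, 0, sqrt(3e-12)), T = 0.03)
  expect_identical(r$N, 200L)
  expect_equal(r$rel_precision, 0.1)   # sqrt(2/200): the +/-10% at 200 recycles
  expect_equal(r$D_hat, mean(r$D_i))
  expect_true(all(r$D_i >= 0))
  # recovery oracle: 1e4 exact displacement readouts at D = 5e-11
  set.seed(65)
  big <- ml_pooled(rnorm(1e4, 0, sqrt(3e-12)), T = 0.03)
  expect_equal(big$D_hat, 5e-11, tolerance = 0.03)
})

test_that("estimator is unbiased with correct precision law (chi-squared theory)", {
  set.seed(66)
  D <- 5e-11; T <- 0.03
  for (N in c(50, 200, 800)) {
    reps <- 400
    Dh <- replicate(reps, ml_pooled(rnorm(N, 0, sqrt(2 * D * T)), T)$D_hat)
    se <- D * sqrt(2 / N) / sqrt(reps)
    expect_lt(abs(mean(Dh) - D), 3 * se)                 # unbiasedness
    rel <- sd(Dh) / mean(Dh)
    expect_lt(abs(rel - sqrt(2 / N)) / sqrt(2 / N), 0.15)  # precision law
  }
})

test_that("estimate is invariant under time translation and spatial reflection", {
  m <- default_models()
  set.seed(67)
  run <- run_experiment(m$diff, m$beam, m$stage, m$control, duration = 6,
                        store_truth = FALSE)
  est <- estimate_diffusivity(run$cycles, v = m$stage$v_trans, T = 0.03)
  shifted <- run$cycles
  shifted$tp <- shifted$tp + 5; shifted$tw <- shifted$tw + 5
  est_s <- estimate_diffusivity(shifted, v = m$stage$v_trans, T = 0.03)
  expect_equal(est_s$D_hat, est$D_hat)
  reflected <- run$cycles
  reflected$X <- -reflected$X; reflected$direction <- -reflected$direction
  est_r <- estimate_diffusivity(reflected, v = m$stage$v_trans, T = 0.03)
  expect_equal(est_r$D_hat, est$D_hat)
})

test_that("end-to-end pipeline recovers the generating diffusivity within 10% (median of 20 runs)", {
  m <- default_models()
  Dh <- numeric(20)
  for (sd in 1:20) {
    set.seed(sd)
    run <- run_experiment(m$diff, m$beam, m$stage, m$control, duration = 6,
                          store_truth = FALSE)
    Dh[sd] <- estimate_diffusivity(run$cycles, v = m$stage$v_trans,
                                   T = 0.03)$D_hat
  }
  expect_lt(abs(stats::median(Dh) / 5e-11 - 1), 0.1)
})
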