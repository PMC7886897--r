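# build an analytic spike with a logistic upstroke: the curvature maximum
# of a logistic sits at 21.13% of its amplitude, giving a closed-form
# expected threshold
.constructed_spike <- function(dt = 0.025, vbase = -55, peak = 5,
                               t_mid = 20, sigma = 0.25) {
  t <- seq(0, 40, by = dt)
  v <- vbase + (peak - vbase) / (1 + exp(-(t - t_mid) / sigma))
  down <- t >= t_mid + 2
  v[down] <- v[which(t >= t_mid + 2)[1]] - 30 * pmin((t[down] - t_mid - 2), 2)
  list(t = t, v = v,
       thr_expected = vbase + (peak - vbase) * (3 - sqrt(3)) / 6)
}

test_that("the second-derivative threshold recovers a constructed flexus", {
  w <- .constructed_spike()
  thr <- ap_threshold(w$t, w$v, 20.5)
  expect_lt(abs(thr - w$thr_expected), 2.0)
  # a linear ramp has no spike: NaN with warning
  t <- seq(0, 10, 0.025)
  expect_warning(out <- ap_threshold(t, -70 + t, 5), "rising")
  expect_true(is.na(out))
})

test_that("AP shape on a triangular pulse follows from geometry", {
  dt <- 0.01
  t <- seq(0, 40, by = dt)
  v <- rep(-60, length(t))
  up <- t >= 20 & t <= 22
  v[up] <- -60 + (40 - (-60)) * (t[up] - 20) / 2
  dn <- t > 22 & t <= 24
  v[dn] <- 40 - (40 - (-60)) * (t[dn] - 22) / 2
  shp <- ap_shape(t, v, 21)
  # threshold on a pure triangle lands near the ramp foot; amplitude and
  # half-width then follow the triangle's geometry
  expect_equal(shp$peak, 40, tolerance = 0.2)
  vhalf <- (shp$threshold + 40) / 2
  hw_expected <- 2 * 2 * (40 - vhalf) / 100
  expect_equal(shp$half_width, hw_expected, tolerance = 0.05)
  expect_equal(shp$amplitude, 40 - shp$threshold, tolerance = 1e-9)
})

test_that("train statistics count and bin correctly", {
  s <- seq(100, 2000, by = 200)          # 10 spikes in 2 s
  st <- train_stats(s, c(0, 2000))
  expect_equal(st$rate, 5)
  expect_equal(st$isi, rep(200, 9))
  # empty train
  st0 <- train_stats(numeric(0), c(0, 1000))
  expect_equal(st0$rate, 0)
  expect_length(st0$isi, 0)
  # jittered periodic train: ISI histogram peaks at the period
  set.seed(1)
  s2 <- seq(0, 5000, by = 50) + rnorm(101, 0, 2)
  st2 <- train_stats(s2, c(0, 5000), isi_breaks = seq(0, 500, 10))
  expect_equal(which.max(st2$isi_hist), 5)   # the 40-50 ms bin
})

test_that("PSTH conserves counts and aligns to onset", {
  trains <- list(c(1010), c(990, 1030), c(1500))
  h <- psth(trains, onset = 1000, bin = 40, window = c(-1000, 1000))
  expect_equal(sum(h$counts), 4)
  # a spike at onset+10 falls in the first post-onset bin
  h1 <- psth(list(c(1010)), onset = 1000, bin = 40, window = c(-200, 200))
  expect_equal(h1$counts[h1$mids == 20], 1)
  # uniform rate: expected counts r * binwidth * trials
  set.seed(2)
  r <- 50 # Hz
  trains2 <- lapply(1:40, function(i) sort(runif(r * 2, 0, 2000)))
  h2 <- psth(trains2, onset = 1000, bin = 40, window = c(-1000, 1000))
  expect_equal(mean(h2$rate), r, tolerance = 0.1)
})

test_that("sag and its time constant are recovered from a construction", {
  t <- seq(0, 2000, by = 0.1)
  tau <- 150; sag <- 8
  v <- rep(-65, length(t))
  on <- t >= 200
  v[on] <- (-75 + sag) - sag * exp(-(t[on] - 200) / tau)
  out <- sag_rebound(t, v, c(200, 2000))
  expect_equal(out$sag_mV, sag, tolerance = 0.4)
  expect_equal(out$sag_tau_ms, tau, tolerance = tau * 0.05)
  # passive trace without relaxation: sag 0
  v2 <- rep(-70, length(t))
  expect_equal(sag_rebound(t, v2, c(100, 2000))$sag_mV, 0)
})

test_that("pause length reports the constructed silent gap", {
  base <- seq(0, 1000, by = 40)
  resumed <- seq(1300, 2000, by = 40)
  expect_equal(pause_length(c(base, resumed), 1000, 40), 300)
  # immediate resumption: pause is about one baseline ISI
  expect_equal(pause_length(c(base, seq(1040, 1400, 40)), 1000, 40), 40)
  expect_true(is.na(pause_length(base, 1000, 40)))
})

test_that("fitness is zero iff features equal the targets", {
  tg <- data.frame(feature = c("a", "b"), mean = c(10, 5), sem = c(2, 1))
  expect_equal(unname(fitness(list(a = 10, b = 5), tg)), c(0, 0))
  expect_equal(unname(fitness(list(a = 14, b = 5), tg)), c(2, 0))
  expect_equal(unname(fitness(list(a = NA, b = 5), tg, penalty = 99))[1], 99)
  expect_error(fitness(list(a = 1), data.frame(feature = "a", mean = 1,
                                               sem = 0)), "sem")
})

test_that("input-output slopes are exact on synthetic lines", {
  x <- c(4, 8, 12, 16, 20)
  expect_equal(io_gain_curve(x, 2 * x + 7)$slope, 2, tolerance = 1e-12)
  expect_equal(io_gain_curve(x, rep(3, 5))$slope, 0, tolerance = 1e-12)
})

test_that("sigmoid gain fits recover f50 and flag flat curves", {
  f <- c(4, 10, 20, 50, 100, 200, 500)
  gain <- 1 + 2 / (1 + exp(-(log10(f) - log10(60)) / 0.25))
  fit <- gain_sigmoid_fit(f, gain)
  expect_equal(fit$f50, 60, tolerance = 1)
  expect_warning(flat <- gain_sigmoid_fit(f, rep(1, 7)), "flat")
  expect_true(is.na(flat$f50))
})
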