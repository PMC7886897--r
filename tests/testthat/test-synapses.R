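test_that("TM first-pulse release equals p and recovers fully", {
  tm <- synapse_library()$pf_ampa$tm
  rel <- tm_release_train(c(0), tm)
  expect_equal(rel, tm$p)
  # two spikes far apart: both release p
  rel2 <- tm_release_train(c(0, 1e6), tm)
  expect_equal(rel2, c(tm$p, tm$p), tolerance = 1e-9)
  expect_error(tm_release_train(c(10, 5), tm), "negative")
})

test_that("PF-SC trains facilitate then depress (event recursion oracle)", {
  tm <- synapse_library()$pf_ampa$tm
  for (f in c(50, 100, 200)) {
    rel <- tm_release_train(seq(0, by = 1000 / f, length.out = 20), tm)
    norm <- rel / rel[1]
    expect_gt(max(norm), 1)                # facilitation above 1 early
    expect_lt(norm[20], max(norm))         # later depression
    peak_at <- which.max(norm)
    expect_lt(peak_at, 10)
  }
})

test_that("event recursion matches the analytic fixed point to 1e-9", {
  for (ps in synapse_library()) {
    tm <- ps$tm
    for (f in c(10, 50, 200)) {
      rel <- tm_release_train(seq(0, by = 1000 / f, length.out = 400), tm)
      expect_equal(rel[400], tm_steady_state(f, tm), tolerance = 1e-9)
    }
  }
})

test_that("resources and utilization stay in [0,1] for random trains", {
  set.seed(42)
  lib <- synapse_library()
  for (rep in 1:20) {
    tm <- lib[[sample(3, 1)]]$tm
    times <- cumsum(rexp(50, rate = runif(1, 0.005, 0.5)))
    st <- tm_state()
    for (tt in times) {
      up <- tm_update(st, tt, tm)
      st <- up$state
      expect_gte(st$R, 0); expect_lte(st$R, 1)
      expect_gte(st$u, 0); expect_lte(st$u, 1)
      expect_gte(up$released, 0)
    }
  }
})

test_that("the GABA train is purely depressing (tau_fac = 0)", {
  tm <- synapse_library()$sc_gaba$tm
  expect_equal(tm$tau_fac, 0)
  rel <- tm_release_train(seq(0, by = 20, length.out = 20), tm)
  expect_true(all(diff(rel) <= 1e-12))
})

test_that("STF/STD switches transform the printed parameters", {
  tm <- synapse_library()$pf_ampa$tm
  expect_equal(stp_switch(tm, "STF_off")$tau_fac, 108)   # 10 x 10.8
  expect_equal(stp_switch(tm, "STD_off")$tau_rec, 0)
  expect_identical(stp_switch(tm, "none"), tm)
  # STF off makes facilitation persist, flattening early growth
  rel_on <- tm_release_train(seq(0, by = 10, length.out = 10), tm)
  rel_off <- tm_release_train(seq(0, by = 10, length.out = 10),
                              stp_switch(tm, "STD_off"))
  expect_true(all(diff(rel_off) >= -1e-12))  # no depression without STD
})

test_that("the magnesium block is monotone and vanishes without Mg", {
  expect_equal(nmda_block(-70, mg = 0), 1)
  expect_lt(nmda_block(-70), nmda_block(0))
  expect_gt(nmda_block(-70), 0)
  # standard parameters at -70 mV, 1 mM
  k <- 3.57; gamma <- 0.062
  expect_equal(nmda_block(-70, 1, k, gamma),
               1 / (1 + exp(0.062 * 70) / 3.57), tolerance = 1e-12)
})

test_that("receptor waveforms superpose linearly with closed-form peaks", {
  kin <- list(kind = "exp", tau_decay = 10)
  t <- seq(0, 100, by = 0.1)
  g1 <- receptor_g(t, data.frame(time = 5, released = 0.3), kin, 1000)
  expect_equal(max(g1), 0.3 * 1000, tolerance = 1e-6)
  # coincident events are exactly additive
  g2 <- receptor_g(t, data.frame(time = c(5, 5), released = c(0.3, 0.3)),
                   kin, 1000)
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
  # no events -> zero
  expect_equal(receptor_g(t, NULL, kin, 1000), rep(0, length(t)))
  # bi-exponential peak is release * g_max by the normalization factor
  kin2 <- list(kind = "dualexp", tau_rise = 2, tau_decay = 20)
  g3 <- receptor_g(t, data.frame(time = 0, released = 0.5), kin2, 1000)
  expect_equal(max(g3), 0.5 * 1000, tolerance = 1e-3)
})

test_that("EPSC amplitudes under clamp track the TM release sequence", {
  # AMPA-only train: normalized EPSC amplitudes should follow the
  # desensitization-scaled release recursion qualitatively (facilitate,
  # then depress); the first amplitude defines release p
  m <- sc_test_model()
  e <- epsc_train(m, freq = 100, n_pulses = 20, nmda = FALSE)
  expect_length(e$amplitudes, 20)
  expect_true(all(e$amplitudes > 0))
  expect_gt(max(e$normalized), 1)
  expect_lt(e$normalized[20], max(e$normalized))
  # single-pulse train: normalized sequence is exactly [1]
  e1 <- epsc_train(m, freq = 100, n_pulses = 1, nmda = FALSE)
  expect_equal(e1$normalized, 1)
})

test_that("overlapping pulses faster than the step are rejected", {
  m <- sc_test_model()
  expect_error(epsc_train(m, freq = 80000), "closer than")
})
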