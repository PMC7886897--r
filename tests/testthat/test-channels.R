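test_that("the library holds 14 channels and all gate curves stay in [0,1]", {
  lib <- builtin_channel_library()
  expect_length(lib, 14)
  v <- seq(-120, 60, by = 0.5)
  for (ch in lib) for (g in ch$gates) {
    d <- gate_dynamics(g, v, ca = 5e-5)
    expect_true(all(d$inf >= 0 & d$inf <= 1), label = ch$name)
    expect_true(all(d$tau > 0), label = ch$name)
  }
})

test_that("Q10 temperature correction scales time constants exactly", {
  g <- gate_spec("m", 1, function(v, ca) 0.5 + 0 * v,
                 function(v, ca) 10 + 0 * v, q10 = 3, t_ref = 32)
  expect_equal(gate_dynamics(g, 0, temp = 32)$tau, 10)
  expect_equal(gate_dynamics(g, 0, temp = 42)$tau, 10 / 3)
  expect_equal(gate_dynamics(g, 0, temp = 22)$tau, 30)
  # steady state unchanged by temperature
  expect_equal(gate_dynamics(g, 0, temp = 22)$inf, 0.5)
})

test_that("a Boltzmann gate is half-activated at its half-voltage", {
  lib <- builtin_channel_library()
  m <- lib$Kv7$gates[[1]]
  # half-voltage found independently by root-finding on the curve
  half <- uniroot(function(v) m$inf(v, 5e-5) - 0.5, c(-90, 0))$root
  expect_equal(m$inf(half, 5e-5), 0.5, tolerance = 1e-9)
})

test_that("channel current follows the ohmic form and conventions", {
  lib <- builtin_channel_library()
  rev <- reversal_set()
  kv <- lib$Kv3.4
  # V = E_ion -> zero current
  expect_equal(channel_current(kv, 1, 0.01, rev$K), 0)
  # all gates open, V - E = 10 -> 10 * G
  expect_equal(channel_current(kv, 1, 0.01, rev$K + 10), 0.1)
  # gate exponent honoured: state s enters as s^2 for Kv3.4
  s <- 0.5
  expect_equal(channel_current(kv, s, 0.01, rev$K + 10), 0.1 * s^2)
  expect_error(channel_current(kv, 1.2, 0.01, 0), "0, 1")
})

test_that("KCa1.1 opens with calcium and HCN1/Kir2.3 with hyperpolarization", {
  lib <- builtin_channel_library()
  bk <- lib$KCa1.1$gates[[1]]
  expect_gt(bk$inf(-20, 5e-4), bk$inf(-20, 5e-5))
  expect_gt(bk$inf(-20, 5e-3), bk$inf(-20, 5e-4))
  hcn <- lib$HCN1$gates[[1]]
  expect_gt(hcn$inf(-100, 5e-5), hcn$inf(-50, 5e-5))
  kir <- lib$Kir2.3$gates[[1]]
  # conducts more below E_K than above (inward rectification)
  rev <- reversal_set()
  g_below <- kir$inf(rev$K - 15, 5e-5)
  g_above <- kir$inf(rev$K + 15, 5e-5)
  expect_gt(g_below, g_above)
})

test_that("calcium pool relaxes to rest and matches the linear steady state", {
  pool <- calcium_pool()
  # no influx at rest: concentration stays put
  p <- pool
  for (i in 1:200) p <- step_calcium(p, 0, 1e-6, 0.025)
  expect_equal(p$ca, pool$rest, tolerance = 1e-6)
  # extrusion only: exponential decay at the stated time constant
  p <- pool; p$ca <- pool$rest + 1e-3
  # freeze the buffer so the decay is a pure single exponential
  p$btot <- 0; p$bound <- 0
  n_tau <- round(pool$tau_ex / 0.025)
  for (i in seq_len(n_tau)) p <- step_calcium(p, 0, 1e-6, 0.025)
  expect_equal((p$ca - pool$rest) / 1e-3, exp(-1), tolerance = 0.01)
  # constant influx: analytic steady state rest + influx * tau
  i_ca <- -0.05  # mA/cm2 inward
  influx <- -i_ca / (2 * 96485 * pool$depth * 1e-4)
  p <- pool; p$btot <- 0; p$bound <- 0
  for (i in 1:4000) p <- step_calcium(p, i_ca, 1e-6, 0.025)
  expect_equal(p$ca, pool$rest + influx * pool$tau_ex, tolerance = 1e-3)
  # concentration can never go negative
  p <- pool; p$ca <- 1e-9
  for (i in 1:100) p <- step_calcium(p, 0, 1e-6, 0.025)
  expect_gte(p$ca, 0)
})
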