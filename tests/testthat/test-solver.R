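test_that("assemble builds one coupling per child and the hand formula", {
  cab <- passive_cable(n = 5, L_um = 100, diam_um = 2)
  sys <- assemble(cab)
  expect_equal(sum(sys$g_axial_uS > 0), 4)   # N-1 couplings
  # two identical cylinders: coupling = 1 / (2 * Ra*(L/2)/(pi d^2/4))
  L <- 100e-4; d <- 2e-4
  r_half <- 110 * (L / 2) / (pi * d^2 / 4)
  expect_equal(sys$g_axial_uS[2], 1 / (2 * r_half) * 1e6, tolerance = 1e-12)
  # single compartment: no axial terms
  one <- passive_one_comp()
  expect_equal(assemble(one)$g_axial_uS, 0)
})

test_that("a passive compartment follows the RC charging closed form", {
  m <- passive_one_comp(area_cm2 = 1e-5, g_leak = 3e-5, cm = 1)
  g_nS <- 3e-5 * 1e-5 * 1e9        # 0.3 nS
  c_pF <- 1 * 1e-5 * 1e6           # 10 pF
  tau <- c_pF / g_nS               # ms
  i_pA <- -5
  tr <- stellate:::.run_sim(m, 400,
    stims = list(list(comp = 1, t0 = 100, t1 = 400, amp_pA = i_pA)),
    record = "soma.v")
  v <- tr$v[, 1]; t <- tr$t
  # before the step the cell rests exactly at E_leak
  expect_equal(v[t == 99], -48, tolerance = 1e-9)
  dv_inf <- i_pA / g_nS
  pred <- -48 + dv_inf * (1 - exp(-(200 - 100) / tau))
  expect_equal(v[t == 200], pred, tolerance = abs(dv_inf) * 1e-3)
  expect_equal(v[t == 400], -48 + dv_inf, tolerance = abs(dv_inf) * 1e-3)
})

test_that("charge balance holds at every accepted step", {
  m <- sc_test_model()
  tr <- run_protocol(m, step_protocol(16, dur = 300, pre = 100, post = 0))
  expect_lt(tr$max_residual, 1e-6)
})

test_that("passive cable attenuation matches the analytic solution", {
  n <- 20; L <- 50; d <- 2; gl <- 3e-5; Ra <- 110
  cab <- passive_cable(n = n, L_um = L, diam_um = d, g_leak = gl,
                       r_axial = Ra)
  tr <- stellate:::.run_sim(cab, 2000,
    stims = list(list(comp = 1, t0 = 0, t1 = 2000, amp_pA = -10)),
    record = paste0("c", c(1, 10, 20), ".v"))
  vss <- tr$v[nrow(tr$v), ] + 48
  lambda <- sqrt((d * 1e-4 / 4) / (gl * Ra)) * 1e4   # um
  Ltot <- n * L
  x <- (c(1, 10, 20) - 0.5) * L
  pred <- cosh((Ltot - x) / lambda) / cosh(Ltot / lambda)
  expect_equal(as.numeric(vss / vss[1]), pred / pred[1], tolerance = 0.01)
})

test_that("same seed gives identical traces; dt halving moves spikes little", {
  m <- sc_test_model()
  tr1 <- run_protocol(m, step_protocol(0, dur = 1000, pre = 200, post = 0),
                      seed = 5)
  tr2 <- run_protocol(m, step_protocol(0, dur = 1000, pre = 200, post = 0),
                      seed = 5)
  expect_identical(tr1$v, tr2$v)
  m_fine <- m; m_fine$dt <- 0.0125
  tr3 <- run_protocol(m_fine, step_protocol(0, dur = 1000, pre = 200,
                                            post = 0))
  s1 <- tr1$spikes[[1]]; s3 <- tr3$spikes[[1]]
  k <- min(length(s1), length(s3))
  expect_gt(k, 5)
  expect_lt(max(abs(s1[1:k] - s3[1:k])) / k, 0.5)
})

test_that("ideal clamp records the mirror of the synaptic current", {
  # GABA synapse placed at the soma of a passive cell under clamp
  m <- passive_one_comp()
  m$synapses[[1]] <- stellate:::.make_synapse(1, "sc_gaba",
                                              events = c(50))
  tr <- stellate:::.run_sim(m, 150, clamp = list(comp = 1, v = -70,
                                                 t0 = 0, t1 = 150),
                            record = "soma.v")
  # predicted conductance waveform from the receptor closed form
  lib <- synapse_library()$sc_gaba
  g_pred <- receptor_g(tr$t, data.frame(time = 50, released = lib$tm$p),
                       lib$receptor, lib$tm$g_pS)
  i_pred <- g_pred * 1e-3 * (-70 - lib$tm$e_rev)   # pA
  base <- mean(tr$i_clamp[tr$t > 40 & tr$t < 50])
  i_syn <- tr$i_clamp - base
  expect_equal(min(i_syn), min(i_pred), tolerance = abs(min(i_pred)) * 0.005)
  # clamped node voltage is pinned
  expect_true(all(abs(tr$v[tr$t > 1, 1] + 70) < 1e-9))
})

test_that("integration failures surface with a time stamp", {
  m <- passive_one_comp()
  m$v_init <- NaN                 # poisoned state must be caught, not run
  expect_error(stellate:::.run_sim(m, 50), "integration failure")
})
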