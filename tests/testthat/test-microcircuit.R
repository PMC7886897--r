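test_that("circuit wiring honours the standard synapse counts", {
  sc <- sc_test_model()
  circ <- build_circuit(circuit_config(n_sc_pc = 100, seed = 4),
                        sc_model_1 = sc)
  groups <- vapply(circ$synapses, function(s) s$group, "x")
  expect_equal(sum(groups == "pc_pf"), 200)     # 100 PF contacts x 2 parts
  expect_equal(sum(groups %in% c("pf_ampa", "pf_nmda")), 6)  # 3 PF-SC x 2
  expect_equal(sum(groups == "sc_pc"), 100)
  expect_equal(sum(groups == "sc_sc"), 0)
  # second stellate cell adds exactly 32 SC-SC synapses
  circ2 <- build_circuit(circuit_config(sc_sc_enabled = TRUE, seed = 4),
                         sc_model_1 = sc)
  g2 <- vapply(circ2$synapses, function(s) s$group, "x")
  expect_equal(sum(g2 == "sc_sc"), 32)
  expect_named(circ2$cells, c("sc1", "sc2", "pc"))
  # identical seed, identical placement
  circ3 <- build_circuit(circuit_config(n_sc_pc = 100, seed = 4),
                         sc_model_1 = sc)
  expect_identical(vapply(circ$synapses, function(s) s$comp, 1L),
                   vapply(circ3$synapses, function(s) s$comp, 1L))
})

test_that("branch III never receives inhibitory synapses", {
  pc <- purkinje_model()
  expect_error(attach_pc_gaba_synapses(pc, target = c("branch3")),
               "branch III")
  pc2 <- attach_pc_gaba_synapses(pc, n = 200, seed = 1)
  comps <- vapply(pc2$synapses, function(s) as.integer(s$comp), 1L)
  expect_false(any(pc$compartments$class[comps] == "branch3"))
  # PF excitation targets branch II only
  pc3 <- attach_pc_pf_synapses(pc, n = 50)
  comps3 <- vapply(pc3$synapses, function(s) s$comp, 1L)
  expect_true(all(pc$compartments$class[comps3] == "branch2"))
})

test_that("removing all SC->PC synapses reproduces the SC-off wiring", {
  sc <- sc_test_model()
  c_off <- build_circuit(circuit_config(sc_enabled = FALSE, seed = 2),
                         sc_model_1 = sc)
  c_zero <- build_circuit(circuit_config(n_sc_pc = 0, seed = 2),
                          sc_model_1 = sc)
  r_off <- stellate:::.run_circuit_train(c_off, 100)
  r_zero <- stellate:::.run_circuit_train(c_zero, 100)
  expect_identical(r_off$trace$spikes$pc, r_zero$trace$spikes$pc)
})

test_that("response latency is read from a fine-binned PSTH", {
  set.seed(3)
  # baseline 20 Hz, response at onset+40 ms jumping to 200 Hz
  trains <- lapply(1:30, function(i) {
    base <- runif(40, -2000, 2000)
    burst <- 40 + cumsum(rexp(8, 0.2))
    sort(c(base[base < 40 | base > 150], burst))
  })
  lat <- response_latency(trains, onset = 0, bin = 10)
  expect_gte(lat, 35); expect_lte(lat, 65)
  # no response at all -> NA
  flat <- lapply(1:10, function(i) seq(-2000 + i, 2000, by = 47))
  expect_true(is.na(response_latency(flat, onset = 0)))
})

test_that("PF-count calibration is monotone and anchored at zero", {
  sc <- sc_test_model()
  expect_equal(calibrate_pf_count(sc, 0), 0L)
  n_lo <- calibrate_pf_count(sc, 30, trials = 2)
  n_hi <- calibrate_pf_count(sc, 55, trials = 2)
  expect_lte(n_lo, n_hi)
  expect_gte(n_lo, 1)
  expect_error(calibrate_pf_count(sc, 1e5, max_n = 2, trials = 1),
               "not reached")
})

test_that("stellate burst responses grow with input frequency", {
  sc <- sc_test_model()
  r20 <- sc_burst_response(sc, freq = 20, trials = 3, seed = 2)
  r200 <- sc_burst_response(sc, freq = 200, trials = 3, seed = 2)
  expect_gt(r200$burst_hz, r20$burst_hz)
  expect_gt(r200$pct_increase, 0)
  # no synapses activated: output equals the pacemaking baseline
  r0 <- sc_burst_response(sc, freq = 100, n_syn = 0, trials = 4, seed = 2)
  expect_lt(abs(r0$burst_hz - r0$baseline_hz), 12)
})
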