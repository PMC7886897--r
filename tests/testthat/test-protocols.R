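test_that("the standard battery matches the optimization protocol set", {
  bat <- standard_battery()
  amps <- vapply(bat, function(p) p$amps, 1.0)
  expect_setequal(amps, c(0, 4, 16, -16))
  expect_true(all(vapply(bat, function(p) p$dur, 1.0) == 2000))
  expect_equal(bat$step_0pA$amps, 0)
  ladder <- standard_battery(extended = TRUE)
  expect_equal(vapply(ladder, function(p) p$amps, 1.0),
               setNames(seq(-16, 20, 4), names(ladder)))
})

test_that("the PF train set covers the seven frequencies", {
  ts <- pf_train_set()
  expect_length(ts, 7)
  expect_equal(vapply(ts, function(p) p$freq, 1.0),
               c(f4 = 4, f10 = 10, f20 = 20, f50 = 50, f100 = 100,
                 f200 = 200, f500 = 500))
  expect_true(all(vapply(ts, function(p) p$n_syn, 1.0) == 3))
  ev <- realize_events(ts$f100)
  expect_length(ev, 10)
  expect_equal(max(ev) - min(ev), 90)          # (10-1)/100 s
  ts20 <- pf_train_set(n_pulses = 20)
  expect_length(realize_events(ts20$f50), 20)
})

test_that("event realization is deterministic for trains and seeded noise", {
  bg <- inhibitory_background(rate = 20, n_syn = 5, process = "periodic",
                              dur = 1000)
  ev1 <- realize_events(bg, seed = 3)
  ev2 <- realize_events(bg, seed = 3)
  expect_identical(ev1, ev2)
  # periodic 20 Hz: inter-event interval exactly 50 ms
  expect_true(all(abs(diff(ev1[[1]]) - 50) < 1e-9))
  # events never exceed the protocol window
  expect_true(all(unlist(ev1) <= bg$onset + bg$dur))
  # Poisson stream: same seed reproducible, count near rate * duration
  bgp <- inhibitory_background(rate = 20, n_syn = 30, process = "poisson",
                               dur = 15000)
  evp <- realize_events(bgp, seed = 9)
  expect_identical(evp, realize_events(bgp, seed = 9))
  counts <- vapply(evp, length, 1L)
  expect_lt(abs(mean(counts) - 300), 3 * sqrt(300) / sqrt(30))
})

test_that("configurations serialize to YAML and back losslessly", {
  cfg <- default_config()
  cfg$protocol$amps_pA <- c(-16, 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$protocol$amps_pA, c(-16, 4))
  expect_equal(unlist(cfg2$conductances), unlist(cfg$conductances))
  # unknown keys are rejected by schema validation
  bad <- c(cfg, list(bogus = list(a = 1)))
  write_config(bad, path)
  expect_error(read_config(path), "unknown config")
})

test_that("clamp protocols validate their voltage range", {
  expect_error(clamp_protocol(v = -200), "v >=")
  p <- clamp_protocol(v = -70, train = train_protocol(freq = 50))
  expect_gt(p$t_end, 1000)
})
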