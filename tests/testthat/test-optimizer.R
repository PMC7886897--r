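test_that("IBEA recovers the analytic Pareto front of a toy problem", {
  # objectives f1 = (x-1)^2 + y^2, f2 = (x-3)^2 + y^2:
  # the front is y = 0, x in [1, 3]
  obj <- function(g) c((g[1] - 1)^2 + g[2]^2, (g[1] - 3)^2 + g[2]^2)
  res <- ibea_optimize(obj, lower = c(0.1, 0.1), upper = c(5, 5),
                       pop_size = 30, generations = 30, seed = 7,
                       sigma_mut = 0.4)
  front <- do.call(rbind, res$archive$genomes)
  expect_gt(nrow(front), 5)
  expect_true(all(front[, 1] > 0.8 & front[, 1] < 3.2))
  expect_lt(median(front[, 2]), 0.3)
  # non-dominated archive: no member dominates another
  fits <- res$archive$fitness
  for (i in seq_len(nrow(fits))) for (j in seq_len(nrow(fits))) {
    if (i == j) next
    expect_false(all(fits[j, ] <= fits[i, ]) && any(fits[j, ] < fits[i, ]))
  }
  # hall-of-fame error never regresses across generations
  expect_true(all(diff(cummin(res$history$best_sum)) <= 0))
  # reproducible given the seed
  res2 <- ibea_optimize(obj, lower = c(0.1, 0.1), upper = c(5, 5),
                        pop_size = 30, generations = 30, seed = 7,
                        sigma_mut = 0.4)
  expect_equal(res$hof$genome, res2$hof$genome)
})

test_that("genome evaluation is deterministic and penalizes silent models", {
  m <- sc_test_model()
  g <- sc_default_conductances()
  f1 <- evaluate_genome(g, m)
  f2 <- evaluate_genome(g, m)
  expect_identical(f1, f2)
  expect_true(all(is.finite(f1)))
  # zero sodium: no spikes, spike-dependent features take the penalty
  g0 <- g
  g0[grepl("Nav", names(g0))] <- 0
  f0 <- evaluate_genome(g0, m, penalty = 250)
  expect_equal(unname(f0["amplitude"]), 250)
  expect_gt(f0["freq_0"], f1["freq_0"])
})

test_that("the parameter space covers the 36 slots with sane bounds", {
  sp <- parameter_space()
  expect_equal(nrow(sp), 36)
  expect_true(all(sp$low > 0 & sp$low < sp$high))
  expect_setequal(sp$name, names(sc_default_conductances()))
  sp2 <- parameter_space(spread = 2)
  expect_equal(sp2$high / sp2$center, rep(2, 36), tolerance = 1e-12)
})

test_that("select_best picks the minimal-error archive member", {
  fake <- list(archive = list(
    genomes = list(c(a = 1, b = 1), c(a = 2, b = 0.1), c(a = 0.5, b = 0.5)),
    fitness = rbind(c(1, 1), c(0.2, 0.2), c(0.2, 0.2))))
  best <- select_best(list(fake))[[1]]
  # tie between rows 2 and 3 broken by lower total conductance
  expect_equal(best, c(a = 0.5, b = 0.5))
})

test_that("optimization refines the stellate model toward its targets", {
  m <- sc_test_model()
  space <- parameter_space(spread = 1.6)
  res <- optimize_conductances(m, space = space, pop_size = 6,
                               generations = 2, seed = 11)
  expect_equal(res$evaluations, 6 + 2 * 6)
  start <- sum(evaluate_genome(sc_default_conductances(), m))
  expect_lte(res$hof$sum, start + 1e-9)
  expect_length(res$hof$genome, 36)
  expect_true(all(res$hof$genome >= space$low - 1e-12 &
                  res$hof$genome <= space$high + 1e-12))
})
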