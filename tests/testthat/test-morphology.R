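test_that("SWC read/write round-trips topology, labels and diameters", {
  m <- generate_sc_morphology(seed = 7)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path)
  expect_equal(nrow(m2$nodes), nrow(m$nodes))
  expect_equal(m2$nodes$type, m$nodes$type)
  expect_equal(m2$nodes$parent, m$nodes$parent)
  expect_equal(m2$nodes$radius, m$nodes$radius, tolerance = 1e-5)
  expect_equal(m2$nodes$x, m$nodes$x, tolerance = 1e-5)
  # re-read morphometrics identical
  mm1 <- morphometrics(m); mm2 <- morphometrics(m2)
  expect_equal(mm2$dendritic_length, mm1$dendritic_length, tolerance = 1e-5)
  expect_equal(mm2$proximal_count, mm1$proximal_count)
})

test_that("malformed and multi-root SWC files are rejected with context", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# header", "1 1 0 0 0 2 -1", "2 3 5 0 0"), path)
  expect_error(read_swc(path), "line 3")
  writeLines(c("1 1 0 0 0 2 -1", "2 1 5 0 0 2 -1"), path)
  expect_error(read_swc(path), "root")
})

test_that("a minimal soma+dendrite SWC parses into two sections", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 2 -1", "2 1 0 4 0 2 1", "3 3 10 4 0 0.2 2"), path)
  m <- read_swc(path)
  expect_setequal(unique(m$nodes$type), c(1L, 3L))
  cls <- classify_compartments(m)
  expect_equal(cls, c("soma", "soma", "dist_dend"))
})

test_that("total dendritic length equals brute-force point-distance sum", {
  m <- generate_sc_morphology(seed = 11)
  n <- m$nodes
  # independent oracle: walk every node, sum Euclidean distance to parent
  total <- 0
  for (i in seq_len(nrow(n))) {
    if (n$parent[i] == -1 || n$type[i] != 3L) next
    p <- n[match(n$parent[i], n$id), ]
    total <- total + sqrt((n$x[i] - p$x)^2 + (n$y[i] - p$y)^2 +
                          (n$z[i] - p$z)^2)
  }
  expect_equal(morphometrics(m)$dendritic_length, total, tolerance = 1e-9)
  expect_gt(nrow(n), 60)
})

test_that("generator matches the printed morphometric targets", {
  tg <- morphometric_targets()
  m <- generate_sc_morphology(seed = 1)
  mm <- morphometrics(m)
  expect_lt(abs(mm$dendritic_length - 845.2), 121.2 + 1e-6)
  # repeated calls with the same seed give identical trees
  m2 <- generate_sc_morphology(seed = 1)
  expect_identical(m$nodes, m2$nodes)
  # across seeds the mean soma surface sits in the printed band
  surfaces <- vapply(1:40, function(s)
    morphometrics(generate_sc_morphology(seed = s))$soma_surface, 1.0)
  expect_lt(abs(mean(surfaces) - 42.4), 9.3)
  # all five compartment classes present
  cls <- classify_compartments(m)
  expect_setequal(unique(cls),
                  c("soma", "prox_dend", "dist_dend", "ais", "axon"))
})

test_that("compartment classification honours the diameter cut-off", {
  m <- generate_sc_morphology(seed = 3)
  cls <- classify_compartments(m, cutoff_um = 0.6)
  d <- 2 * m$nodes$radius
  dend <- m$nodes$type == 3L
  expect_true(all(cls[dend & d >= 0.6] == "prox_dend"))
  expect_true(all(cls[dend & d < 0.6] == "dist_dend"))
  # axon-labelled nodes are never dendritic
  expect_false(any(cls[m$nodes$type == 2L] %in% c("prox_dend", "dist_dend")))
})

test_that("soma surface follows the cylinder closed form", {
  # one cylinder, L = 10 um, d = 1 um -> lateral surface 10*pi um2
  nodes <- data.frame(id = 1:2, type = 1L, x = c(0, 10), y = 0, z = 0,
                      radius = 0.5, parent = c(-1L, 1L))
  m <- morphology(nodes)
  expect_equal(morphometrics(m)$soma_surface, 10 * pi, tolerance = 1e-12)
  expect_equal(morphometrics(m)$dendritic_length, 0)
})

test_that("morphology invariants are validated", {
  nodes <- data.frame(id = 1:2, type = 1L, x = 0, y = 0, z = 0,
                      radius = c(1, -0.2), parent = c(-1L, 1L))
  expect_error(morphology(nodes), "positive")
  nodes$radius <- 1
  nodes$parent <- c(-1L, 99L)
  expect_error(morphology(nodes), "dangling")
})
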