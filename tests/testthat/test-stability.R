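test_that("1-D census classifies crossings by their direction", {
  # linear restoring force: one stable point at 50
  cen <- find_stable_points_1d(function(E) -(E - 50), c(0, 100))
  expect_equal(nrow(cen), 1)
  expect_equal(cen$location, 50, tolerance = 1e-6)
  expect_equal(as.character(cen$classification), "stable")
  # a force that never crosses zero has no fixed points
  expect_equal(nrow(find_stable_points_1d(function(E) 1 + 0 * E,
                                          c(0, 100))), 0)
  # sinusoid with known crossings: down-crossings at 12.5 + 25k
  cen2 <- find_stable_points_1d(function(E) sin(2 * pi * E / 25),
                                c(0, 100), h = 0.7)
  st <- cen2$location[cen2$classification == "stable"]
  un <- cen2$location[cen2$classification == "unstable"]
  expect_equal(st, c(12.5, 37.5, 62.5, 87.5), tolerance = 1e-5)
  expect_equal(un, c(25, 50, 75), tolerance = 1e-5)
})

test_that("stable and unstable crossings alternate along the axis", {
  kr <- gaussian_kernel5()
  for (seed in 1:10) {
    fld <- sample_force_field(kr, 1, 100, seed = seed)
    cen <- find_stable_points_1d(fld, c(0, 100))
    cls <- as.character(cen$classification[order(cen$location)])
    if (length(cls) > 1)
      expect_true(all(cls[-1] != cls[-length(cls)]),
                  label = paste("alternation at seed", seed))
  }
})

test_that("N-D census recovers a separable linear field exactly", {
  cen <- find_fixed_points_nd(function(E) -(E - 50), range = 100,
                              n_env = 2)
  expect_equal(nrow(cen), 1)
  expect_equal(unlist(cen[1, 1:2]), c(E_1 = 50, E_2 = 50),
               tolerance = 1e-9)
  expect_equal(as.character(cen$classification), "stable")
})

test_that("product fields get the full combinatorial census", {
  # two independent 1-D fields; the separable 2-D field's fixed points are
  # all pairs of 1-D crossings, with the product sign pattern
  kr <- gaussian_kernel5()
  f1 <- sample_force_field(kr, 1, 100, seed = 101)
  f2 <- sample_force_field(kr, 1, 100, seed = 102)
  c1 <- find_stable_points_1d(f1, c(0, 100))
  c2 <- find_stable_points_1d(f2, c(0, 100))
  cl <- function(x) pmin(pmax(x, 0), 100)
  sep <- function(E) c(field_at(f1, cl(E[1])), field_at(f2, cl(E[2])))
  cen <- find_fixed_points_nd(sep, range = 100, n_env = 2, h = f1$h)
  expect_equal(nrow(cen), nrow(c1) * nrow(c2))
  cls <- function(a, b) {
    if (a == "stable" && b == "stable") "stable"
    else if (a == "unstable" && b == "unstable") "unstable"
    else "saddle"
  }
  want <- expand.grid(i = seq_len(nrow(c1)), j = seq_len(nrow(c2)))
  want$E_1 <- c1$location[want$i]
  want$E_2 <- c2$location[want$j]
  want$classification <- mapply(cls,
                                as.character(c1$classification)[want$i],
                                as.character(c2$classification)[want$j])
  for (r in seq_len(nrow(want))) {
    d <- sqrt((cen$E_1 - want$E_1[r])^2 + (cen$E_2 - want$E_2[r])^2)
    k <- which.min(d)
    expect_lt(d[k], 1e-4 * 100)
    expect_equal(as.character(cen$classification[k]),
                 want$classification[r])
  }
  expect_equal(sum(cen$classification == "stable"),
               sum(c1$classification == "stable") *
                 sum(c2$classification == "stable"))
})

test_that("rein pair probability: closed form, sampling error, degeneracy", {
  expect_identical(rein_pair_probability(), 0.25)
  mc <- rein_pair_probability("monte_carlo", n_trials = 1e5, seed = 8)
  expect_lt(abs(mc - 0.25), 0.005)
  expect_equal(rein_pair_probability("monte_carlo", 1e4, seed = 9,
                                     prob_positive = 1), 0)
  expect_identical(rein_pair_probability(prob_positive = 1), 0)
})

test_that("the expected stable-point count scales as Kac-Rice dictates", {
  # 1-D closed form = Rice down-crossing oracle for the sqrt(2)-width kernel
  kr <- gaussian_kernel5()
  expect_equal(expected_stable_points(1, 100, 5), rice_crossings(kr, 100),
               tolerance = 1e-12)
  expect_equal(expected_stable_points(1, 100, 5),
               100 / (2 * sqrt(2) * pi * 5))
  # only the ratio R/width matters
  expect_equal(expected_stable_points(1, 100, 5),
               expected_stable_points(1, 200, 10))
  expect_equal(expected_stable_points(2, 100, 5),
               expected_stable_points(2, 200, 10))
  # broad niches span the range: the count collapses towards O(1)
  w <- c(5, 10, 20, 50, 90)
  v <- vapply(w, function(s) expected_stable_points(1, 100, s), numeric(1))
  expect_true(all(diff(v) < 0))
  expect_lt(v[length(v)], 1)
  # exponential growth with dimension
  expect_gt(expected_stable_points(2, 100, 5),
            expected_stable_points(1, 100, 5)^1.5)
})

test_that("the diversity threshold moves the right way", {
  expect_lt(threshold_K(100, 10), threshold_K(100, 5))
  expect_gt(threshold_K(200, 5), threshold_K(100, 5))
  expect_gt(threshold_K(100, 5, n_env = 2), threshold_K(100, 5)^1.5)
})

test_that("the plateau detector finds a synthetic staircase", {
  tr <- staircase_trajectory()
  pl <- detect_plateaus(tr)
  expect_equal(nrow(pl), 2)
  # plateau edges are trimmed by up to one detector window on each side
  expect_lt(abs(pl$t_start[1] - 0), 11)
  expect_lt(abs(pl$t_end[1] - 40), 11)
  expect_lt(abs(pl$t_start[2] - 45), 11)
  expect_gt(pl$t_start[2], pl$t_end[1])
  expect_equal(pl$E_mean[1], 20, tolerance = 0.01)
  expect_equal(pl$E_mean[2], 40, tolerance = 0.01)
})

test_that("settled trajectories land on census stable points only", {
  kr <- gaussian_kernel5()
  fld <- sample_force_field(kr, 1, 100, seed = 64)
  cen <- find_stable_points_1d(fld, c(0, 100))
  st <- cen$location[cen$classification == "stable"]
  un <- cen$location[cen$classification == "unstable"]
  cfg <- rein_config(dt = 0.05)
  set.seed(4)
  for (E0 in runif(6, 5, 95)) {
    tr <- rein_simulate(fld, E0, config = cfg, t_end = 300, stride = 20)
    Ef <- tr$env[nrow(tr$env), 1]
    if (Ef < 0 || Ef > 100) next # escaped the essential range
    expect_lt(min(abs(st - Ef)), 0.05)
    if (length(un)) expect_gt(min(abs(un - Ef)), 0.5)
  }
})
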