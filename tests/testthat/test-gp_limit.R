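test_that("the gaussian force kernel is the niche autocorrelation", {
  kr <- force_kernel(niche_shape("gaussian", 5))
  # autocorrelation of a width-5 Gaussian is a Gaussian of width 5*sqrt(2)
  expect_equal(kernel_cov(kr, 5 * sqrt(2)) / kernel_cov(kr, 0),
               exp(-1 / 2))
  expect_equal(kr$length_scale, 5 * sqrt(2))
  for (d in c(0.5, 3, 11))
    expect_equal(kernel_cov(kr, d), kernel_cov(kr, -d))
  # separable across axes
  expect_equal(kernel_cov(kr, c(3, 4)),
               kernel_cov(kr, 3) * kernel_cov(kr, 4))
})

test_that("numerical kernels match quadrature and stay even", {
  for (fam in c("skewed", "bimodal")) {
    sh <- niche_shape(fam, 5)
    kr <- force_kernel(sh)
    # independent oracle: direct quadrature of the autocorrelation
    ac <- function(d) stats::integrate(function(u)
      reinworld:::.niche_response(sh, u) *
        reinworld:::.niche_response(sh, u + d), -200, 200,
      rel.tol = 1e-9)$value
    a0 <- ac(0)
    for (d in c(2, 5, 9))
      expect_equal(kr$corr(d), ac(d) / a0, tolerance = 1e-3)
    expect_equal(kr$corr(7), kr$corr(-7), tolerance = 1e-12)
  }
})

test_that("finite-K force covariance converges to the kernel", {
  # 200 independent populations of K = 2000; compare the empirical
  # correlation of F(30), F(35) with the kernel prediction, and the
  # marginal variance with the uniform-mixing closed form K/3 * s*sqrt(pi)/R
  K <- 2000; R <- 100; s <- 5
  nrep <- 200
  F1 <- F2 <- numeric(nrep)
  cfg <- rein_config(K = K, essential_range = R, niche_width = s)
  set.seed(31)
  for (i in seq_len(nrep)) {
    pop <- sample_population(cfg, seed = NULL)
    F1[i] <- total_biotic_force(pop, 30)
    F2[i] <- total_biotic_force(pop, 35)
  }
  kr <- gaussian_kernel5()
  rho <- kernel_cov(kr, 5) / kernel_cov(kr, 0)
  se_rho <- (1 - rho^2) / sqrt(nrep)
  expect_lt(abs(cor(F1, F2) - rho), 4 * se_rho)
  v_theory <- K / 3 * s * sqrt(pi) / R
  se_v <- v_theory * sqrt(2 / nrep)
  expect_lt(abs(var(F1) - v_theory), 4 * se_v)
})

test_that("sampled fields have the kernel's marginal and lag structure", {
  kr <- gaussian_kernel5()
  nrep <- 300
  samp <- sapply(seq_len(nrep), function(i)
    sample_force_field(kr, 1, 100, seed = 1000 + i)$samples[, 1])
  # marginal variance k(0) = 1, pooled over nodes and replicates
  expect_equal(mean(samp^2), 1, tolerance = 0.05)
  # adjacent-node correlation equals corr(h)
  h <- 100 / ceiling(100 / 1.25)
  rho <- kr$corr(h)
  emp <- cor(as.numeric(samp[-nrow(samp), ]), as.numeric(samp[-1, ]))
  expect_equal(emp, rho, tolerance = 0.005)
  # determinism
  f1 <- sample_force_field(kr, 1, 100, seed = 7)
  f2 <- sample_force_field(kr, 1, 100, seed = 7)
  expect_identical(f1$samples, f2$samples)
})

test_that("separable tensor sampling factorises the full grid covariance", {
  kr <- gaussian_kernel5()
  x <- seq(0, 20, by = 2.5)
  K1 <- outer(x, x, function(a, b) kr$corr(a - b))
  pts <- as.matrix(expand.grid(x, x))
  Kf <- outer(seq_len(nrow(pts)), seq_len(nrow(pts)),
              Vectorize(function(i, j)
                kr$corr(pts[i, 1] - pts[j, 1]) *
                  kr$corr(pts[i, 2] - pts[j, 2])))
  expect_equal(kronecker(K1, K1), Kf, tolerance = 1e-12)
  # the separable sampler reproduces the same covariance empirically
  nrep <- 400
  set.seed(9)
  v <- matrix(0, nrep, 2)
  for (i in seq_len(nrep)) {
    fl <- sample_force_field(kr, 2, 20, h = 2.5, seed = 5000 + i)
    v[i, 1] <- fl$samples[3, 3, 1]
    v[i, 2] <- fl$samples[3, 5, 1]
  }
  expect_equal(mean(v[, 1]^2), 1, tolerance = 0.2)
  expect_equal(cor(v[, 1], v[, 2]), kr$corr(5), tolerance = 0.12)
  # direct dense factorisation agrees with the separable path in law
  fd <- sample_force_field(kr, 2, 20, h = 2.5, seed = 1, method = "direct")
  fs <- sample_force_field(kr, 2, 20, h = 2.5, seed = 1)
  expect_identical(dim(fd$samples), dim(fs$samples))
})

test_that("interpolation is exact at nodes and linear between them", {
  kr <- gaussian_kernel5()
  fld <- sample_force_field(kr, 1, 100, seed = 12)
  x <- fld$grid[[1]]
  expect_equal(field_at(fld, x[10]), fld$samples[10, 1])
  expect_equal(field_at(fld, (x[10] + x[11]) / 2),
               mean(fld$samples[10:11, 1]))
  # clamped with a warning outside the hull, error in strict mode
  expect_warning(field_at(fld, 101), "clamp")
  expect_error(field_at(fld, 101, strict = TRUE), "outside")
  # 2-D: exact at nodes, bilinear at cell centres
  f2 <- sample_force_field(kr, 2, 20, h = 2.5, seed = 13)
  g <- f2$grid[[1]]
  expect_equal(field_at(f2, c(g[2], g[4])),
               c(f2$samples[2, 4, 1], f2$samples[2, 4, 2]))
  ctr <- c(mean(g[2:3]), mean(g[4:5]))
  expect_equal(field_at(f2, ctr)[1], mean(f2$samples[2:3, 4:5, 1]))
})

test_that("linear interpolation stays within the GP conditional bound", {
  # against the kriging oracle: conditional mean/sd given all grid nodes
  kr <- gaussian_kernel5()
  fld <- sample_force_field(kr, 1, 100, seed = 77)
  x <- fld$grid[[1]]
  z <- fld$samples[, 1]
  Kmat <- outer(x, x, function(a, b) kr$corr(a - b)) +
    1e-10 * diag(length(x))
  mid <- (x[-1] + x[-length(x)]) / 2
  kv <- outer(mid, x, function(a, b) kr$corr(a - b))
  w <- kv %*% solve(Kmat)
  cond_mean <- drop(w %*% z)
  cond_var <- pmax(0, 1 - rowSums(w * kv))
  lin <- vapply(mid, function(m) field_at(fld, m), numeric(1))
  # linear interpolation differs from the conditional mean by at most the
  # second-difference error h^2/8 * |f''|, with sd(f'') = sqrt(3)/l^2 for
  # the squared-exponential kernel: allow four curvature sds plus the
  # conditional envelope
  l <- fld$kernel$length_scale
  h <- fld$h
  bound <- (h^2 / 8) * 4 * sqrt(3) / l^2 + 4 * max(sqrt(cond_var))
  expect_lt(max(abs(lin - cond_mean)), bound)
})

test_that("the finite-K force is Gaussian at large K but not at K = 3", {
  # central-limit direction check on the one-point marginal
  cfg_big <- rein_config(K = 10000)
  cfg_small <- rein_config(K = 3)
  set.seed(55)
  nrep <- 300
  big <- vapply(seq_len(nrep), function(i)
    total_biotic_force(sample_population(cfg_big, seed = NULL), 50),
    numeric(1))
  small <- vapply(seq_len(nrep), function(i)
    total_biotic_force(sample_population(cfg_small, seed = NULL), 50),
    numeric(1))
  expect_gt(shapiro.test(big)$p.value, 0.01)
  expect_lt(shapiro.test(small)$p.value, 1e-6)
})

test_that("fields round-trip through their text serialisation", {
  kr <- force_kernel(niche_shape("gaussian", 5))
  fld <- sample_force_field(kr, 2, 40, h = 2.5, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_field(fld, f)
  back <- read_field(f)
  expect_equal(back$samples, fld$samples, tolerance = 1e-15)
  expect_equal(back$h, fld$h)
  expect_equal(back$kernel$width, 5)
  expect_equal(field_at(back, c(17, 23)), field_at(fld, c(17, 23)))
})
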