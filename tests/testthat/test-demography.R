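test_that("mismatch distribution counts pairs correctly", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3,
              dimnames = list(c("D", "E", "H"), c("D", "E", "H")))
  d["E", "H"] <- d["H", "E"] <- 2
  d["D", "H"] <- d["H", "D"] <- 1
  # one-haplotype sample: all pairs identical
  f0 <- mismatch_distribution(c(A = 8), matrix(0, 1, 1,
                                               dimnames = list("A", "A")),
                              counts = TRUE)
  expect_equal(as.numeric(f0), 1)
  # the haplogroup-II composition under one count policy
  f <- mismatch_distribution(c(D = 109, E = 14, H = 8), d, counts = TRUE)
  expect_equal(as.numeric(f), c(6005, 2398, 112) / 8515, tolerance = 1e-12)
  # two singletons three steps apart: spike at class 3
  d3 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  f3 <- mismatch_distribution(c("A", "B"), d3)
  expect_equal(as.numeric(f3), c(0, 0, 0, 1))
  # order invariance and mean = average pairwise difference
  set.seed(14)
  haps <- sample(c("D", "E", "H"), 20, replace = TRUE)
  f1 <- mismatch_distribution(haps, d)
  f2 <- mismatch_distribution(rev(haps), d)
  expect_equal(f1, f2)
  dd <- d[haps, haps]
  expect_equal(sum(as.numeric(f1) * as.numeric(names(f1))),
               mean(dd[upper.tri(dd)]), tolerance = 1e-12)
  expect_error(mismatch_distribution("A", d), ">= 2")
})

test_that("expected mismatch matches its limits and a numerical oracle", {
  # tau = 0: equilibrium geometric spectrum at theta0
  f <- expected_mismatch(0, 2, 5, 0:30)
  geom <- 2^(0:30) / 3^(1:31)
  expect_equal(as.numeric(f), geom / sum(geom), tolerance = 1e-9)
  # theta0 = 0, large theta1: Poisson(tau)
  f2 <- expected_mismatch(3, 0, 1e7, 0:30)
  expect_equal(as.numeric(f2), dpois(0:30, 3) / ppois(30, 3),
               tolerance = 1e-4)
  expect_equal(sum(expected_mismatch(1.7, 0.3, 12, 0:25)), 1,
               tolerance = 1e-12)
  # numerical oracle: integrate the coalescence-time mixture directly
  tau <- 2.5; th0 <- 0.8; th1 <- 40
  jmax <- 40
  oracle <- vapply(0:jmax, function(j) {
    recent <- stats::integrate(function(x)
      exp(-x / th1) / th1 * dpois(j, x), 0, tau, rel.tol = 1e-10)$value
    old <- exp(-tau / th1) * sum(dpois(0:j, tau) *
      th0^(j - 0:j) / (1 + th0)^(j - 0:j + 1))
    recent + old
  }, numeric(1))
  oracle <- oracle / sum(oracle)
  expect_equal(as.numeric(expected_mismatch(tau, th0, th1, 0:jmax)),
               oracle, tolerance = 1e-6)
  expect_error(expected_mismatch(-1, 0, 1), "input error")
  expect_error(expected_mismatch(1, 5, 2), "input error")
})

test_that("raggedness follows the fixed boundary convention", {
  # spike at class 0: rise and fall both count
  expect_equal(raggedness(c(1)), 2)
  # uniform spectrum: only the two boundary terms remain
  u <- rep(1 / 10, 10)
  expect_equal(raggedness(u), 2 / 100, tolerance = 1e-12)
  # smooth unimodal spectra are less ragged than shuffled versions
  set.seed(15)
  for (rep in 1:5) {
    smooth <- dpois(0:12, 4)
    smooth <- smooth / sum(smooth)
    shuffled <- sample(smooth)
    expect_lt(raggedness(smooth), raggedness(shuffled))
  }
})

test_that("the sudden-expansion fit is self-consistent and deterministic", {
  f_true <- expected_mismatch(3, 1, 100, 0:25)
  fit <- fit_sudden_expansion(f_true)
  expect_lt(fit$ssd, 1e-6)
  expect_equal(fit$tau, 3, tolerance = 0.1)
  fit_b <- fit_sudden_expansion(f_true)
  expect_identical(fit$tau, fit_b$tau)
  # a spike at zero demands tau near zero
  spike <- c(1, rep(0, 6))
  fit0 <- fit_sudden_expansion(spike)
  expect_lt(fit0$tau, 0.2)
})

test_that("the coalescent simulator matches closed-form expectations", {
  set.seed(16)
  # equilibrium: mean pairwise difference ~ theta
  means <- replicate(300, {
    D <- sim_sudden_expansion(10, 0, 4, 4)
    mean(D[upper.tri(D)])
  })
  expect_equal(mean(means), 4, tolerance = 0.15)
  # expansion: E[pi] = E[pair coalescence time] =
  #   theta1 (1 - e^(-tau/theta1)) + theta0 e^(-tau/theta1)
  tau <- 3; th0 <- 0.5; th1 <- 50
  expected <- th1 * (1 - exp(-tau / th1)) + th0 * exp(-tau / th1)
  means2 <- replicate(300, {
    D <- sim_sudden_expansion(10, tau, th0, th1)
    mean(D[upper.tri(D)])
  })
  expect_equal(mean(means2), expected, tolerance = 0.1)
})

test_that("simulated datasets are reproducible and collapse correctly", {
  a <- simulate_expansion_dataset(20, 2, 0.5, 50, n_pops = 2, seed = 17)
  b <- simulate_expansion_dataset(20, 2, 0.5, 50, n_pops = 2, seed = 17)
  expect_identical(a, b)
  expect_equal(sum(a$counts), 20)
  # step distances between collapsed haplotypes agree with individuals
  for (i in seq_along(a$haplotype)) for (j in seq_along(a$haplotype))
    expect_equal(a$d[a$haplotype[i], a$haplotype[j]], a$D[i, j])
})

test_that("the parametric bootstrap accepts data from the fitted model", {
  set.seed(18)
  D <- sim_sudden_expansion(60, 4, 0.5, 60)
  f <- mismatch_distribution(paste0("i", seq_len(nrow(D))),
                             `dimnames<-`(D, list(paste0("i", 1:nrow(D)),
                                                  paste0("i", 1:nrow(D)))))
  fit <- fit_sudden_expansion(f, refine = FALSE)
  pb <- parametric_bootstrap(fit, n = 60, B = 60, seed = 19)
  expect_gt(pb$p_ssd, 0.05)
  expect_gte(pb$p_rag, 0.05)
  expect_error(parametric_bootstrap(fit, n = 60, B = 0), "B must be")
})

test_that("expansion-time conversion follows T = tau/2u with u = mu k g", {
  expect_equal(expansion_time(0)$generations, 0)
  et <- expansion_time(0.773, mu = 1.52e-9, k = 2106, g = 1)
  expect_equal(et$u, 1.52e-9 * 2106, tolerance = 1e-12)
  expect_equal(et$generations, 0.773 / (2 * 1.52e-9 * 2106),
               tolerance = 1e-9)
  expect_equal(et$myr, 0.1207, tolerance = 1e-3)
  expect_equal(expansion_time(1, k = 4212)$generations,
               expansion_time(1, k = 2106)$generations / 2,
               tolerance = 1e-12)
  expect_error(expansion_time(1, mu = 0), "positive")
})
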