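test_that("degree-minute coordinates parse to decimal degrees", {
  expect_equal(parse_dms("90°00′"), 90)
  expect_equal(parse_dms("91°06′"), 91.1)
  expect_equal(parse_dms("91°06′/30°29′"),
               c(lon = 91.1, lat = 30 + 29 / 60))
  expect_error(parse_dms("not a coordinate"), "parse error")
})

test_that("haversine distances match an independent spherical oracle", {
  p <- c(91.1, 30.4833)
  expect_equal(great_circle(p, p), 0)
  expect_equal(great_circle(c(0, 0), c(180, 0)), pi * 6371,
               tolerance = 1e-9)
  q <- c(91.433, 29.7)
  expect_equal(great_circle(p, q), oracle_great_circle(p, q),
               tolerance = 1e-6)
  expect_error(great_circle(c(0, 95), c(0, 0)), "latitude")
})

test_that("AMOVA components equal the individual-level sums-of-squares oracle", {
  set.seed(41)
  k <- 4
  d <- matrix(0, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
  d[upper.tri(d)] <- sample(1:5, 6, replace = TRUE)
  d <- d + t(d)
  counts <- matrix(c(4, 1, 0, 2,
                     0, 3, 2, 1,
                     1, 0, 5, 0), 3, k, byrow = TRUE,
                   dimnames = list(paste0("p", 1:3), LETTERS[1:k]))
  grouping <- c(p1 = "g1", p2 = "g1", p3 = "g2")
  res <- amova(counts, d, grouping = grouping[rownames(counts)],
               n_perm = 49, seed = 2)
  ind <- expand_counts(counts)
  ind_d2 <- d[ind$hap, ind$hap]
  ss <- oracle_amova_ss(ind_d2, ind$pop, grouping)
  expect_equal(res$ss, ss, tolerance = 1e-10)
  # components sum to the total variance implied by the Phi-statistics
  expect_equal(res$FST, (res$sigma[1] + res$sigma[2]) / sum(res$sigma),
               ignore_attr = TRUE, tolerance = 1e-12)
  # invariance to population relabeling
  perm <- c(3, 1, 2)
  res2 <- amova(counts[perm, ], d, grouping = grouping[rownames(counts)[perm]],
                n_perm = 0)
  expect_equal(sort(res2$sigma), sort(res$sigma), tolerance = 1e-10)
})

test_that("AMOVA hits its degenerate corners", {
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  same <- rbind(p1 = c(A = 4, B = 4), p2 = c(A = 4, B = 4),
                p3 = c(A = 4, B = 4))
  res <- amova(same, d, n_perm = 99, seed = 3)
  # identical compositions: no among-population variance; the unbiased
  # component goes slightly negative and is reported as computed
  expect_lt(res$FST, 0.05)
  expect_true(res$negative_components)
  expect_gt(res$p["FST"], 0.5)
  private <- rbind(p1 = c(A = 5, B = 0), p2 = c(A = 0, B = 5))
  res2 <- amova(private, d, n_perm = 49, seed = 4)
  expect_equal(res2$FST, 1, tolerance = 1e-12)
  mono <- rbind(p1 = c(A = 5, B = 0), p2 = c(A = 5, B = 0))
  expect_error(amova(mono, d, n_perm = 0), "degenerate")
})

test_that("pairwise Phi_ST agrees with the two-population AMOVA", {
  set.seed(51)
  k <- 3
  d <- matrix(0, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
  d[upper.tri(d)] <- c(1, 2, 3)
  d <- d + t(d)
  counts <- matrix(c(4, 2, 0,
                     1, 3, 2,
                     0, 1, 5), 3, k, byrow = TRUE,
                   dimnames = list(paste0("p", 1:3), LETTERS[1:k]))
  pw <- pairwise_phist(counts, d, n_perm = 99, seed = 6)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    ref <- amova(counts[pair, ], d, n_perm = 0)
    expect_equal(pw$phist[pair[1], pair[2]], ref$FST, tolerance = 1e-12)
  }
  expect_true(all(pw$p[upper.tri(pw$p)] > 0 & pw$p[upper.tri(pw$p)] <= 1))
  fixed <- rbind(p1 = c(A = 5, B = 0, C = 0), p2 = c(A = 0, B = 5, C = 0))
  expect_equal(pairwise_phist(fixed, d, n_perm = 0)$phist[1, 2], 1,
               tolerance = 1e-12)
})

test_that("Mantel correlation is exact at its corners and affine-invariant", {
  set.seed(61)
  n <- 8
  m1 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  res <- mantel_test(m1, m1, n_perm = 99, seed = 7)
  expect_equal(res$r, 1, tolerance = 1e-12)
  res_neg <- mantel_test(m1, -m1 + 10, n_perm = 99, seed = 7)
  expect_equal(res_neg$r, -1, tolerance = 1e-12)
  m2 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  r_raw <- mantel_test(m1, m2, n_perm = 9, seed = 8)$r
  r_aff <- mantel_test(m1 * 3 + 2, m2 * 0.5 - 1, n_perm = 9, seed = 8)$r
  expect_equal(r_raw, r_aff, tolerance = 1e-12)
  expect_error(mantel_test(m1, matrix(1, n, n), n_perm = 9),
               "correlation-undefined")
})

test_that("Mantel agrees with vegan as an independent cross-check", {
  set.seed(71)
  n <- 10
  m1 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  m2 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  ours <- mantel_test(m1, m2, n_perm = 499, seed = 9,
                      alternative = "greater")
  ref <- vegan::mantel(m1, m2, permutations = 499)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.1)
})

test_that("SAMOVA recovers a planted two-cluster partition with F_CT = 1", {
  d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  counts <- rbind(p1 = c(A = 6, B = 0), p2 = c(A = 6, B = 0),
                  p3 = c(A = 6, B = 0),
                  p4 = c(A = 0, B = 6), p5 = c(A = 0, B = 6),
                  p6 = c(A = 0, B = 6))
  coords <- data.frame(lon = c(90, 90.2, 90.1, 95, 95.2, 95.1),
                       lat = c(30, 30.1, 30.3, 33, 33.1, 33.3))
  res <- samova(counts, d, coords, K = 2, n_rep = 5, n_steps = 400,
                seed = 10)
  expect_equal(res$FCT, 1, tolerance = 1e-12)
  expect_length(unique(res$grouping[1:3]), 1L)
  expect_length(unique(res$grouping[4:6]), 1L)
  expect_false(res$grouping[1] == res$grouping[4])
  expect_equal(max(res$FCT_per_rep), res$FCT)
})

test_that("SAMOVA with K = number of populations is the singleton partition", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  counts <- rbind(p1 = c(A = 4, B = 1), p2 = c(A = 1, B = 4),
                  p3 = c(A = 3, B = 2))
  coords <- data.frame(lon = c(90, 91, 92), lat = c(30, 31, 30))
  res <- samova(counts, d, coords, K = 3, n_rep = 2, n_steps = 50, seed = 11)
  expect_length(unique(res$grouping), 3L)
  expect_error(samova(counts, d, coords, K = 1), "K out of range")
})
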