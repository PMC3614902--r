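test_that("K2P distance matches its closed form and ape's implementation", {
  s <- strsplit(paste(rep("ACGT", 25), collapse = ""), "")[[1]]
  expect_equal(k2p_distance(s, s), 0)
  # one transition among 100 sites: P = 0.01, Q = 0
  s2 <- s; s2[1] <- "G"
  expect_equal(k2p_distance(s, s2), -0.5 * log(1 - 0.02), tolerance = 1e-12)
  # one transversion among 100 sites: P = 0, Q = 0.01
  s3 <- s; s3[1] <- "C"
  expect_equal(k2p_distance(s, s3),
               -0.5 * log(0.99) - 0.25 * log(0.98), tolerance = 1e-12)
  set.seed(81)
  base <- sample(c("a", "c", "g", "t"), 200, replace = TRUE)
  m <- rbind(base, base, base)
  for (i in 2:3) {                      # ~10% divergence per sequence
    mut <- sample(200, 20)
    m[i, mut] <- sample(c("a", "c", "g", "t"), 20, replace = TRUE)
  }
  rownames(m) <- paste0("s", 1:3)
  dref <- ape::dist.dna(ape::as.DNAbin(m), model = "K80")
  aln <- aligned_sequences(toupper(m))
  expect_equal(as.vector(as.dist(k2p_matrix(aln))), as.vector(dref),
               tolerance = 1e-10)
  expect_error(k2p_distance(s, rep("A", 100)), "saturation")
})

test_that("NJ recovers random additive trees exactly", {
  set.seed(91)
  for (rep in 1:10) {
    tr <- ape::rtree(sample(5:9, 1))
    tr$edge.length <- tr$edge.length + 0.05  # keep branches positive
    d <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(d, midpoint = FALSE)
    expect_equal(ape::dist.topo(ape::unroot(tr), rec), 0,
                 ignore_attr = TRUE)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), ">= 3 taxa")
})

test_that("the step-distance NJ tree separates the two haplogroups", {
  hm <- load_table2()
  tr <- nj_tree(pairwise_steps(hm), midpoint = TRUE)
  hpg2 <- hv_constants()$hpg2
  mrca <- ape::getMRCA(tr, hpg2)
  clade <- ape::extract.clade(tr, mrca)$tip.label
  expect_setequal(clade, hpg2)
})

test_that("NJ bootstrap is deterministic per seed and supports clean splits", {
  # two clearly separated clades with many concordant characters
  m <- rbind(A = rep(c("A", "A"), each = 10), B = rep(c("A", "A"), each = 10),
             C = rep(c("C", "C"), each = 10), D = rep(c("C", "C"), each = 10))
  m[, 1] <- c("A", "G", "C", "C")  # some within-clade variation
  m[, 11] <- c("A", "A", "C", "T")
  hm <- haplo_matrix(m)
  b1 <- nj_bootstrap(hm, n_reps = 100, seed = 12)
  b2 <- nj_bootstrap(hm, n_reps = 100, seed = 12)
  expect_identical(b1$support, b2$support)
  expect_gte(max(b1$support), 99)  # the AB|CD split is in every replicate
})

test_that("parsimony limit is monotone in length with the right extremes", {
  expect_equal(parsimony_limit(1000, p = 0.999999), 1L)
  lims <- vapply(c(100, 500, 1000, 2106, 5000), parsimony_limit, integer(1))
  expect_true(all(diff(lims) >= 0))
  expect_gte(parsimony_limit(2106), 5L)
  # direct evaluation of the product for small L
  L <- 50
  probs <- cumprod(c(1, 1 - seq_len(L - 1) / L))
  expect_equal(parsimony_limit(L, 0.9), max(which(probs >= 0.9)))
})

test_that("two haplotypes one step apart give a single direct edge", {
  m <- rbind(A = c("A", "C"), B = c("A", "T"))
  net <- tcs_network(haplo_matrix(m), L = 500)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(sum(net$nodes$type == "inferred"), 0L)
})

test_that("the fixture network matches the published topology", {
  hm <- load_table2()
  freqs <- colSums(rebuild_published_dataset()$counts)
  net <- tcs_network(hm, freqs = freqs)
  one_step <- c("A-B", "A-E", "A-F", "B-G", "D-E", "D-H")
  direct <- apply(net$edges, 1, function(e)
    paste(sort(e), collapse = "-"))
  expect_true(all(one_step %in% direct))
  # C attaches through exactly one inferred intermediate
  expect_equal(sum(net$nodes$type == "inferred"), 1L)
  mid <- net$nodes$label[net$nodes$type == "inferred"]
  expect_setequal(c(net$edges$from[net$edges$to == mid],
                    net$edges$to[net$edges$from == mid]), c("A", "C"))
  # the two published hubs
  deg <- table(c(net$edges$from, net$edges$to))
  expect_gte(deg[["A"]], 3)
  expect_gte(deg[["D"]], 2)
  expect_length(unique(net$components), 1L)
})

test_that("network path lengths reproduce step distances within the limit", {
  hm <- load_table2()
  net <- tcs_network(hm)
  d <- pairwise_steps(hm)
  paths <- network_path_lengths(net)
  obs <- rownames(d)
  expect_equal(paths[obs, obs], matrix(as.numeric(d), 8, 8,
                                       dimnames = dimnames(d)))
})

test_that("strict-clock ages follow the closed form and scale correctly", {
  m <- rbind(A = c("A", "C", "G", "T"), B = c("T", "C", "G", "A"))
  hm <- haplo_matrix(m)
  dat <- strict_clock_age(hm, "A", "B", mu = 1e-9, L = 1000, n_boot = 0)
  expect_equal(dat$age_myr, 2 / (2 * 1e-9 * 1000) / 1e6, tolerance = 1e-12)
  dat2 <- strict_clock_age(hm, "A", "B", mu = 2e-9, L = 1000, n_boot = 0)
  expect_equal(dat2$age_myr, dat$age_myr / 2, tolerance = 1e-12)
  dat3 <- strict_clock_age(hm, "A", "B", mu = 1e-9, L = 2000, n_boot = 0)
  expect_equal(dat3$age_myr, dat$age_myr / 2, tolerance = 1e-12)
  expect_error(strict_clock_age(hm, "A", "A"), "disjoint")
})

test_that("simulated clock data recover the generating root age", {
  # two lineages split T years ago accumulate Poisson(2 mu L T)
  # substitutions over L sites; the character-bootstrap interval should
  # cover the true age in roughly 95% of replicates
  set.seed(13)
  mu <- 1e-7; L <- 1000L; T_true <- 5e5
  lambda <- 2 * mu * L * T_true   # = 100 expected differences
  n_rep <- 30L
  hits <- 0L
  for (rep in seq_len(n_rep)) {
    n_diff <- max(1L, rpois(1, lambda))
    chars <- matrix("A", 2, L)
    chars[2, seq_len(n_diff)] <- "C"
    rownames(chars) <- c("g1", "g2")
    colnames(chars) <- paste0("s", seq_len(L))
    hm <- haplo_matrix(chars)
    dat <- strict_clock_age(hm, "g1", "g2", mu = mu, L = L, n_boot = 200)
    if (dat$interval_myr[1] <= T_true / 1e6 &&
        dat$interval_myr[2] >= T_true / 1e6) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.85)
})
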