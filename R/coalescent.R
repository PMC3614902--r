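#' Simulate pairwise differences under the sudden-expansion coalescent
#'
#' Coalescent of `n` lineages with an instantaneous population-size change:
#' time is measured in mutational units (the units of tau), the pairwise
#' coalescence rate is 1/theta1 more recently than `tau` and 1/theta0
#' before it, and mutations fall on branches as a Poisson process with rate
#' 1/2 per lineage per unit time, each at a new site (infinite sites). At
#' equilibrium (tau = 0 or theta0 = theta1) the expected pairwise
#' difference equals theta.
#'
#' @param n Sample size (>= 2).
#' @param tau Expansion age in mutational units (>= 0).
#' @param theta0,theta1 Pre- and post-expansion scaled sizes
#'   (0 <= theta0, theta1 > 0).
#' @return Integer matrix (n x n) of pairwise differences.
#' @export
sim_sudden_expansion <- function(n, tau, theta0, theta1) {
  stopifnot(n >= 2L, tau >= 0, theta0 >= 0, theta1 > 0)
  ## coalescence times (backwards); epoch switch at tau
  active <- as.list(seq_len(n))          # tip sets of live lineages
  birth <- rep(0, n)                     # time each live lineage began
  branches <- vector("list", 2L * n - 2L)
  blen <- numeric(2L * n - 2L)
  nb <- 0L
  t_now <- 0
  k <- n
  while (k > 1L) {
    repeat {
      theta <- if (t_now < tau) theta1 else theta0
      if (theta == 0) { t_next <- max(t_now, tau); break }
      rate <- k * (k - 1) / 2 / theta
      dt <- stats::rexp(1L, rate)
      if (t_now < tau && t_now + dt > tau) { t_now <- tau; next }
      t_next <- t_now + dt
      break
    }
    t_now <- t_next
    pair <- sample.int(k, 2L)
    for (idx in pair) {
      nb <- nb + 1L
      branches[[nb]] <- active[[idx]]
      blen[nb] <- t_now - birth[idx]
    }
    merged <- c(active[[pair[1L]]], active[[pair[2L]]])
    active[[pair[1L]]] <- merged
    birth[pair[1L]] <- t_now
    active <- active[-pair[2L]]
    birth <- birth[-pair[2L]]
    k <- k - 1L
  }
  ## mutations per branch ~ Poisson(len / 2); D_ij = mutations on the path
  muts <- stats::rpois(nb, blen[seq_len(nb)] / 2)
  D <- matrix(0L, n, n)
  u <- numeric(n)
  Z <- matrix(0, nb, n)
  for (b in seq_len(nb)) Z[b, branches[[b]]] <- 1
  u <- colSums(muts * Z)
  cross <- crossprod(Z, muts * Z)
  D <- outer(u, rep(1, n)) + outer(rep(1, n), u) - 2 * cross
  storage.mode(D) <- "integer"
  diag(D) <- 0L
  D
}

#' Mismatch spectrum of a pairwise-difference matrix
#' @param D Symmetric integer matrix of pairwise differences.
#' @return Relative-frequency spectrum over classes 0..max (named vector).
#' @keywords internal
diff_matrix_spectrum <- function(D) {
  v <- D[upper.tri(D)]
  tab <- tabulate(v + 1L, nbins = max(v) + 1L)
  f <- tab / sum(tab)
  names(f) <- 0:(length(f) - 1L)
  f
}

#' Simulate a (possibly subdivided) expansion dataset
#'
#' Draws one sudden-expansion coalescent sample, collapses identical
#' mutation profiles into haplotypes, and optionally spreads the
#' individuals over `n_pops` populations. `migration = 1` assigns
#' individuals to populations completely at random (no structure, the null
#' of the differentiation tests); `migration = 0` assigns them by clustering
#' the pairwise differences, planting maximal structure; intermediate values
#' randomly reassign that fraction of individuals.
#'
#' @param n Number of individuals.
#' @param tau,theta0,theta1 Sudden-expansion parameters (see
#'   [sim_sudden_expansion()]).
#' @param n_pops Number of populations (default 1).
#' @param migration Mixing fraction in `[0, 1]` (default 1 = panmixia).
#' @param seed Optional integer seed.
#' @return List: `haplotype` (per-individual labels), `pop` (factor),
#'   `counts` (population x haplotype matrix), `d` (haplotype step-distance
#'   matrix), `D` (individual difference matrix).
#' @export
simulate_expansion_dataset <- function(n, tau, theta0, theta1,
                                       n_pops = 1L, migration = 1,
                                       seed = NULL) {
  stopifnot(n_pops >= 1L, migration >= 0, migration <= 1)
  if (!is.null(seed)) set.seed(seed)
  D <- sim_sudden_expansion(n, tau, theta0, theta1)
  ## collapse to haplotypes: identical rows of D <=> identical profiles
  key <- apply(D, 1L, paste, collapse = ",")
  first <- !duplicated(key)
  hap_id <- match(key, key[first])
  labs <- default_haplotype_labels(sum(first))
  hap <- labs[hap_id]
  d <- D[first, first, drop = FALSE]
  dimnames(d) <- list(labs, labs)

  if (n_pops == 1L) {
    pop <- factor(rep("P1", n))
  } else {
    base <- rep_len(seq_len(n_pops), n)
    if (migration >= 1) {
      pop_idx <- sample(base)
    } else {
      hc <- stats::hclust(stats::as.dist(D), method = "average")
      pop_idx <- stats::cutree(hc, k = n_pops)
      ## enforce non-empty after cut (cutree guarantees k groups)
      mix <- which(stats::runif(n) < migration)
      if (length(mix)) pop_idx[mix] <- sample.int(n_pops, length(mix),
                                                  replace = TRUE)
    }
    pop <- factor(paste0("P", pop_idx), levels = paste0("P", seq_len(n_pops)))
  }
  counts <- table(pop, factor(hap, levels = labs))
  counts <- matrix(as.integer(counts), nrow = nlevels(pop),
                   dimnames = list(levels(pop), labs))
  list(haplotype = hap, pop = pop, counts = counts, d = d, D = D)
}
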