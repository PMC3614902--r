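#' Kimura two-parameter distance between two aligned sequences
#'
#' d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q), with P and Q the
#' proportions of transitions and transversions among the sites compared;
#' columns where either sequence has a gap or N are excluded pairwise.
#'
#' @param seq1,seq2 Character vectors of equal length (A/C/G/T/-/N).
#' @return K2P distance (substitutions/site).
#' @export
k2p_distance <- function(seq1, seq2) {
  if (length(seq1) != length(seq2))
    stop("input error: sequences must have equal length")
  ok <- seq1 %in% c("A", "C", "G", "T") & seq2 %in% c("A", "C", "G", "T")
  a <- seq1[ok]
  b <- seq2[ok]
  n <- length(a)
  if (n == 0L) stop("input error: no comparable sites")
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturation error: K2P distance undefined")
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' K2P distance matrix for an alignment
#' @param aln An [aligned_sequences()] object.
#' @return Symmetric matrix of K2P distances.
#' @export
k2p_matrix <- function(aln) {
  m <- aln$seqs
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- k2p_distance(m[i, ], m[j, ])
  d
}

#' Neighbor-joining tree, optionally midpoint rooted
#'
#' Saitou-Nei agglomeration (via \pkg{ape}) on any distance matrix;
#' midpoint rooting places the root halfway along the longest
#' leaf-to-leaf path (via \pkg{phangorn}).
#'
#' @param d Distance matrix (>= 3 taxa).
#' @param midpoint Root the tree at its midpoint (default TRUE)?
#' @return An \pkg{ape} `phylo` tree.
#' @export
nj_tree <- function(d, midpoint = TRUE) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("input error: need >= 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  if (midpoint) tr <- phangorn::midpoint(tr)
  tr
}

#' Bootstrap supports for the NJ tree of a haplotype matrix
#'
#' Resamples the characters (columns) with replacement, rebuilds the step
#' distances and the NJ tree each time, and maps bipartition frequencies
#' (percent) onto the reference tree's internal nodes.
#'
#' @param hm A [haplo_matrix()].
#' @param n_reps Bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @return List: `tree` (reference NJ tree, unrooted, with `node.label`
#'   percent supports) and `support` (numeric vector per internal node).
#' @export
nj_bootstrap <- function(hm, n_reps = 1000L, seed = NULL) {
  if (n_reps < 1L) stop("input error: n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ref <- nj_tree(pairwise_steps(hm), midpoint = FALSE)
  nc <- ncol(hm)
  boot <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    m <- unclass_hm(hm)[, cols, drop = FALSE]
    k <- nrow(m)
    db <- matrix(0, k, k, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(k - 1L))
      for (j in (i + 1L):k)
        db[i, j] <- db[j, i] <- sum(m[i, ] != m[j, ])
    boot[[b]] <- ape::nj(stats::as.dist(db))
  }
  counts <- ape::prop.clades(ref, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_reps
  ref$node.label <- round(support, 1)
  list(tree = ref, support = support)
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps j for which the probability that j
#' mutations on an L-site sequence all strike distinct sites (so that the
#' minimum-step connection is the true genealogical one) is at least `p`:
#' P(j) = prod_{i=1}^{j-1} (1 - i/L). The classical 95% limit grows with
#' sequence length; haplotype pairs beyond the limit are left unconnected.
#'
#' @param L Number of sites (>= 1).
#' @param p Connection probability limit (default 0.95).
#' @return Integer number of steps (>= 1).
#' @export
parsimony_limit <- function(L, p = 0.95) {
  stopifnot(L >= 1, p > 0, p <= 1)
  j <- 1L
  prob <- 1
  while (j < L) {
    nxt <- prob * (1 - j / L)
    if (nxt < p) break
    prob <- nxt
    j <- j + 1L
  }
  j
}

#' Statistical-parsimony haplotype network
#'
#' Connects haplotypes in order of increasing mutational steps, joining two
#' network components only when their closest pair is within the
#' connection limit; multi-step connections insert inferred intermediate
#' nodes so that every edge spans exactly one step. Ties at equal distance
#' are broken toward the pair with higher total frequency, then
#' lexicographically.
#'
#' @param hm A [haplo_matrix()].
#' @param freqs Optional named frequencies/counts of the observed
#'   haplotypes (used for tie-breaking and node annotation).
#' @param p Connection probability limit (default 0.95).
#' @param L Sequence length used for the limit; defaults to the summed
#'   locus lengths of `hm`'s site table when available, else the number of
#'   characters.
#' @return Object of class `haplo_network`: `nodes` (label, type, freq),
#'   `edges` (from, to, one step each), `limit`, `components` (membership
#'   for observed haplotypes). A warning is issued when the network is
#'   disconnected at the limit.
#' @export
tcs_network <- function(hm, freqs = NULL, p = 0.95, L = NULL) {
  d <- pairwise_steps(hm)
  labs <- rownames(d)
  k <- length(labs)
  if (is.null(L)) {
    sites <- attr(hm, "sites")
    L <- if (!is.null(sites) &&
             all(sites$locus %in% names(locus_lengths_hv())))
      sum(locus_lengths_hv()) else ncol(hm)
  }
  limit <- parsimony_limit(L, p)
  if (is.null(freqs)) freqs <- stats::setNames(rep(1, k), labs)
  freqs <- freqs[labs]
  freqs[is.na(freqs)] <- 0

  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[pairs],
               -(freqs[pairs[, 1L]] + freqs[pairs[, 2L]]),
               labs[pairs[, 1L]], labs[pairs[, 2L]])
  pairs <- pairs[ord, , drop = FALSE]

  comp <- seq_len(k)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  edges <- NULL
  nodes <- data.frame(label = labs, type = "observed",
                      freq = as.numeric(freqs), stringsAsFactors = FALSE)
  n_inferred <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    steps <- d[i, j]
    if (steps > limit) next
    ri <- find(i); rj <- find(j)
    if (ri == rj) next
    comp[ri] <- rj
    chain <- labs[i]
    if (steps > 1L) {
      mids <- paste0("m", n_inferred + seq_len(steps - 1L))
      n_inferred <- n_inferred + steps - 1L
      nodes <- rbind(nodes, data.frame(label = mids, type = "inferred",
                                       freq = 0, stringsAsFactors = FALSE))
      chain <- c(chain, mids)
    }
    chain <- c(chain, labs[j])
    edges <- rbind(edges, data.frame(from = chain[-length(chain)],
                                     to = chain[-1L],
                                     stringsAsFactors = FALSE))
  }
  roots <- vapply(seq_len(k), find, integer(1L))
  membership <- match(roots, unique(roots))
  names(membership) <- labs
  if (length(unique(membership)) > 1L)
    warning("network disconnected at the ", limit, "-step limit: ",
            length(unique(membership)), " components")
  structure(list(nodes = nodes,
                 edges = if (is.null(edges))
                   data.frame(from = character(), to = character()) else edges,
                 limit = limit, components = membership),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("Statistical-parsimony network:",
      sum(x$nodes$type == "observed"), "haplotypes,",
      sum(x$nodes$type == "inferred"), "inferred intermediate(s),",
      nrow(x$edges), "single-step edges (limit", x$limit, "steps)\n")
  invisible(x)
}

#' Strict-clock age of the split between two haplotype groups
#'
#' Point estimate = (mean mutational steps between the groups) / (2 mu L)
#' years, i.e. half the mean divergence converted with a per-site clock.
#' The uncertainty interval bootstraps the characters of the haplotype
#' matrix.
#'
#' @param hm A [haplo_matrix()].
#' @param group1,group2 Disjoint non-empty sets of haplotype labels.
#' @param mu Substitution rate (substitutions/site/year).
#' @param L Effective sequence length (bp).
#' @param n_boot Bootstrap replicates for the interval (default 1000).
#' @param conf Interval coverage (default 0.95).
#' @param seed Optional integer seed.
#' @return Object of class `dating`: `age_myr` (point), `interval_myr`,
#'   `mean_steps`, `mu`, `L`, `method`.
#' @export
strict_clock_age <- function(hm, group1, group2, mu = 1.52e-9, L = 2106,
                             n_boot = 1000L, conf = 0.95, seed = NULL) {
  stopifnot(mu > 0, L > 0)
  if (length(intersect(group1, group2)))
    stop("input error: groups must be disjoint")
  if (!length(group1) || !length(group2))
    stop("input error: groups must be non-empty")
  if (!all(c(group1, group2) %in% rownames(hm)))
    stop("input error: unknown haplotype labels")
  mean_cross <- function(d) mean(d[group1, group2, drop = FALSE])
  d <- pairwise_steps(hm)
  steps <- mean_cross(d)
  age_years <- steps / (2 * mu * L)
  if (steps == 0)
    warning("zero between-group distance: age 0")
  interval <- NULL
  if (n_boot >= 1L) {
    if (!is.null(seed)) set.seed(seed)
    nc <- ncol(hm)
    m <- unclass_hm(hm)
    ages <- vapply(seq_len(n_boot), function(b) {
      cols <- sample.int(nc, nc, replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      db <- matrix(0, nrow(mb), nrow(mb),
                   dimnames = list(rownames(mb), rownames(mb)))
      for (i in seq_len(nrow(mb) - 1L))
        for (j in (i + 1L):nrow(mb))
          db[i, j] <- db[j, i] <- sum(mb[i, ] != mb[j, ])
      mean_cross(db) / (2 * mu * L)
    }, numeric(1L))
    a <- (1 - conf) / 2
    interval <- stats::quantile(ages, c(a, 1 - a), names = FALSE) / 1e6
  }
  structure(list(age_myr = age_years / 1e6, interval_myr = interval,
                 mean_steps = steps, mu = mu, L = L,
                 group1 = group1, group2 = group2,
                 method = "strict-clock distance", n_boot = n_boot),
            class = "dating")
}

#' @export
print.dating <- function(x, ...) {
  cat(sprintf("Strict-clock split age: %.3f Myr (mean %.3g steps, mu = %g, L = %d)\n",
              x$age_myr, x$mean_steps, x$mu, as.integer(x$L)))
  if (!is.null(x$interval_myr))
    cat(sprintf("  bootstrap interval: [%.3f, %.3f] Myr (%d replicates)\n",
                x$interval_myr[1L], x$interval_myr[2L], x$n_boot))
  invisible(x)
}
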