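#' Nei's unbiased gene diversity
#'
#' h = n (1 - sum p_i^2) / (n - 1), the probability that two individuals
#' drawn without replacement carry different haplotypes.
#'
#' @param counts Vector of haplotype counts (n = sum >= 2).
#' @return Gene diversity in `[0, 1]`.
#' @export
gene_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2)
    stop("undefined-diversity error: need n >= 2")
  p <- counts / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Nucleotide diversity from haplotype counts and step distances
#'
#' pi = n/(n-1) * sum_{i != j} p_i p_j d_ij / L, the unbiased mean
#' per-site pairwise difference.
#'
#' @param counts Named vector of haplotype counts (names index `d`).
#' @param d Symmetric step-distance matrix over haplotypes.
#' @param L Sequence length in bp (> 0).
#' @return Nucleotide diversity.
#' @export
nucleotide_diversity <- function(counts, d, L) {
  if (L <= 0) stop("input error: L must be positive")
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2)
    stop("undefined-diversity error: need n >= 2")
  if (is.null(names(counts)) && length(counts) == nrow(d))
    names(counts) <- rownames(d)
  if (!all(names(counts) %in% rownames(d)))
    stop("input error: haplotypes in counts missing from distance matrix")
  p <- counts / n
  dd <- d[names(counts), names(counts), drop = FALSE]
  n / (n - 1) * as.numeric(t(p) %*% dd %*% p) / L
}

## Pons & Petit decomposition for an arbitrary dissimilarity weight matrix.
## delta[i,j] = 1 - kronecker (unordered, gives H_S/H_T) or d[i,j]
## (ordered, gives V_S/V_T). Sample-size correction uses the harmonic mean
## n-tilde across populations.
pons_petit_decomposition <- function(counts, delta) {
  counts <- as.matrix(counts)
  nk <- rowSums(counts)
  if (any(nk < 2))
    stop("input error: every population needs n >= 2")
  s <- nrow(counts)
  if (s < 2)
    stop("input error: need >= 2 populations")
  p <- counts / nk
  n_tilde <- s / sum(1 / nk)
  vk_obs <- vapply(seq_len(s), function(k)
    as.numeric(t(p[k, ]) %*% delta %*% p[k, ]), numeric(1L))
  VS <- n_tilde / (n_tilde - 1) * mean(vk_obs)
  pbar <- colMeans(p)
  VT <- as.numeric(t(pbar) %*% delta %*% pbar) + VS / (n_tilde * s)
  list(within = VS, total = VT)
}

#' Diversity decomposition and differentiation (Pons & Petit)
#'
#' Computes the frequency-based (unordered) decomposition H_S/H_T with
#' G_ST = (H_T - H_S)/H_T, and the distance-weighted (ordered)
#' decomposition V_S/V_T with N_ST = (V_T - V_S)/V_T, using the Pons &
#' Petit small-sample correction with the harmonic-mean sample size.
#' Also reports per-population and species-level (pooled) diversity.
#'
#' @param counts Population x haplotype count matrix (all n_k >= 2).
#' @param d Haplotype step-distance matrix (columns of `counts` must be a
#'   subset of its row names, or unnamed and conformable).
#' @param L Optional sequence length for nucleotide diversity.
#' @return Object of class `permut_stats`: list with `HS`, `HT`, `GST`,
#'   `VS`, `VT`, `NST`, `h_pop`, `h_species`, `pi_species` (if `L` given),
#'   `n_pops`, `n_ind`.
#' @export
permut_stats <- function(counts, d, L = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) && ncol(counts) == nrow(d))
    colnames(counts) <- rownames(d)
  if (!all(colnames(counts) %in% rownames(d)))
    stop("input error: count columns missing from distance matrix")
  d <- d[colnames(counts), colnames(counts), drop = FALSE]
  one <- 1 - diag(ncol(counts))
  un <- pons_petit_decomposition(counts, one)
  if (un$total <= 0)
    stop("differentiation-undefined error: H_T = 0")
  or <- pons_petit_decomposition(counts, d)
  pooled <- colSums(counts)
  res <- list(HS = un$within, HT = un$total,
              GST = (un$total - un$within) / un$total,
              VS = or$within, VT = or$total,
              NST = if (or$total > 0) (or$total - or$within) / or$total
                    else NA_real_,
              h_pop = apply(counts, 1L, gene_diversity),
              h_species = gene_diversity(pooled),
              pi_species = if (!is.null(L))
                nucleotide_diversity(pooled, d, L) else NULL,
              n_pops = nrow(counts), n_ind = sum(counts))
  class(res) <- "permut_stats"
  res
}

#' @export
print.permut_stats <- function(x, ...) {
  cat(sprintf("Pons & Petit decomposition (%d populations, %d individuals)\n",
              x$n_pops, x$n_ind))
  cat(sprintf("  H_S = %.3f  H_T = %.3f  G_ST = %.3f\n", x$HS, x$HT, x$GST))
  cat(sprintf("  V_S = %.3f  V_T = %.3f  N_ST = %.3f\n", x$VS, x$VT, x$NST))
  cat(sprintf("  species h = %.3f", x$h_species))
  if (!is.null(x$pi_species)) cat(sprintf("  species pi = %.4f", x$pi_species))
  cat("\n")
  invisible(x)
}

#' Permutation test comparing N_ST with G_ST
#'
#' Permutes haplotype identities in the step-distance matrix (row/column
#' relabelling), holding the haplotype frequencies fixed, and recomputes
#' N_ST each time. The U statistic standardizes the observed N_ST - G_ST
#' against the permutation distribution and is referred to a Gaussian (the
#' classical criterion: significant phylogeographical structure when
#' U > 1.96, i.e. closely related haplotypes co-occur within populations
#' more often than expected). The raw one-sided permutation fraction is
#' also returned.
#'
#' @param counts Population x haplotype count matrix.
#' @param d Haplotype step-distance matrix.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return List: `GST`, `NST`, `diff` (observed N_ST - G_ST), `U`
#'   (standardized statistic), `p` (two-sided Gaussian p for the U test),
#'   `p_empirical` (one-sided fraction of permuted N_ST - G_ST >= observed),
#'   `n_perm`.
#' @export
gst_nst_test <- function(counts, d, n_perm = 1000L, seed = NULL) {
  if (n_perm < 1L) stop("input error: n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) && ncol(counts) == nrow(d))
    colnames(counts) <- rownames(d)
  d <- d[colnames(counts), colnames(counts), drop = FALSE]
  obs <- permut_stats(counts, d)
  u_obs <- obs$NST - obs$GST
  k <- ncol(counts)
  u_perm <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(k)
    dp <- d[idx, idx, drop = FALSE]
    dimnames(dp) <- dimnames(d)
    or <- pons_petit_decomposition(counts, dp)
    nst <- (or$total - or$within) / or$total
    nst - obs$GST
  }, numeric(1L))
  s <- stats::sd(u_perm)
  U <- if (s > 0) (u_obs - mean(u_perm)) / s else 0
  list(GST = obs$GST, NST = obs$NST, diff = u_obs, U = U,
       p = 2 * stats::pnorm(-abs(U)),
       p_empirical = mean(u_perm >= u_obs), n_perm = n_perm)
}
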