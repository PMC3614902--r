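#' Observed mismatch distribution
#'
#' Relative frequency of pairwise mutational differences over all C(n,2)
#' pairs of individuals, classes 0..max.
#'
#' @param haplotypes Per-individual haplotype labels (length n >= 2), or a
#'   named count vector when `counts = TRUE`.
#' @param d Haplotype step-distance matrix.
#' @param counts Interpret `haplotypes` as a named count vector?
#' @return Named numeric vector (classes `0:max`) summing to 1, of class
#'   `mismatch_spectrum`.
#' @export
mismatch_distribution <- function(haplotypes, d, counts = FALSE) {
  if (counts) {
    cvec <- haplotypes
  } else {
    if (length(haplotypes) < 2L)
      stop("input error: need >= 2 individuals")
    cvec <- table(haplotypes)
  }
  cvec <- cvec[cvec > 0]
  n <- sum(cvec)
  if (n < 2L) stop("input error: need >= 2 individuals")
  if (!all(names(cvec) %in% rownames(d)))
    stop("input error: haplotypes missing from distance matrix")
  dd <- d[names(cvec), names(cvec), drop = FALSE]
  dmax <- max(dd)
  counts_by_class <- numeric(dmax + 1L)
  ## within-haplotype pairs: 0 differences
  counts_by_class[1L] <- sum(choose(cvec, 2L))
  if (length(cvec) > 1L) {
    for (i in seq_len(length(cvec) - 1L)) {
      for (j in (i + 1L):length(cvec)) {
        cls <- dd[i, j] + 1L
        counts_by_class[cls] <- counts_by_class[cls] + cvec[i] * cvec[j]
      }
    }
  }
  f <- counts_by_class / sum(counts_by_class)
  names(f) <- 0:dmax
  structure(f, n = n, class = c("mismatch_spectrum", "numeric"))
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' Closed-form spectrum for a population at scaled size theta1 that was at
#' theta0 until tau mutational time units ago: a pair either coalesces
#' after the expansion (geometric spectrum at theta1, truncated at tau) or
#' persists through it, accumulating Poisson(tau) differences on top of the
#' theta0 equilibrium geometric. With F.hat_j(theta) =
#' theta^j/(1+theta)^(j+1) and a = (theta1+1)/theta1:
#' F_j = F.hat_j(theta1) + e^(-a tau) * ( sum_{k<=j} tau^k/k!
#'       F.hat_{j-k}(theta0) - F.hat_j(theta1) sum_{k<=j} (a tau)^k/k! ).
#' The returned spectrum is renormalized over the requested class range.
#'
#' @param tau Expansion age in mutational units (>= 0).
#' @param theta0,theta1 Pre-/post-expansion scaled sizes
#'   (0 <= theta0 <= theta1).
#' @param classes Integer vector of difference classes (default 0:20).
#' @return Named numeric vector over `classes`, summing to 1.
#' @export
expected_mismatch <- function(tau, theta0, theta1, classes = 0:20) {
  if (tau < 0 || theta0 < 0 || theta1 < theta0 || theta1 <= 0)
    stop("input error: require tau >= 0 and 0 <= theta0 <= theta1, theta1 > 0")
  jmax <- max(classes)
  j <- 0:jmax
  geom <- function(theta) {
    if (theta == 0) c(1, rep(0, jmax)) else theta^j / (1 + theta)^(j + 1)
  }
  f1 <- geom(theta1)
  f0 <- geom(theta0)
  a <- (theta1 + 1) / theta1
  pois_tau <- stats::dpois(j, tau)                  # e^-tau tau^k / k!
  cum_atau <- stats::ppois(j, a * tau)              # e^-atau sum (atau)^k/k!
  conv <- vapply(j, function(jj)
    sum(pois_tau[1:(jj + 1L)] * rev(f0[1:(jj + 1L)])), numeric(1L))
  ## e^(-a tau) sum tau^k/k! = e^(-tau/theta1) * pois terms
  f <- f1 + exp(-tau / theta1) * conv - cum_atau * f1
  f <- pmax(f, 0)
  f <- f[classes + 1L]
  f <- f / sum(f)
  names(f) <- classes
  f
}

#' Harpending's raggedness index
#'
#' r = sum of squared successive differences of the spectrum padded with a
#' zero class at both ends (so a single spike contributes both its rise
#' and its fall). Smooth unimodal spectra give small r; multimodal or
#' spiky spectra give large r.
#'
#' @param f Mismatch spectrum (relative frequencies over classes 0..d).
#' @return Raggedness index.
#' @export
raggedness <- function(f) {
  if (length(f) < 1L) stop("input error: empty spectrum")
  sum(diff(c(0, as.numeric(f), 0))^2)
}

## pad/trim a spectrum to a class range 0..jmax (renormalized)
spectrum_on_classes <- function(f, jmax) {
  out <- numeric(jmax + 1L)
  idx <- seq_len(min(length(f), jmax + 1L))
  out[idx] <- as.numeric(f)[idx]
  out <- out / sum(out)
  names(out) <- 0:jmax
  out
}

## precomputed model spectra over a parameter grid, reusable across fits
## on the same class range (used heavily by the parametric bootstrap)
make_mismatch_grid <- function(classes, tau_max = 20, theta0_max = 10,
                               theta1_max = 1000) {
  tau_grid <- seq(0, tau_max, length.out = 21L)
  th0_grid <- c(0, exp(seq(log(0.01), log(theta0_max), length.out = 8L)))
  th1_grid <- exp(seq(log(0.1), log(theta1_max), length.out = 10L))
  par <- expand.grid(tau = tau_grid, theta0 = th0_grid, theta1 = th1_grid)
  par <- as.matrix(par[par$theta1 >= par$theta0, , drop = FALSE])
  spectra <- t(vapply(seq_len(nrow(par)), function(r)
    expected_mismatch(par[r, 1L], par[r, 2L], par[r, 3L], classes),
    numeric(length(classes))))
  list(par = par, spectra = spectra, classes = classes)
}

#' Fit the sudden-expansion model to an observed mismatch spectrum
#'
#' Minimizes the sum of squared deviations SSD = sum_j (F_obs(j) -
#' F_exp(j))^2 over (tau, theta0, theta1) on the class range
#' 0..(observed max + 5), by a coarse grid search followed (optionally) by
#' Nelder-Mead refinement. Deterministic for a fixed input.
#'
#' @param f_obs Observed spectrum (from [mismatch_distribution()]).
#' @param refine Run Nelder-Mead refinement after the grid (default TRUE)?
#' @param tau_max,theta0_max,theta1_max Grid upper bounds (defaults 20, 10,
#'   1000; theta grids are log-spaced where wide).
#' @param extra_classes Classes appended beyond the observed maximum
#'   (default 5).
#' @param grid Optional precomputed grid (internal; lets the parametric
#'   bootstrap reuse one grid across replicates).
#' @return Object of class `mismatch_fit`: `tau`, `theta0`, `theta1`,
#'   `ssd`, `classes`, `f_obs`, `f_exp`.
#' @export
fit_sudden_expansion <- function(f_obs, refine = TRUE, tau_max = 20,
                                 theta0_max = 10, theta1_max = 1000,
                                 extra_classes = 5L, grid = NULL) {
  if (is.null(grid)) {
    jmax <- (length(f_obs) - 1L) + extra_classes
    grid <- make_mismatch_grid(0:jmax, tau_max, theta0_max, theta1_max)
  }
  classes <- grid$classes
  jmax <- max(classes)
  fo <- spectrum_on_classes(f_obs, jmax)
  ssd_all <- colSums((t(grid$spectra) - fo)^2)
  ibest <- which.min(ssd_all)
  best <- grid$par[ibest, ]
  best_ssd <- ssd_all[ibest]
  if (refine) {
    ## box-constrained refinement on (tau, theta0, theta1-fraction), the
    ## fraction mapping [0, 1] onto [theta0, theta1_max] so the ordering
    ## constraint is built into the parameterization
    to_par <- function(x) {
      th0 <- x[2L]
      c(x[1L], th0, th0 + max(x[3L], 1e-8) * (theta1_max - th0))
    }
    obj <- function(x) {
      p <- to_par(x)
      fe <- expected_mismatch(p[1L], p[2L], p[3L], classes)
      sum((fo - fe)^2)
    }
    x0 <- c(best[1L], best[2L],
            min(1, max(1e-6, (best[3L] - best[2L]) /
                         max(theta1_max - best[2L], 1e-9))))
    lower <- c(0, 0, 0)
    upper <- c(tau_max, theta0_max, 1)
    opt <- tryCatch(
      stats::optim(x0, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e4)),
      error = function(e) NULL)
    x1 <- if (!is.null(opt) && is.finite(opt$value) &&
              opt$value < obj(x0)) opt$par else x0
    ## derivative-free polish; coordinates are clamped into the box
    clamp <- function(x) pmin(pmax(x, lower), upper)
    nm <- stats::optim(x1, function(x) obj(clamp(x)),
                       method = "Nelder-Mead",
                       control = list(maxit = 500L, reltol = 1e-12))
    cand <- rbind(if (!is.null(opt)) c(opt$value, opt$par),
                  c(nm$value, clamp(nm$par)))
    cbest <- cand[which.min(cand[, 1L]), ]
    if (is.finite(cbest[1L]) && cbest[1L] <= best_ssd) {
      best <- to_par(cbest[-1L])
      best_ssd <- cbest[1L]
    }
  }
  if (!is.finite(best_ssd))
    stop("fit error: SSD not finite over the search grid")
  best <- unname(best)
  structure(list(tau = best[1L], theta0 = best[2L], theta1 = best[3L],
                 ssd = best_ssd, classes = classes, f_obs = fo,
                 f_exp = expected_mismatch(best[1L], best[2L], best[3L],
                                           classes)),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("Sudden-expansion fit: tau = %.3f, theta0 = %.3f, theta1 = %.3g, SSD = %.4g\n",
              x$tau, x$theta0, x$theta1, x$ssd))
  invisible(x)
}

#' Parametric bootstrap goodness-of-fit for the sudden-expansion model
#'
#' Simulates `B` coalescent samples of size `n` under the fitted (tau,
#' theta0, theta1), refits the model to each simulated spectrum with the
#' same estimator configuration, and reports P_SSD = fraction of simulated
#' SSD >= observed SSD and P_rag = fraction of simulated raggedness >=
#' observed raggedness. So that observed and simulated statistics are
#' exchangeable under the null, the observed SSD is recomputed with the
#' identical configuration (grid fit by default) before the comparison.
#' Large p-values mean the observed spectrum is compatible with a sudden
#' expansion.
#'
#' @param fit A `mismatch_fit`.
#' @param n Sample size of the observed data.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param refine Nelder-Mead refinement when refitting (default FALSE:
#'   grid only, applied identically to the observed and every simulated
#'   spectrum).
#' @return List: `p_ssd`, `p_rag`, `ssd_obs`, `rag_obs`, `B`, and the
#'   simulated statistics `ssd_sim`, `rag_sim`.
#' @export
parametric_bootstrap <- function(fit, n, B = 1000L, seed = NULL,
                                 refine = FALSE) {
  if (B < 1L) stop("input error: B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rag_obs <- raggedness(fit$f_obs)
  grid <- make_mismatch_grid(fit$classes)
  ssd_obs <- fit_sudden_expansion(fit$f_obs, refine = refine,
                                  grid = grid)$ssd
  ssd_sim <- numeric(B)
  rag_sim <- numeric(B)
  for (b in seq_len(B)) {
    D <- sim_sudden_expansion(n, fit$tau, fit$theta0, fit$theta1)
    fs <- diff_matrix_spectrum(D)
    fb <- fit_sudden_expansion(fs, refine = refine, grid = grid)
    ssd_sim[b] <- fb$ssd
    rag_sim[b] <- raggedness(fs)
  }
  list(p_ssd = mean(ssd_sim >= ssd_obs),
       p_rag = mean(rag_sim >= rag_obs),
       ssd_obs = ssd_obs, rag_obs = rag_obs,
       B = B, ssd_sim = ssd_sim, rag_sim = rag_sim)
}

#' Convert the expansion parameter tau to time since expansion
#'
#' T = tau / (2u) generations with u = mu * k * g: mu the substitution
#' rate per site per year, k the sequence length in bp (indels counting as
#' one mutation each), g the generation time in years.
#'
#' @param tau Expansion parameter (>= 0).
#' @param mu Substitution rate (s/s/y, > 0).
#' @param k Sequence length (bp, > 0).
#' @param g Generation time (years, > 0).
#' @return List: `u`, `generations`, `years`, `myr`.
#' @export
expansion_time <- function(tau, mu = 1.52e-9, k = 2106, g = 1) {
  if (tau < 0) stop("input error: tau must be >= 0")
  if (mu <= 0 || k <= 0 || g <= 0)
    stop("input error: mu, k, g must be positive")
  u <- mu * k * g
  gen <- tau / (2 * u)
  list(u = u, generations = gen, years = gen * g, myr = gen * g / 1e6)
}
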