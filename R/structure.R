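#' Parse degree-minute coordinate strings
#'
#' Accepts a single coordinate (`"91°06′"`) or a longitude/latitude pair
#' separated by `/` (`"91°06′/29°46′"`). Decimal value = degrees +
#' minutes/60; east/north hemispheres are assumed.
#'
#' @param x Coordinate string.
#' @return A numeric scalar, or named vector `c(lon, lat)` for a pair.
#' @export
parse_dms <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("/", x, fixed = TRUE)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("parse error: expected lon/lat pair")
    return(c(lon = parse_dms(parts[1L]), lat = parse_dms(parts[2L])))
  }
  m <- regmatches(x, regexec("^\\s*([0-9]+)°\\s*([0-9]+(?:\\.[0-9]+)?)?[′']?\\s*$",
                             x))[[1L]]
  if (length(m) == 0L || m[2L] == "")
    stop("parse error: cannot parse coordinate '", x, "'")
  deg <- as.numeric(m[2L])
  minute <- if (is.na(m[3L]) || m[3L] == "") 0 else as.numeric(m[3L])
  deg + minute / 60
}

#' Great-circle (haversine) distance
#'
#' @param a,b Numeric vectors `c(lon, lat)` in decimal degrees.
#' @param radius_km Earth radius (default 6371 km).
#' @return Distance in km.
#' @export
great_circle <- function(a, b, radius_km = 6371) {
  if (abs(a[2L]) > 90 || abs(b[2L]) > 90)
    stop("input error: latitude outside [-90, 90]")
  rad <- pi / 180
  dlat <- (b[2L] - a[2L]) * rad
  dlon <- (b[1L] - a[1L]) * rad
  h <- sin(dlat / 2)^2 +
    cos(a[2L] * rad) * cos(b[2L] * rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(h)))
}

#' Great-circle distance matrix over populations
#'
#' @param coords Data frame with columns `lon`, `lat` (decimal degrees) and
#'   optionally `code` for dimnames.
#' @return Symmetric matrix of distances in km.
#' @export
geo_matrix <- function(coords) {
  n <- nrow(coords)
  labs <- if (!is.null(coords$code)) coords$code else rownames(coords)
  g <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        g[i, j] <- great_circle(c(coords$lon[i], coords$lat[i]),
                                c(coords$lon[j], coords$lat[j]))
        g[j, i] <- g[i, j]
      }
    }
  }
  g
}

## AMOVA sums of squares from a population x haplotype count matrix and a
## squared-distance matrix between haplotypes (for step data the number of
## steps plays the role of the squared inter-individual distance).
## SSD of a pooled set with haplotype count vector c:
##   SSD = (1 / (2 * sum(c))) * c' d c
pooled_ssd <- function(cvec, d) {
  n <- sum(cvec)
  if (n == 0) return(0)
  as.numeric(t(cvec) %*% d %*% cvec) / (2 * n)
}

amova_components <- function(counts, d, grouping) {
  counts <- as.matrix(counts)
  nk <- rowSums(counts)
  N <- sum(nk)
  P <- nrow(counts)
  g <- as.factor(grouping)
  G <- nlevels(g)
  ss_wp <- sum(vapply(seq_len(P), function(k) pooled_ssd(counts[k, ], d),
                      numeric(1L)))
  group_counts <- rowsum(counts, g)
  Ng <- rowSums(group_counts)
  ss_wg <- sum(vapply(seq_len(G), function(a)
    pooled_ssd(group_counts[a, ], d), numeric(1L)))
  ss_total <- pooled_ssd(colSums(counts), d)
  ss_ap <- ss_wg - ss_wp        # among populations within groups
  ss_ag <- ss_total - ss_wg     # among groups

  df_wp <- N - P
  df_ap <- P - G
  df_ag <- G - 1L

  sigma_c <- if (df_wp > 0) ss_wp / df_wp else NA_real_
  ## expected-mean-square coefficients (Excoffier, Smouse & Quattro)
  sum_n2_by_group <- vapply(seq_len(G), function(a)
    sum(nk[g == levels(g)[a]]^2) / Ng[a], numeric(1L))
  if (G < P) {
    n_prime <- (N - sum(sum_n2_by_group)) / df_ap
    sigma_b <- (ss_ap / df_ap - sigma_c) / n_prime
  } else {
    n_prime <- NA_real_
    sigma_b <- 0
  }
  if (G > 1L) {
    n_dprime <- (sum(sum_n2_by_group) - sum(nk^2) / N) / df_ag
    n_tprime <- (N - sum(Ng^2) / N) / df_ag
    sigma_a <- (ss_ag / df_ag - sigma_c - n_dprime * sigma_b) / n_tprime
  } else {
    sigma_a <- 0
  }
  total <- sigma_a + sigma_b + sigma_c
  list(ss = c(among_groups = ss_ag, among_pops = ss_ap, within_pops = ss_wp),
       df = c(among_groups = df_ag, among_pops = df_ap, within_pops = df_wp),
       sigma = c(among_groups = sigma_a, among_pops = sigma_b,
                 within_pops = sigma_c),
       FCT = if (G > 1L && total > 0) sigma_a / total else NA_real_,
       FSC = if (G < P && (sigma_b + sigma_c) > 0)
               sigma_b / (sigma_b + sigma_c) else NA_real_,
       FST = if (total > 0) (sigma_a + sigma_b) / total else NA_real_)
}

#' Analysis of molecular variance (AMOVA) on haplotype step distances
#'
#' Excoffier-Smouse-Quattro sums of squares computed from a population x
#' haplotype count matrix and the haplotype step-distance matrix (each step
#' counting as one squared unit of inter-individual distance). With a
#' grouping the three-level hierarchy (among groups / among populations
#' within groups / within populations) is returned with Phi-statistics
#' F_CT, F_SC and F_ST; without one, the two-level analysis returns F_ST
#' only. Negative variance components are reported as computed and flagged.
#'
#' @param counts Population x haplotype count matrix.
#' @param d Haplotype step-distance matrix.
#' @param grouping Factor/vector assigning each population to a group, or
#'   `NULL` for the two-level analysis.
#' @param n_perm Permutations for significance (default 10000); the null
#'   for F_ST permutes individuals among populations, for F_CT whole
#'   populations among groups, for F_SC individuals among populations
#'   within groups.
#' @param seed Optional integer seed.
#' @return Object of class `amova`: variance components, Phi-statistics,
#'   permutation p-values.
#' @export
amova <- function(counts, d, grouping = NULL, n_perm = 10000L, seed = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) && ncol(counts) == nrow(d))
    colnames(counts) <- rownames(d)
  d <- d[colnames(counts), colnames(counts), drop = FALSE]
  storage.mode(d) <- "double"
  if (is.null(grouping)) grouping <- rep(1L, nrow(counts))
  if (length(grouping) != nrow(counts))
    stop("input error: grouping must cover all populations")
  g <- as.factor(grouping)
  obs <- amova_components(counts, d, g)
  if (!is.finite(obs$FST))
    stop("degenerate total variance: no molecular variation")
  if (!is.null(seed)) set.seed(seed)

  p <- c(FCT = NA_real_, FSC = NA_real_, FST = NA_real_)
  if (n_perm >= 1L) {
    ## F_ST: permute individuals among populations
    ind_hap <- rep(colnames(counts), colSums(counts))
    nk <- rowSums(counts)
    pop_of <- rep(seq_len(nrow(counts)), nk)
    fst_perm <- vapply(seq_len(n_perm), function(b) {
      hap <- sample(ind_hap)
      cm <- table(factor(pop_of, levels = seq_len(nrow(counts))),
                  factor(hap, levels = colnames(counts)))
      cm <- matrix(as.integer(cm), nrow(counts),
                   dimnames = dimnames(counts))
      amova_components(cm, d, g)$FST
    }, numeric(1L))
    p["FST"] <- (sum(fst_perm >= obs$FST) + 1) / (n_perm + 1)

    if (nlevels(g) > 1L) {
      ## F_CT: permute populations among groups
      fct_perm <- vapply(seq_len(n_perm), function(b) {
        amova_components(counts, d, sample(as.integer(g)))$FCT
      }, numeric(1L))
      p["FCT"] <- (sum(fct_perm >= obs$FCT) + 1) / (n_perm + 1)

      if (nlevels(g) < nrow(counts)) {
        ## F_SC: permute individuals among populations within groups
        fsc_perm <- vapply(seq_len(n_perm), function(b) {
          hap <- ind_hap
          for (a in levels(g)) {
            sel <- g[pop_of] == a
            hap[sel] <- sample(hap[sel])
          }
          cm <- table(factor(pop_of, levels = seq_len(nrow(counts))),
                      factor(hap, levels = colnames(counts)))
          cm <- matrix(as.integer(cm), nrow(counts),
                       dimnames = dimnames(counts))
          amova_components(cm, d, g)$FSC
        }, numeric(1L))
        p["FSC"] <- (sum(fsc_perm >= obs$FSC) + 1) / (n_perm + 1)
      }
    }
  }
  res <- c(obs, list(p = p, n_perm = n_perm,
                     negative_components = any(obs$sigma < 0, na.rm = TRUE),
                     grouping = g))
  class(res) <- "amova"
  res
}

#' @export
print.amova <- function(x, ...) {
  cat("AMOVA (", nlevels(x$grouping), "group(s),",
      length(x$grouping), "populations )\n")
  tab <- data.frame(df = x$df, SS = x$ss, sigma2 = x$sigma)
  print(tab)
  cat(sprintf("  F_ST = %.4f (p = %.4g)", x$FST, x$p["FST"]))
  if (!is.na(x$FCT)) cat(sprintf("  F_CT = %.4f (p = %.4g)", x$FCT, x$p["FCT"]))
  if (!is.na(x$FSC)) cat(sprintf("  F_SC = %.4f (p = %.4g)", x$FSC, x$p["FSC"]))
  cat("\n")
  if (x$negative_components)
    cat("  note: negative variance component(s) reported as computed\n")
  invisible(x)
}

#' Pairwise Phi_ST between populations
#'
#' Two-population AMOVA for every pair, with permutation of individuals
#' among the two populations for significance.
#'
#' @param counts Population x haplotype count matrix.
#' @param d Haplotype step-distance matrix.
#' @param n_perm Permutations per pair (default 1000); 0 skips testing.
#' @param seed Optional integer seed.
#' @return List with matrices `phist` and `p`.
#' @export
pairwise_phist <- function(counts, d, n_perm = 1000L, seed = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(seed)) set.seed(seed)
  P <- nrow(counts)
  phist <- matrix(0, P, P, dimnames = list(rownames(counts),
                                           rownames(counts)))
  pmat <- matrix(NA_real_, P, P, dimnames = dimnames(phist))
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      sub <- counts[c(i, j), , drop = FALSE]
      keep <- colSums(sub) > 0L
      sub <- sub[, keep, drop = FALSE]
      cmp <- amova_components(sub, d[keep, keep, drop = FALSE],
                              rep(1L, 2L))
      fst <- cmp$FST
      if (!is.finite(fst)) fst <- 0   # no variation in the pair
      phist[i, j] <- phist[j, i] <- fst
      if (n_perm >= 1L && is.finite(cmp$FST)) {
        ind_hap <- rep(colnames(sub), colSums(sub))
        nk <- rowSums(sub)
        pop_of <- rep(1:2, nk)
        perm <- vapply(seq_len(n_perm), function(b) {
          hap <- sample(ind_hap)
          cm <- rbind(table(factor(hap[pop_of == 1L],
                                   levels = colnames(sub))),
                      table(factor(hap[pop_of == 2L],
                                   levels = colnames(sub))))
          f <- amova_components(cm, d[keep, keep, drop = FALSE],
                                rep(1L, 2L))$FST
          if (is.finite(f)) f else 0
        }, numeric(1L))
        pmat[i, j] <- pmat[j, i] <- (sum(perm >= fst) + 1) / (n_perm + 1)
      }
    }
  }
  list(phist = phist, p = pmat)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation over the lower triangles; significance by
#' simultaneous row/column permutation of the second matrix.
#'
#' @param m1,m2 Symmetric matrices of equal dimension.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 1000L, seed = NULL,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!all(dim(m1) == dim(m2)))
    stop("input error: matrices must have the same dimensions")
  lt <- lower.tri(m1)
  if (stats::sd(m1[lt]) == 0 || stats::sd(m2[lt]) == 0)
    stop("correlation-undefined error: constant matrix")
  r_obs <- stats::cor(m1[lt], m2[lt])
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(m1)
  r_perm <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n)
    stats::cor(m1[lt], m2[idx, idx][lt])
  }, numeric(1L))
  count <- switch(alternative,
                  two.sided = sum(abs(r_perm) >= abs(r_obs)),
                  greater = sum(r_perm >= r_obs),
                  less = sum(r_perm <= r_obs))
  list(r = r_obs, p = (count + 1) / (n_perm + 1), n_perm = n_perm,
       alternative = alternative)
}
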