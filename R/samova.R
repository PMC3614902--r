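## Azimuthal equidistant projection centred on the sample centroid: each
## point is mapped to (distance from centre) x (sin, cos of the initial
## bearing). Adequate over the ~25 degrees of longitude the packaged
## sampling spans, and deterministic.
project_azimuthal <- function(coords, radius_km = 6371) {
  rad <- pi / 180
  lon0 <- mean(coords$lon) * rad
  lat0 <- mean(coords$lat) * rad
  lon <- coords$lon * rad
  lat <- coords$lat * rad
  dist <- vapply(seq_len(nrow(coords)), function(i)
    great_circle(c(mean(coords$lon), mean(coords$lat)),
                 c(coords$lon[i], coords$lat[i]), radius_km), numeric(1L))
  az <- atan2(sin(lon - lon0) * cos(lat),
              cos(lat0) * sin(lat) - sin(lat0) * cos(lat) * cos(lon - lon0))
  cbind(x = dist * sin(az), y = dist * cos(az))
}

## Gabriel neighbourhood graph: i~j iff no third point falls inside the
## circle with diameter ij. A connected, deterministic planar neighbour
## graph (a subgraph of the Delaunay triangulation).
gabriel_graph <- function(xy) {
  n <- nrow(xy)
  adj <- matrix(FALSE, n, n)
  d2 <- as.matrix(stats::dist(xy))^2
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- TRUE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if (d2[i, k] + d2[j, k] < d2[i, j] - 1e-9) { ok <- FALSE; break }
      }
      if (ok) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  adj
}

random_contiguous_partition <- function(adj, K) {
  n <- nrow(adj)
  grp <- rep(NA_integer_, n)
  seeds <- sample.int(n, K)
  grp[seeds] <- seq_len(K)
  repeat {
    frontier <- which(is.na(grp))
    if (!length(frontier)) break
    ## grow: pick an unassigned node adjacent to an assigned one
    cand <- frontier[vapply(frontier, function(v)
      any(!is.na(grp[adj[v, ]])), logical(1L))]
    if (!length(cand)) {           # disconnected graph: attach arbitrarily
      v <- frontier[1L]
      grp[v] <- sample.int(K, 1L)
      next
    }
    v <- if (length(cand) == 1L) cand else sample(cand, 1L)
    nb <- grp[adj[v, ]]
    nb <- nb[!is.na(nb)]
    grp[v] <- if (length(nb) == 1L) nb else sample(nb, 1L)
  }
  grp
}

#' Spatial analysis of molecular variance (SAMOVA-style search)
#'
#' Searches for the partition of populations into `K` geographically
#' cohesive groups that maximizes the among-group fixation index F_CT, by
#' simulated annealing over a neighbourhood graph (Gabriel graph on
#' azimuthal-equidistant projected coordinates). Proposals move one
#' population that borders another group into that group; each repetition
#' starts from a random contiguous partition, anneals, then hill-climbs to
#' a local optimum. The best partition over all repetitions is returned.
#'
#' @param counts Population x haplotype count matrix.
#' @param d Haplotype step-distance matrix.
#' @param coords Data frame with `lon`, `lat` per population.
#' @param K Number of groups (2..number of populations).
#' @param n_rep Independent repetitions (default 100).
#' @param n_steps Annealing proposal steps per repetition (default 10000).
#' @param seed Optional integer seed.
#' @return Object of class `samova_result`: `K`, `grouping` (integer vector),
#'   `FCT`, `FCT_per_rep`, `n_rep`.
#' @export
samova <- function(counts, d, coords, K, n_rep = 100L, n_steps = 10000L,
                   seed = NULL) {
  counts <- as.matrix(counts)
  P <- nrow(counts)
  if (K < 2L || K > P) stop("input error: K out of range")
  if (is.null(colnames(counts)) && ncol(counts) == nrow(d))
    colnames(counts) <- rownames(d)
  d <- d[colnames(counts), colnames(counts), drop = FALSE]
  storage.mode(d) <- "double"
  if (!is.null(seed)) set.seed(seed)
  xy <- project_azimuthal(coords)
  adj <- gabriel_graph(xy)

  ## incremental F_CT evaluation: everything that does not depend on the
  ## grouping is precomputed; each proposal touches only the two groups
  ## involved, at O(haplotypes) cost
  nk <- rowSums(counts)
  N <- sum(nk)
  ss_wp <- sum(vapply(seq_len(P), function(k) pooled_ssd(counts[k, ], d),
                      numeric(1L)))
  ss_total <- pooled_ssd(colSums(counts), d)
  sum_nk2_N <- sum(nk^2) / N
  Dx <- counts %*% d                  # row v: d %*% counts[v, ]
  xDx <- rowSums(Dx * counts)         # counts[v, ]' d counts[v, ]
  df_wp <- N - P
  sigma_c <- ss_wp / df_wp

  group_stats <- function(grp) {
    cg <- rowsum(counts, grp)[paste0(seq_len(K)), , drop = FALSE]
    list(cg = cg,
         Ng = as.numeric(rowsum(nk, grp)[paste0(seq_len(K)), ]),
         s2g = as.numeric(rowsum(nk^2, grp)[paste0(seq_len(K)), ]),
         valg = rowSums((cg %*% d) * cg))
  }
  fct_from <- function(st) {
    ss_wg <- sum(st$valg / (2 * st$Ng))
    ss_ap <- ss_wg - ss_wp
    ss_ag <- ss_total - ss_wg
    df_ap <- P - K
    df_ag <- K - 1L
    sum_ratio <- sum(st$s2g / st$Ng)
    sigma_b <- if (df_ap > 0) {
      n_prime <- (N - sum_ratio) / df_ap
      (ss_ap / df_ap - sigma_c) / n_prime
    } else 0
    n_dprime <- (sum_ratio - sum_nk2_N) / df_ag
    n_tprime <- (N - sum(st$Ng^2) / N) / df_ag
    sigma_a <- (ss_ag / df_ag - sigma_c - n_dprime * sigma_b) / n_tprime
    total <- sigma_a + sigma_b + sigma_c
    if (total > 0) sigma_a / total else -Inf
  }
  apply_move <- function(st, v, from, to) {
    x <- counts[v, ]
    st$valg[from] <- st$valg[from] - 2 * sum(Dx[v, ] * st$cg[from, ]) +
      xDx[v]
    st$valg[to] <- st$valg[to] + 2 * sum(Dx[v, ] * st$cg[to, ]) + xDx[v]
    st$cg[from, ] <- st$cg[from, ] - x
    st$cg[to, ] <- st$cg[to, ] + x
    st$Ng[from] <- st$Ng[from] - nk[v]
    st$Ng[to] <- st$Ng[to] + nk[v]
    st$s2g[from] <- st$s2g[from] - nk[v]^2
    st$s2g[to] <- st$s2g[to] + nk[v]^2
    st
  }
  fct_of <- function(grp) fct_from(group_stats(grp))
  propose <- function(grp) {
    sizes <- tabulate(grp, K)
    movable <- which(vapply(seq_len(P), function(v) {
      sizes[grp[v]] > 1L && any(grp[adj[v, ]] != grp[v])
    }, logical(1L)))
    if (!length(movable)) return(NULL)
    v <- if (length(movable) == 1L) movable else sample(movable, 1L)
    targets <- unique(grp[adj[v, ]])
    targets <- targets[targets != grp[v]]
    to <- if (length(targets) == 1L) targets else sample(targets, 1L)
    c(v = v, to = to)
  }

  best_grp <- NULL
  best_f <- -Inf
  per_rep <- numeric(n_rep)
  for (rep_i in seq_len(n_rep)) {
    grp <- random_contiguous_partition(adj, K)
    st <- group_stats(grp)
    f <- fct_from(st)
    ## calibrate T0 so roughly 80% of downhill moves accept initially
    deltas <- numeric(0L)
    for (b in seq_len(min(50L, n_steps))) {
      mv <- propose(grp)
      if (is.null(mv)) break
      f2 <- fct_from(apply_move(st, mv["v"], grp[mv["v"]], mv["to"]))
      deltas <- c(deltas, f2 - f)
    }
    neg <- -deltas[deltas < 0 & is.finite(deltas)]
    T0 <- if (length(neg)) stats::median(neg) / -log(0.8) else 1e-3
    temp <- max(T0, 1e-8)
    cool_every <- max(1L, n_steps %/% 50L)
    rep_best <- grp
    rep_best_f <- f
    for (step in seq_len(n_steps)) {
      mv <- propose(grp)
      if (is.null(mv)) break
      st2 <- apply_move(st, mv["v"], grp[mv["v"]], mv["to"])
      f2 <- fct_from(st2)
      if (f2 >= f || stats::runif(1L) < exp((f2 - f) / temp)) {
        grp[mv["v"]] <- mv["to"]
        st <- st2
        f <- f2
        if (f > rep_best_f) { rep_best <- grp; rep_best_f <- f }
      }
      if (step %% cool_every == 0L) temp <- temp * 0.9
    }
    ## greedy polish from the repetition's best state
    grp <- rep_best
    st <- group_stats(grp)
    f <- rep_best_f
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      sizes <- tabulate(grp, K)
      for (v in seq_len(P)) {
        if (sizes[grp[v]] <= 1L) next
        for (tg in setdiff(unique(grp[adj[v, ]]), grp[v])) {
          st2 <- apply_move(st, v, grp[v], tg)
          f2 <- fct_from(st2)
          if (f2 > f + 1e-12) {
            grp[v] <- tg
            st <- st2
            f <- f2
            sizes <- tabulate(grp, K)
            improved <- TRUE
          }
        }
      }
    }
    per_rep[rep_i] <- f
    if (f > best_f) { best_f <- f; best_grp <- grp }
  }
  structure(list(K = K, grouping = stats::setNames(best_grp,
                                                   rownames(counts)),
                 FCT = best_f, FCT_per_rep = per_rep, n_rep = n_rep),
            class = "samova_result")
}

#' @export
print.samova_result <- function(x, ...) {
  cat(sprintf("SAMOVA: K = %d, best F_CT = %.4f over %d repetition(s)\n",
              x$K, x$FCT, x$n_rep))
  for (k in seq_len(x$K))
    cat(sprintf("  group %d: %s\n", k,
                paste(names(x$grouping)[x$grouping == k], collapse = " ")))
  invisible(x)
}
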