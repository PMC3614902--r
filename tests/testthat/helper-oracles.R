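# Shared fixtures and independent oracle implementations used across tests.
# Oracles are deliberately written as plain transcriptions of the published
# formulas (explicit loops, no reuse of package internals).

# random haplotype matrix with a mix of substitution and indel characters,
# carrying a site table compatible with synth_alignment()
random_haplo_matrix <- function(n_hap = 5L, n_sub = 3L, n_indel = 2L) {
  repeat {
    sub_states <- replicate(n_sub, sample(c("A", "C", "G", "T"), n_hap,
                                          replace = TRUE))
    indel_states <- replicate(n_indel, {
      ins <- paste(sample(c("A", "C", "G", "T"), sample(3:6, 1L),
                          replace = TRUE), collapse = "")
      sample(c("-", ins), n_hap, replace = TRUE)
    })
    m <- cbind(sub_states, indel_states)
    if (!anyDuplicated(apply(m, 1L, paste, collapse = "\r")) &&
        all(apply(m, 2L, function(s) length(unique(s)) >= 2L)))
      break
  }
  n_sites <- n_sub + n_indel
  kind <- c(rep("substitution", n_sub), rep("indel", n_indel))
  span <- c(rep(1L, n_sub),
            vapply(seq_len(n_indel), function(j)
              nchar(setdiff(unique(indel_states[, j]), "-")[1L]),
              integer(1L)))
  # generous spacing inside one 400-bp locus
  pos <- cumsum(span + 15L)
  sites <- data.frame(locus = "locusA", position = pos, kind = kind,
                      span = span, start = pos, end = pos + span - 1L,
                      states = "", stringsAsFactors = FALSE)
  colnames(m) <- paste0("s", seq_len(n_sites))
  rownames(m) <- paste0("hap", seq_len(n_hap))
  haplo_matrix(m, sites = sites)
}

# brute-force pairwise step count, column by column
oracle_steps <- function(m) {
  k <- nrow(m)
  d <- matrix(0L, k, k, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    s <- 0L
    for (c in seq_len(ncol(m))) if (m[i, c] != m[j, c]) s <- s + 1L
    d[i, j] <- s
  }
  d
}

# direct transcription of the Pons & Petit estimators with an arbitrary
# dissimilarity matrix delta (delta = 1 - I gives HS/HT)
oracle_pons_petit <- function(counts, delta) {
  s <- nrow(counts)
  nk <- rowSums(counts)
  ntilde <- s / sum(1 / nk)
  vks <- numeric(s)
  for (k in seq_len(s)) {
    p <- unname(counts[k, ] / nk[k])
    acc <- 0
    for (i in seq_len(ncol(counts))) for (j in seq_len(ncol(counts)))
      acc <- acc + delta[i, j] * p[i] * p[j]
    vks[k] <- acc
  }
  VS <- ntilde / (ntilde - 1) * mean(vks)
  pbar <- unname(colSums(sweep(counts, 1L, nk, "/")) / s)
  tot <- 0
  for (i in seq_len(ncol(counts))) for (j in seq_len(ncol(counts)))
    tot <- tot + delta[i, j] * pbar[i] * pbar[j]
  VT <- tot + VS / (ntilde * s)
  c(within = unname(VS), total = unname(VT), coef = unname((VT - VS) / VT))
}

# spherical-law-of-cosines great-circle distance (independent of the
# haversine implementation under test)
oracle_great_circle <- function(a, b, R = 6371) {
  rad <- pi / 180
  cosang <- sin(a[2] * rad) * sin(b[2] * rad) +
    cos(a[2] * rad) * cos(b[2] * rad) * cos((b[1] - a[1]) * rad)
  R * acos(pmin(1, pmax(-1, cosang)))
}

# AMOVA sums of squares from the full individual-by-individual squared
# distance matrix, the textbook way; `grouping` is a named vector
# (population -> group label)
oracle_amova_ss <- function(ind_d2, pop, grouping) {
  N <- length(pop)
  ss_of <- function(idx) {
    if (length(idx) == 0L) return(0)
    sum(ind_d2[idx, idx, drop = FALSE]) / (2 * length(idx))
  }
  pops <- names(grouping)
  ss_total <- ss_of(seq_len(N))
  ss_wp <- sum(vapply(pops, function(pp) ss_of(which(pop == pp)),
                      numeric(1L)))
  ss_wg <- sum(vapply(unique(grouping), function(g) {
    ss_of(which(pop %in% pops[grouping == g]))
  }, numeric(1L)))
  c(among_groups = ss_total - ss_wg, among_pops = ss_wg - ss_wp,
    within_pops = ss_wp)
}

# expand a count matrix into per-individual haplotype / population vectors
expand_counts <- function(counts) {
  pop <- rep(rownames(counts), rowSums(counts))
  hap <- unlist(lapply(seq_len(nrow(counts)), function(i)
    rep(colnames(counts), counts[i, ])))
  list(pop = pop, hap = hap)
}

# shortest-path step distances over a haplotype network (BFS, unit edges)
network_path_lengths <- function(net) {
  labs <- net$nodes$label
  n <- length(labs)
  adj <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  for (e in seq_len(nrow(net$edges))) {
    adj[net$edges$from[e], net$edges$to[e]] <- TRUE
    adj[net$edges$to[e], net$edges$from[e]] <- TRUE
  }
  d <- matrix(Inf, n, n, dimnames = list(labs, labs))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & dist > dist[v] + 1)
      dist[nb] <- dist[v] + 1
      queue <- c(queue, nb)
    }
    d[s, ] <- dist
  }
  d
}
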