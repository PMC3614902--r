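#' Packaged haplotype character matrix (eight cpDNA haplotypes A-H)
#'
#' Transcription of the published polymorphism table for *Hippuris
#' vulgaris*: eight variable characters (four substitutions, four indels)
#' across four chloroplast non-coding regions, defining haplotypes A-H.
#' Within-locus positions are nominal (the printed table does not give them
#' unambiguously); analyses use only the character states.
#'
#' @return A [haplo_matrix()] with 8 rows and 8 columns; attribute `sites`
#'   holds locus, position, kind and indel span of every character.
#' @export
load_table2 <- function() {
  f <- system.file("extdata", "table2_haplotypes.tsv", package = "haplogeo",
                   mustWork = TRUE)
  x <- utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
  states <- t(as.matrix(x[, LETTERS[1:8]]))
  colnames(states) <- x$char_id
  span <- ifelse(x$kind == "indel",
                 nchar(apply(x[, LETTERS[1:8]], 1L,
                             function(s) s[s != "-"][1L])),
                 1L)
  lens <- locus_lengths_hv()
  start_locus <- cumsum(c(0L, lens[-length(lens)]))[match(x$locus, names(lens))]
  sites <- data.frame(locus = x$locus, position = x$position,
                      kind = x$kind, span = as.integer(span),
                      start = as.integer(start_locus + x$position),
                      end = as.integer(start_locus + x$position + span - 1L),
                      states = vapply(seq_len(nrow(x)), function(j)
                        paste(sort(unique(unlist(x[j, LETTERS[1:8]]))),
                              collapse = ","), character(1L)),
                      stringsAsFactors = FALSE)
  class(sites) <- c("variable_sites", "data.frame")
  haplo_matrix(states, sites = sites)
}

#' Packaged population table (47 populations, 385 individuals)
#'
#' Transcription of the published sampling table: population code, locality,
#' degree-minute coordinates, altitude, sample size, the (alphabetical) list
#' of haplotypes observed, and haplotype diversity h printed to 3 decimals.
#'
#' @return Data frame with one row per population; `haplotypes` is a
#'   comma-separated string, `lon`/`lat` are decimal degrees.
#' @export
load_table1 <- function() {
  f <- system.file("extdata", "table1_populations.tsv", package = "haplogeo",
                   mustWork = TRUE)
  x <- utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
  x$lon <- vapply(x$lon_dms, parse_dms, numeric(1L))
  x$lat <- vapply(x$lat_dms, parse_dms, numeric(1L))
  x
}

#' Constants used by the packaged analyses
#'
#' Substitution rate mu (substitutions/site/year), total alignment length k
#' (bp), generation time g (years) and the two haplogroup definitions.
#'
#' @return Named list.
#' @export
hv_constants <- function() {
  list(mu = 1.52e-9, k = 2106L, g = 1,
       hpg1 = c("A", "B", "C", "F", "G"),
       hpg2 = c("D", "E", "H"))
}

locus_lengths_hv <- function() {
  c("ycf6-psbM" = 515L, "trnT-trnL" = 427L,
    "rps16" = 513L, "atpI-atpH" = 651L)
}

round_half_up <- function(x, digits = 3L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Back-solve haplotype counts from a printed diversity value
#'
#' Enumerates all multisets of `m` positive integers summing to `n` and
#' keeps those whose unbiased gene diversity, rounded half-up to `digits`
#' decimals, equals the printed `h`.
#'
#' @param n Sample size (>= 2).
#' @param m Number of haplotypes in the population (1..n).
#' @param h Printed gene diversity (3 decimals).
#' @param digits Decimals used for the comparison (default 3).
#' @return List of integer count multisets (each sorted decreasing), with
#'   attribute `unique` saying whether exactly one matched.
#' @export
back_solve_counts <- function(n, m, h, digits = 3L) {
  stopifnot(n >= 1L, m >= 1L, m <= n, h >= 0, h < 1)
  parts <- integer_partitions(n, m)
  if (m == 1L) {
    keep <- list(n)
  } else {
    keep <- Filter(function(p) {
      round_half_up(gene_diversity(p), digits) == round_half_up(h, digits)
    }, parts)
  }
  if (length(keep) == 0L)
    stop("inconsistency error: no count multiset of ", n, " into ", m,
         " parts gives h = ", h)
  structure(keep, unique = length(keep) == 1L)
}

## all partitions of n into exactly m positive parts, decreasing order
integer_partitions <- function(n, m) {
  if (m == 1L) return(list(n))
  out <- list()
  for (first in ceiling(n / m):(n - m + 1L)) {
    for (rest in integer_partitions(n - first, m - 1L)) {
      if (rest[1L] <= first) out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

#' Rebuild the full population-by-haplotype count matrix
#'
#' Monomorphic populations get their single haplotype at count n. For
#' polymorphic populations the count multiset is back-solved from the
#' printed h (unique for every row of the packaged table) and assigned to
#' the listed haplotypes according to a count policy: the published table
#' lists haplotypes alphabetically and carries no frequency information, so
#' any assignment consistent with n and h is admissible.
#'
#' @param policy `"widespread-major"` (default): larger counts go to the
#'   globally more widespread haplotype (by number of populations carrying
#'   it, A > D > E > C > B > F,G,H); or `"alphabetical-major"`: larger
#'   counts in alphabetical order.
#' @return List of class `pop_data`: `counts` (47 x 8 integer matrix),
#'   `coords` (data frame code/lon/lat/altitude), `table` (the fixture
#'   table), `policy`.
#' @export
rebuild_published_dataset <- function(policy = c("widespread-major",
                                             "alphabetical-major")) {
  policy <- match.arg(policy)
  t1 <- load_table1()
  haps <- LETTERS[1:8]
  hap_lists <- strsplit(t1$haplotypes, ",", fixed = TRUE)
  n_pops_with <- vapply(haps, function(a)
    sum(vapply(hap_lists, function(l) a %in% l, logical(1L))), integer(1L))
  global_order <- haps[order(-n_pops_with, haps)]

  counts <- matrix(0L, nrow(t1), length(haps),
                   dimnames = list(t1$code, haps))
  for (i in seq_len(nrow(t1))) {
    hl <- hap_lists[[i]]
    if (length(hl) == 1L) {
      counts[i, hl] <- t1$n[i]
      next
    }
    cm <- back_solve_counts(t1$n[i], length(hl), t1$h[i])
    if (!attr(cm, "unique"))
      stop("ambiguity flag: row ", t1$code[i], " has ", length(cm),
           " admissible count multisets")
    parts <- sort(cm[[1L]], decreasing = TRUE)
    ord <- switch(policy,
                  "widespread-major" = hl[order(match(hl, global_order))],
                  "alphabetical-major" = sort(hl))
    counts[i, ord] <- parts
  }
  ## every rebuilt row must reproduce the printed h at 3 decimals
  for (i in seq_len(nrow(t1))) {
    ci <- counts[i, counts[i, ] > 0L]
    if (round_half_up(gene_diversity(ci)) != t1$h[i])
      stop("inconsistency error: rebuilt counts for ", t1$code[i],
           " do not reproduce printed h")
  }
  structure(list(counts = counts,
                 coords = data.frame(code = t1$code, lon = t1$lon,
                                     lat = t1$lat,
                                     altitude = t1$altitude_m,
                                     stringsAsFactors = FALSE),
                 table = t1, policy = policy),
            class = "pop_data")
}

#' @export
print.pop_data <- function(x, ...) {
  cat("Population data:", nrow(x$counts), "populations,",
      sum(x$counts), "individuals,", sum(colSums(x$counts) > 0L),
      "haplotypes (count policy:", x$policy, ")\n")
  invisible(x)
}

#' Per-individual haplotype assignments from a count matrix
#'
#' @param pd A `pop_data` object (or a bare count matrix).
#' @return Data frame with `individual_id`, `population_code`, `haplotype`.
#' @export
expand_individuals <- function(pd) {
  counts <- if (inherits(pd, "pop_data")) pd$counts else pd
  rows <- rep(seq_len(nrow(counts)), rowSums(counts))
  haps <- unlist(lapply(seq_len(nrow(counts)), function(i)
    rep(colnames(counts), counts[i, ])))
  data.frame(individual_id = paste0(rownames(counts)[rows], "_",
                                    unlist(lapply(rowSums(counts), seq_len))),
             population_code = rownames(counts)[rows],
             haplotype = haps, stringsAsFactors = FALSE)
}

#' Synthesize an alignment that carries a given haplotype matrix
#'
#' Embeds the variable characters of `hm` (substitutions as single columns,
#' indels as gap spans) into an invariant random background split into loci,
#' so that scanning and calling the synthetic alignment recovers `hm`
#' exactly. The packaged haplotype matrix yields the published layout: four
#' loci of 515, 427, 513 and 651 bp, 2,106 bp in total.
#'
#' @param hm A [haplo_matrix()] whose `sites` attribute gives locus,
#'   position and span of every character.
#' @param assignments Optional named vector (individual -> haplotype label);
#'   default one individual per haplotype.
#' @param locus_lengths Named vector of locus alignment lengths; default the
#'   packaged four-locus layout when all of `hm`'s loci belong to it.
#' @param seed Optional integer seed for the random background.
#' @return An [aligned_sequences()] object.
#' @export
synth_alignment <- function(hm, assignments = NULL, locus_lengths = NULL,
                            seed = NULL) {
  sites <- attr(hm, "sites")
  if (is.null(sites))
    stop("input error: 'hm' carries no site table")
  if (is.null(locus_lengths)) {
    if (all(sites$locus %in% names(locus_lengths_hv())))
      locus_lengths <- locus_lengths_hv()
    else
      stop("input error: 'locus_lengths' required for non-packaged loci")
  }
  if (!all(sites$locus %in% names(locus_lengths)))
    stop("input error: sites reference unknown loci")
  ends_ok <- sites$position + sites$span - 1L <=
    locus_lengths[sites$locus]
  if (!all(ends_ok))
    stop("input error: locus too small for a variable site")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  L <- sum(locus_lengths)
  background <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  starts <- cumsum(c(0L, locus_lengths[-length(locus_lengths)]))
  names(starts) <- names(locus_lengths)

  if (is.null(assignments)) {
    assignments <- rownames(hm)
    names(assignments) <- rownames(hm)
  }
  if (!all(assignments %in% rownames(hm)))
    stop("input error: assignments name unknown haplotypes")

  ## per-haplotype sequence, then replicated per individual
  hap_seqs <- matrix(rep(background, each = nrow(hm)), nrow = nrow(hm),
                     dimnames = list(rownames(hm), NULL))
  occupied <- rep(FALSE, L)
  for (j in seq_len(nrow(sites))) {
    s <- sites[j, ]
    cols <- (starts[s$locus] + s$position):(starts[s$locus] + s$position +
                                              s$span - 1L)
    if (any(occupied[cols]))
      stop("input error: overlapping variable sites")
    occupied[cols] <- TRUE
    st <- hm[, j]
    if (s$kind == "substitution") {
      hap_seqs[, cols] <- st
    } else {
      for (h in seq_len(nrow(hm))) {
        hap_seqs[h, cols] <-
          if (st[h] == "-") "-" else strsplit(st[h], "")[[1L]]
      }
    }
  }
  seqs <- hap_seqs[assignments, , drop = FALSE]
  rownames(seqs) <- names(assignments)
  aligned_sequences(seqs, locus_lengths)
}
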