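#' Scan an alignment for variable sites, coding indels as single events
#'
#' Substitution sites are alignment columns carrying at least two distinct
#' bases among the non-gap sequences. Indels use simple indel coding: every
#' maximal contiguous gap run with identical start and end across sequences
#' is one character (a single mutational event, whatever its length); gap
#' runs with different or partially overlapping spans are distinct
#' characters.
#'
#' @param aln An [aligned_sequences()] object (>= 2 sequences).
#' @return A data frame of class `variable_sites` with columns `locus`,
#'   `position` (1-based within locus), `kind` (`"substitution"` or
#'   `"indel"`), `span` (indel length in columns, 1 for substitutions),
#'   `start`, `end` (concatenated coordinates) and `states`
#'   (comma-separated observed states).
#' @export
scan_variable_sites <- function(aln) {
  stopifnot(inherits(aln, "aligned_sequences"))
  m <- aln$seqs
  if (nrow(m) < 2L)
    stop("input error: need at least two sequences")

  ## --- indel characters: distinct maximal gap runs ---
  runs <- list()
  for (i in seq_len(nrow(m))) {
    g <- m[i, ] == "-"
    if (!any(g)) next
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      key <- paste0(starts[k], ":", ends[k])
      runs[[key]] <- c(starts[k], ends[k])
    }
  }
  indels <- NULL
  if (length(runs)) {
    spans <- do.call(rbind, runs)
    spans <- spans[order(spans[, 1L], spans[, 2L]), , drop = FALSE]
    indels <- data.frame(start = spans[, 1L], end = spans[, 2L],
                         kind = "indel", stringsAsFactors = FALSE)
  }

  ## --- substitution columns (>= 2 distinct bases among non-gap, non-N) ---
  sub_cols <- which(apply(m, 2L, function(col) {
    b <- col[!(col %in% c("-", "N"))]
    length(unique(b)) >= 2L
  }))
  subs <- NULL
  if (length(sub_cols))
    subs <- data.frame(start = sub_cols, end = sub_cols,
                       kind = "substitution", stringsAsFactors = FALSE)

  sites <- rbind(subs, indels)
  if (is.null(sites))
    sites <- data.frame(start = integer(), end = integer(),
                        kind = character(), stringsAsFactors = FALSE)

  ## map to locus coordinates; order by locus then position
  loci <- aln$loci
  idx <- findInterval(sites$start, loci$start)
  if (nrow(sites) && any(sites$end > loci$end[idx]))
    stop("alignment error: a gap run crosses a locus boundary")
  sites$locus <- loci$locus[idx]
  sites$position <- sites$start - loci$start[idx] + 1L
  sites$span <- sites$end - sites$start + 1L
  sites <- sites[order(idx, sites$position, sites$kind), , drop = FALSE]
  sites$states <- vapply(seq_len(nrow(sites)), function(j) {
    st <- site_states(m, sites[j, ])
    paste(sort(unique(st)), collapse = ",")
  }, character(1L))
  rownames(sites) <- NULL
  out <- sites[, c("locus", "position", "kind", "span", "start", "end",
                   "states")]
  class(out) <- c("variable_sites", "data.frame")
  out
}

## character state of every sequence at one variable site:
##  - substitution: the base (or "-"/"N") in that column
##  - indel: "-" if the sequence's maximal gap run equals the span exactly,
##    otherwise the literal characters spanning it
site_states <- function(m, site) {
  if (site$kind == "substitution") return(m[, site$start])
  cols <- site$start:site$end
  block <- m[, cols, drop = FALSE]
  all_gap <- rowSums(block == "-") == length(cols)
  exact <- all_gap
  if (site$start > 1L) exact <- exact & m[, site$start - 1L] != "-"
  if (site$end < ncol(m)) exact <- exact & m[, site$end + 1L] != "-"
  st <- apply(block, 1L, paste, collapse = "")
  st[exact] <- "-"
  st
}

#' Call haplotypes from variable sites
#'
#' Each individual is assigned the combination of its states at the variable
#' sites. With `mode = "substitutions_only"` the indel characters are
#' dropped before calling, which can merge (but never split) haplotypes.
#'
#' @param aln An [aligned_sequences()] object.
#' @param sites Variable sites from [scan_variable_sites()] on the same
#'   alignment.
#' @param mode `"with_indels"` (default) or `"substitutions_only"`.
#' @param on_ambiguous What to do with an `N` at a variable substitution
#'   site: `"error"` (default) or `"drop"` the individual.
#' @param reference Optional `haplo_matrix` whose rows define canonical
#'   labels; called haplotypes matching a reference row inherit its label,
#'   novel ones get numbered labels.
#' @return A `haplo_matrix`: character matrix (haplotypes x sites) with
#'   attributes `sites` (the site table) and `assignments` (named vector
#'   mapping individuals to haplotype labels).
#' @export
call_haplotypes <- function(aln, sites,
                            mode = c("with_indels", "substitutions_only"),
                            on_ambiguous = c("error", "drop"),
                            reference = NULL) {
  mode <- match.arg(mode)
  on_ambiguous <- match.arg(on_ambiguous)
  stopifnot(inherits(aln, "aligned_sequences"))
  m <- aln$seqs
  if (mode == "substitutions_only")
    sites <- sites[sites$kind == "substitution", , drop = FALSE]

  if (nrow(sites) == 0L) {
    states <- matrix(character(), nrow(m), 0L,
                     dimnames = list(rownames(m), NULL))
  } else {
    states <- vapply(seq_len(nrow(sites)),
                     function(j) site_states(m, sites[j, ]),
                     character(nrow(m)))
    states <- matrix(states, nrow = nrow(m),
                     dimnames = list(rownames(m), site_labels(sites)))
  }

  amb <- sites$kind == "substitution"
  has_n <- if (any(amb)) rowSums(states[, amb, drop = FALSE] == "N") > 0L
           else rep(FALSE, nrow(m))
  if (any(has_n)) {
    if (on_ambiguous == "error")
      stop("ambiguous base (N) at a variable site in: ",
           paste(rownames(m)[has_n], collapse = ", "))
    states <- states[!has_n, , drop = FALSE]
  }

  key <- apply(states, 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  hm <- states[first, , drop = FALSE]
  labels <- default_haplotype_labels(nrow(hm))
  if (!is.null(reference)) {
    ref_key <- apply(unclass_hm(reference), 1L, paste, collapse = "\r")
    hit <- match(apply(hm, 1L, paste, collapse = "\r"), ref_key)
    labels <- ifelse(is.na(hit),
                     paste0("N", cumsum(is.na(hit))),
                     rownames(reference)[hit])
  }
  rownames(hm) <- labels
  assignments <- labels[match(key, key[first])]
  names(assignments) <- rownames(states)
  haplo_matrix(hm, sites = sites, assignments = assignments)
}

default_haplotype_labels <- function(k) {
  if (k <= 26L) LETTERS[seq_len(k)] else paste0("H", seq_len(k))
}

site_labels <- function(sites) {
  paste0(sites$locus, ":", sites$position,
         ifelse(sites$kind == "indel", "i", ""))
}

#' Construct a haplotype character matrix
#'
#' @param states Character matrix, rows = haplotypes (rownames = labels),
#'   columns = variable sites.
#' @param sites Optional site table (see [scan_variable_sites()]).
#' @param assignments Optional named vector mapping individuals to labels.
#' @return Object of class `haplo_matrix`.
#' @export
haplo_matrix <- function(states, sites = NULL, assignments = NULL) {
  stopifnot(is.matrix(states), is.character(states))
  if (is.null(rownames(states)))
    rownames(states) <- default_haplotype_labels(nrow(states))
  if (anyDuplicated(apply(states, 1L, paste, collapse = "\r")))
    stop("input error: haplotype rows are not distinct")
  structure(states, sites = sites, assignments = assignments,
            class = c("haplo_matrix", "matrix"))
}

unclass_hm <- function(hm) {
  m <- hm
  attributes(m) <- list(dim = dim(hm), dimnames = dimnames(hm))
  m
}

#' @export
print.haplo_matrix <- function(x, ...) {
  cat("Haplotype matrix:", nrow(x), "haplotypes x", ncol(x), "characters\n")
  print(unclass_hm(x), quote = FALSE)
  invisible(x)
}

#' Mutational-step distances between haplotypes
#'
#' Counts the characters at which two haplotypes differ; every substitution
#' and every indel (whatever its length) is one step.
#'
#' @param hm A `haplo_matrix`.
#' @return Symmetric integer matrix of pairwise steps with zero diagonal.
#' @export
pairwise_steps <- function(hm) {
  m <- unclass_hm(hm)
  k <- nrow(m)
  d <- matrix(0L, k, k, dimnames = list(rownames(m), rownames(m)))
  if (k < 2L) return(d)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}
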