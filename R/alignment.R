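#' Multi-locus aligned sequences
#'
#' Container for a set of pre-aligned sequences spanning one or more loci
#' that are analysed as a single concatenated alignment (the usual situation
#' for chloroplast non-coding regions sequenced in the same individuals).
#' Alignment characters are `A/C/G/T/-/N`; all sequences have equal length.
#'
#' @param seqs Character matrix (individuals x alignment columns) or a list of
#'   equal-length character vectors. Values are upper-cased on input.
#' @param locus_lengths Named integer vector of per-locus alignment lengths,
#'   in concatenation order. Defaults to a single locus spanning the whole
#'   alignment.
#' @return An object of class `aligned_sequences`: a list with `seqs` (the
#'   character matrix) and `loci` (data frame with `locus`, `length`, `start`,
#'   `end` in concatenated coordinates).
#' @export
aligned_sequences <- function(seqs, locus_lengths = NULL) {
  if (is.list(seqs)) {
    len <- unique(lengths(seqs))
    if (length(len) != 1L)
      stop("alignment error: sequences have unequal lengths")
    seqs <- do.call(rbind, seqs)
  }
  if (!is.matrix(seqs) || !is.character(seqs))
    stop("input error: 'seqs' must be a character matrix or list of vectors")
  if (nrow(seqs) < 1L || ncol(seqs) < 1L)
    stop("input error: empty alignment")
  seqs[] <- toupper(seqs)
  bad <- !(seqs %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad))
    stop("alignment error: invalid characters: ",
         paste(unique(seqs[bad]), collapse = ", "))
  if (is.null(locus_lengths))
    locus_lengths <- c(locus1 = ncol(seqs))
  if (is.null(names(locus_lengths)))
    names(locus_lengths) <- paste0("locus", seq_along(locus_lengths))
  if (sum(locus_lengths) != ncol(seqs))
    stop("alignment error: locus lengths sum to ", sum(locus_lengths),
         " but alignment has ", ncol(seqs), " columns")
  ends <- cumsum(locus_lengths)
  loci <- data.frame(locus = names(locus_lengths),
                     length = as.integer(locus_lengths),
                     start = as.integer(ends - locus_lengths + 1L),
                     end = as.integer(ends),
                     stringsAsFactors = FALSE)
  if (is.null(rownames(seqs)))
    rownames(seqs) <- paste0("ind", seq_len(nrow(seqs)))
  structure(list(seqs = seqs, loci = loci), class = "aligned_sequences")
}

#' @export
print.aligned_sequences <- function(x, ...) {
  cat("Aligned sequences:", nrow(x$seqs), "individuals x",
      ncol(x$seqs), "columns\n")
  cat("Loci:", paste0(x$loci$locus, " (", x$loci$length, " bp)",
                      collapse = ", "), "\n")
  invisible(x)
}

#' Read a concatenated FASTA alignment
#'
#' @param file Path to an aligned FASTA file.
#' @param locus_lengths Optional named vector of locus lengths (see
#'   [aligned_sequences()]).
#' @return An `aligned_sequences` object.
#' @export
read_alignment <- function(file, locus_lengths = NULL) {
  dna <- ape::read.FASTA(file)
  m <- t(vapply(as.character(dna), function(s) s, character(length(dna[[1]]))))
  rownames(m) <- names(dna)
  aligned_sequences(m, locus_lengths)
}

#' Write an alignment to FASTA
#'
#' @param aln An `aligned_sequences` object.
#' @param file Output path.
#' @export
write_alignment <- function(aln, file) {
  stopifnot(inherits(aln, "aligned_sequences"))
  dna <- ape::as.DNAbin(tolower(aln$seqs))
  ape::write.FASTA(dna, file)
  invisible(file)
}

#' Read an individual-to-population table
#'
#' Expects a TSV with at least columns `individual_id` and `population_code`.
#'
#' @param file Path to the TSV.
#' @return Data frame.
#' @export
read_population_map <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("individual_id", "population_code")
  if (!all(need %in% names(x)))
    stop("input error: population map needs columns ",
         paste(need, collapse = ", "))
  x
}
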