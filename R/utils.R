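#' Phred quality to base-call accuracy
#'
#' Converts a Phred quality score Q to the implied base-call accuracy
#' `1 - 10^(-Q/10)`.  Q20 corresponds to 99% accuracy and Q30 to 99.9%.
#'
#' @param q numeric vector of Phred quality scores.
#' @return numeric vector of accuracies in \[0, 1\].
#' @examples
#' phred_accuracy(c(20, 30))
#' @export
phred_accuracy <- function(q) {
  stopifnot(is.numeric(q), all(q >= 0))
  1 - 10^(-q / 10)
}

#' Mean Phred-implied error probability of quality strings
#'
#' The per-read average base error rate implied by a Sanger (Phred+33)
#' quality string: the mean over bases of `10^(-Q/10)`.  Averaging is done
#' on the probability scale, not on the Q scale.
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return numeric vector of mean error probabilities.
#' @export
qual_mean_error <- function(qual) {
  qual_mean_error_cpp(as.character(qual))
}

#' Assembly and read-set length statistics
#'
#' Computes the count, total, extreme lengths and the N50..N90 statistics
#' of a sequence set.  Nxx is the largest length L such that sequences of
#' length >= L cover at least xx% of the total bases (largest-first
#' cumulative rule).
#'
#' @param lengths integer vector of sequence lengths (or a
#'   [Biostrings::DNAStringSet], whose widths are used).
#' @return named list: `n`, `total_bp`, `max_bp`, `min_bp`, `N50`..`N90`.
#' @examples
#' read_stats(c(2, 2, 2, 3, 3, 4))$N50
#' @export
read_stats <- function(lengths) {
  if (methods::is(lengths, "XStringSet")) lengths <- Biostrings::width(lengths)
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0 || any(is.na(lengths)))
    stop("read_stats() needs at least one sequence length")
  sl <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(sl)
  tot <- cs[length(cs)]
  nxx <- function(xx) sl[which(cs >= tot * xx / 100)[1]]
  list(n = length(sl), total_bp = tot, max_bp = sl[1], min_bp = sl[length(sl)],
       N50 = nxx(50), N60 = nxx(60), N70 = nxx(70), N80 = nxx(80),
       N90 = nxx(90))
}

## Reverse complement for plain character vectors (delegates to Biostrings).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Run code under a private RNG stream seeded with `seed`, restoring the
## caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive a bounded child seed from a parent seed and a stream label.
child_seed <- function(seed, label) {
  as.integer((fnv1a_cpp(paste0(seed, "/", label)) %% 2147483647))
}

## Random DNA of given length and GC fraction, using the current RNG.
random_dna <- function(n, gc = 0.5) {
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE, prob = p)])
}

gc_fraction <- function(seq) {
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seq),
                                   letters = c("GC"))
  as.numeric(f / nchar(seq))
}

## Minimal FASTQ writer/reader on plain character vectors.  Kept simple and
## fast; quality encoding is Sanger Phred+33 throughout.
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con,
             sep = "\n")
  invisible(path)
}

read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4 != 0)
    stop("malformed FASTQ: line count not a multiple of 4 in ", path)
  ids <- sub("^@", "", ln[seq(1, length(ln), by = 4)])
  ids <- sub("\\s.*$", "", ids)
  seqs <- ln[seq(2, length(ln), by = 4)]
  quals <- ln[seq(4, length(ln), by = 4)]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], ": sequence/quality length differ")
  list(id = ids, seq = seqs, qual = quals)
}

write_fasta <- function(seqs, path, width = 80) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
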