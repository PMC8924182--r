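# Shared low-level helpers: deterministic sub-seed derivation, random and
# mutated sequences, reverse complement on plain characters.

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' A stable polynomial hash of the label folded into the master seed,
#' reduced modulo 2^31 - 1. Used so that per-capsule (and per-stage)
#' random streams are reproducible independently of the order in which
#' capsules are simulated.
#'
#' @param master Integer master seed.
#' @param label Character scalar naming the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(master, label) {
  stopifnot(length(label) == 1L)
  m <- 2147483647
  h <- as.double(master %% m)
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% m
  as.integer(h)
}

#' Reverse complement of a plain character sequence
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate a random genome sequence
#'
#' I.i.d. bases at a given GC content. Skewed GC is what gives synthetic
#' genomes a usable tetranucleotide signature.
#'
#' @param length Sequence length in bp.
#' @param gc Target GC fraction in (0, 1).
#' @param seed Optional integer seed.
#' @return A single character string.
#' @export
randomGenome <- function(length, gc = 0.5, seed = NULL) {
  gen <- function() {
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p),
          collapse = "")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Mutate a sequence by i.i.d. substitutions
#'
#' Each site is substituted with probability `rate`; the replacement base is
#' drawn uniformly from the three alternatives, so no substitution is silent.
#'
#' @param seq Character scalar DNA sequence.
#' @param rate Per-site substitution probability.
#' @param seed Optional integer seed.
#' @return A list with `seq` (mutated sequence) and `sites` (0-based
#'   positions that were substituted), the substitution map used by
#'   divergence oracles.
#' @export
mutateSequence <- function(seq, rate, seed = NULL) {
  run <- function() {
    n <- nchar(seq)
    if (rate <= 0) return(list(seq = seq, sites = integer()))
    sites <- which(runif(n) < rate)
    if (!length(sites)) return(list(seq = seq, sites = integer()))
    raw <- charToRaw(seq)
    code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
    lut <- charToRaw("ACGT")
    old <- code[rawToChar(raw[sites], multiple = TRUE)]
    newb <- (old + sample.int(3L, length(sites), replace = TRUE)) %% 4L
    raw[sites] <- lut[newb + 1L]
    list(seq = rawToChar(raw), sites = sites - 1L)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Hamming mismatch fraction between equal-length sequences
#' @param a,b Character scalars of equal length.
#' @return Fraction of mismatching sites.
#' @export
mismatchFraction <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mean(charToRaw(a) != charToRaw(b))
}

# locale-independent sort
sortC <- function(x) sort(x, method = "radix")

# as.character() that keeps names (base as.character drops attributes)
asSeqChar <- function(x) {
  nm <- names(x)
  x <- as.character(x)
  names(x) <- nm
  x
}

# cut a set of contigs into non-overlapping fragments of fragmentLen,
# dropping trailing partials
cutFragments <- function(contigs, fragmentLen) {
  contigs <- as.character(contigs)
  out <- character()
  for (s in contigs) {
    n <- nchar(s) %/% fragmentLen
    if (n < 1) next
    starts <- (seq_len(n) - 1L) * fragmentLen + 1L
    out <- c(out, substring(s, starts, starts + fragmentLen - 1L))
  }
  out
}
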