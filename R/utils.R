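#' Random DNA sequence
#'
#' @param n length in bp.
#' @return A single uppercase ACGT string.
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of ACGTN sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Apply point substitutions to a sequence. pos is 0-based.
apply_subs <- function(seq, pos, base) {
  if (length(pos) == 0) return(seq)
  r <- charToRaw(seq)
  r[pos + 1L] <- charToRaw(paste(base, collapse = ""))
  rawToChar(r)
}

# Extract single bases at 0-based positions.
base_at <- function(seq, pos) {
  if (length(pos) == 0) return(character(0))
  strsplit(rawToChar(charToRaw(seq)[pos + 1L]), "", fixed = TRUE)[[1]]
}

# All start positions (0-based) of fixed pattern in subject.
find_all <- function(subject, pattern) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
}

# Exact central (1-alpha) interval of Binomial(n, p): [lo, hi] inclusive.
binom_central <- function(n, p = 0.5, alpha = 0.01) {
  c(qbinom(alpha / 2, n, p), qbinom(1 - alpha / 2, n, p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
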