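# Shared fixtures and independent mini-oracles for the test suite.

# A small, fast cross configuration.
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(
    chrom_lengths = c(chr01 = 2e5, chr02 = 2e5),
    w_locus = list(chrom = "chr02", pos = 1e5),
    w_insert_len = 5000, w_flank_len = 3e4,
    n_f1 = 60, bulk_size = 20, depth = 13, parent_depth = 40,
    lability = c(male = 0, monoecious = 0, nonflowering = 0))
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Build a one-row-per-site pileup from explicit base counts.
make_pileup <- function(chrom, pos, ref, A = 0, C = 0, G = 0, T = 0) {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, A = A, C = C,
                   G = G, T = T, stringsAsFactors = FALSE)
  df$depth <- df$A + df$C + df$G + df$T
  class(df) <- c("pileup", "data.frame")
  df
}

# Independent meiosis simulator for linkage tests: markers heterozygous in
# one parent; each F1 inherits that parent's haplotype 1 or 2 along a
# Poisson-crossover gamete. Positions are in cM along one chromosome.
# Returns 1 (het = inherited hap 1, carrying the marker allele) / 0 calls.
sim_bc_markers <- function(n_f1, pos_cM, xovers_per_morgan = 1) {
  n_m <- length(pos_cM)
  calls <- matrix(NA_real_, n_m, n_f1)
  L <- max(pos_cM)
  for (i in seq_len(n_f1)) {
    nx <- rpois(1, L / 100) # one crossover per Morgan on average
    brk <- sort(runif(nx, 0, L))
    src <- (findInterval(pos_cM, brk) + sample(0:1, 1)) %% 2
    calls[, i] <- src
  }
  rownames(calls) <- sprintf("m%02d", seq_len(n_m))
  calls
}

# Brute-force maximal-SSR oracle built on period maximality: for each
# period p, maximal stretches with s[i] == s[i+p] define a run; a run is
# reported if it holds >= min_repeats whole copies of a primitive (hence
# non-mononucleotide) motif. Start is the leftmost position of the run.
ssr_oracle <- function(s, min_motif = 2, max_motif = 10, min_repeats = 10) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  is_prim <- function(motif) {
    m <- nchar(motif)
    for (d in seq_len(m - 1))
      if (m %% d == 0 && strrep(substr(motif, 1, d), m / d) == motif)
        return(FALSE)
    TRUE
  }
  hits <- list()
  for (p in min_motif:max_motif) {
    if (n < 2 * p) next
    eq <- ch[seq_len(n - p)] == ch[seq_len(n - p) + p] &
      ch[seq_len(n - p)] %in% c("A", "C", "G", "T")
    r <- rle(eq)
    stop_at <- cumsum(r$lengths)
    start_at <- stop_at - r$lengths + 1
    for (j in which(r$values)) {
      a <- start_at[j]                 # 1-based run start
      run_len <- r$lengths[j] + p      # total bases with period p
      reps <- run_len %/% p
      if (reps < min_repeats) next
      motif <- substr(s, a, a + p - 1)
      if (!is_prim(motif)) next
      hits[[length(hits) + 1]] <- data.frame(
        start = a - 1L, end = a - 1L + reps * p, motif = motif,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(0), end = integer(0),
                                       motif = character(0)))
  unique(do.call(rbind, hits))
}

# Enumeration-based two-sided Fisher oracle (probability-mass criterion,
# same tie tolerance as the documented convention), via stats::dhyper.
fisher_oracle <- function(t) {
  r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); n <- sum(t)
  if (n == 0) return(1)
  x <- max(0, r1 + c1 - n):min(r1, c1)
  p <- dhyper(x, c1, n - c1, r1)
  pobs <- dhyper(t[1, 1], c1, n - c1, r1)
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}
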