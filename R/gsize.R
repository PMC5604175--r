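#' k-mer-based genome size estimation
#'
#' Either counts canonical k-mers from reads and takes the k-mer coverage Kc
#' as the histogram mode above the first local minimum (excluding the
#' error peak), or accepts the parameters directly. The estimate follows
#' read coverage Rc = (Kc * Rl) / (Rl - k + 1) and
#' genome size = total read length / Rc.
#'
#' @param reads character vector of reads (ignored if `params` given).
#' @param k k-mer size (default 25); must be below the read length.
#' @param params optional list with `Kc`, `Rl` (mean read length, bp) and
#'   `total_len` (total read bases, bp) to bypass counting.
#' @return list of class `kmer_gsize`: k, Kc, Rl, total_len, Rc, size (bp),
#'   and `histogram` when counted from reads.
#' @export
kmer_genome_size <- function(reads = NULL, k = 25, params = NULL) {
  hist <- NULL
  if (is.null(params)) {
    stopifnot(!is.null(reads))
    if (k >= min(nchar(reads))) stop("k must be below the read length")
    hist <- cpp_kmer_histogram(reads, k)
    Rl <- mean(nchar(reads))
    total_len <- sum(nchar(reads))
    # error peak sits at depth 1; Kc is the mode beyond the first local min
    first_min <- 1L
    while (first_min < length(hist) && hist[first_min + 1L] < hist[first_min])
      first_min <- first_min + 1L
    Kc <- first_min + which.max(hist[(first_min + 1L):length(hist)])
  } else {
    Kc <- params$Kc; Rl <- params$Rl; total_len <- params$total_len
  }
  if (k >= Rl) stop("k must be below the read length")
  Rc <- (Kc * Rl) / (Rl - k + 1)
  structure(list(k = k, Kc = Kc, Rl = Rl, total_len = total_len, Rc = Rc,
                 size = total_len / Rc, histogram = hist),
            class = "kmer_gsize")
}

#' @export
print.kmer_gsize <- function(x, ...) {
  cat(sprintf("k-mer genome size: %.1f Mb (k=%d, Kc=%.2f, Rl=%.1f, Rc=%.3f)\n",
              x$size / 1e6, x$k, x$Kc, x$Rl, x$Rc))
  invisible(x)
}

#' Flow-cytometry genome size estimation
#'
#' Genome size from the ratio of G1 fluorescence peak means of the sample
#' and an internal reference standard of known genome size. Returns the
#' size both at full precision and with the ratio rounded to one decimal
#' (the conventional reporting mode).
#'
#' @param peak_sample,peak_ref G1 peak means (arbitrary units, > 0).
#' @param ref_size reference genome size (bp or any unit; the result is in
#'   the same unit).
#' @return list: ratio (3 decimals), ratio_full, size (full precision),
#'   size_rounded_ratio (ref_size * ratio rounded to 1 decimal).
#' @export
fcm_genome_size <- function(peak_sample, peak_ref, ref_size) {
  if (peak_sample <= 0 || peak_ref <= 0) stop("peaks must be positive")
  ratio <- peak_sample / peak_ref
  list(ratio = round(ratio, 3), ratio_full = ratio,
       size = ref_size * ratio,
       size_rounded_ratio = ref_size * round(ratio, 1))
}

#' Assembly summary statistics
#'
#' @param seqs named character vector of scaffold sequences, or a FASTA
#'   path (read with Biostrings).
#' @return list of class `assembly_stats`: n_scaffolds, total_len, largest,
#'   N50, N75, gc_percent (of unambiguous bases), n_per_100kb.
#' @export
assembly_stats <- function(seqs) {
  if (length(seqs) == 1 && file.exists(seqs[1]) && is.null(names(seqs)))
    seqs <- read_fasta(seqs)
  if (!length(seqs)) stop("empty assembly")
  lens <- nchar(seqs)
  count_chars <- function(chars) {
    sum(vapply(seqs, function(s)
      sum(charToRaw(s) %in% charToRaw(chars)), numeric(1)))
  }
  gc <- count_chars("GCgc")
  acgt <- count_chars("ACGTacgt")
  nn <- count_chars("Nn")
  structure(list(n_scaffolds = length(seqs), total_len = sum(lens),
                 largest = max(lens),
                 N50 = n_statistic(lens, 0.5), N75 = n_statistic(lens, 0.75),
                 gc_percent = 100 * gc / acgt,
                 n_per_100kb = 1e5 * nn / sum(lens)),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(paste0("assembly: %d scaffolds, %.2f Mb, largest %.2f Mb, ",
                     "N50 %.0f, N75 %.0f, GC %.2f%%, %.1f Ns/100kb\n"),
              x$n_scaffolds, x$total_len / 1e6, x$largest / 1e6, x$N50,
              x$N75, x$gc_percent, x$n_per_100kb))
  invisible(x)
}

#' Percent excess of an assembly over a genome-size estimate
#'
#' @param assembly_len assembly total length.
#' @param estimate_len estimated genome size (same unit).
#' @param digits rounding (default 1, the conventional reporting precision).
#' @return percent excess.
#' @export
assembly_excess_percent <- function(assembly_len, estimate_len, digits = 1) {
  round((assembly_len / estimate_len - 1) * 100, digits)
}

#' Per-gene averages from annotation totals
#'
#' @param total total feature count or length.
#' @param n_genes number of genes.
#' @param digits rounding (default 2).
#' @return rounded per-gene average.
#' @export
per_gene_average <- function(total, n_genes, digits = 2) {
  round(total / n_genes, digits)
}

#' Gene-model annotation summary statistics
#'
#' Accepts a GFF3 path (parsed with rtracklayer when available) or a plain
#' data.frame with columns `type`, `start`, `end` (1-based inclusive) and
#' `parent`/`id`. Counts exons and introns (introns = exons - transcripts,
#' assuming contiguous single-exon chains per transcript) and their
#' per-gene averages and mean sizes.
#'
#' @param x GFF3 path or data.frame.
#' @return list of class `annotation_stats`: n_genes, n_transcripts,
#'   n_exons, n_introns, exons_per_gene, introns_per_gene, mean_exon_len,
#'   total_exon_len.
#' @export
annotation_stats <- function(x) {
  if (is.character(x)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires rtracklayer; pass a data.frame instead")
    g <- as.data.frame(rtracklayer::import(x))
    x <- data.frame(type = as.character(g$type), start = g$start,
                    end = g$end, stringsAsFactors = FALSE)
  }
  n_genes <- sum(x$type == "gene")
  n_tx <- sum(x$type %in% c("mRNA", "transcript"))
  ex <- x[x$type == "exon", , drop = FALSE]
  n_exons <- nrow(ex)
  n_introns <- n_exons - n_tx
  if (n_genes == 0) stop("no gene features")
  structure(list(n_genes = n_genes, n_transcripts = n_tx, n_exons = n_exons,
                 n_introns = n_introns,
                 exons_per_gene = per_gene_average(n_exons, n_genes),
                 introns_per_gene = per_gene_average(n_introns, n_genes),
                 mean_exon_len = mean(ex$end - ex$start + 1),
                 total_exon_len = sum(ex$end - ex$start + 1)),
            class = "annotation_stats")
}

# is motif primitive (not a whole-number repeat of a shorter motif)?
is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  for (d in seq_len(m - 1)) {
    if (m %% d == 0 &&
        strrep(substr(motif, 1, d), m / d) == motif) return(FALSE)
  }
  TRUE
}

#' Scan sequences for perfect SSRs (microsatellites)
#'
#' Maximal perfect tandem runs of primitive motifs of length
#' `min_motif`..`max_motif` with at least `min_repeats` whole copies.
#' Mononucleotide runs are excluded (motif length starts at 2 and
#' non-primitive motifs such as "AA" are skipped).
#'
#' @param seqs named character vector.
#' @param min_motif,max_motif motif length bounds (defaults 2 and 10).
#' @param min_repeats minimum whole-copy count (default 10).
#' @return data.frame: seqid, start, end (0-based half-open), motif,
#'   motif_len, repeats.
#' @export
find_ssrs <- function(seqs, min_motif = 2, max_motif = 10, min_repeats = 10) {
  stopifnot(min_motif >= 1, max_motif >= min_motif, min_repeats >= 1)
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    for (m in min_motif:max_motif) {
      pat <- paste0("([ACGT]{", m, "})\\1{", min_repeats - 1, ",}")
      hits <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (hits[1] == -1) next
      lens <- attr(hits, "match.length")
      for (h in seq_along(hits)) {
        start <- as.integer(hits[h]) - 1L
        motif <- substr(s, start + 1L, start + m)
        if (!is_primitive_motif(motif)) next
        reps <- lens[h] %/% m
        # homopolymer guard (min_motif = 1 case)
        if (m == 1) next
        out[[length(out) + 1L]] <- data.frame(
          seqid = id, start = start, end = start + reps * m, motif = motif,
          motif_len = m, repeats = reps, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      motif_len = integer(0), repeats = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$seqid, res$start, res$motif_len), , drop = FALSE]
  rownames(res) <- NULL
  res
}
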