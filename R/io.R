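#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = width)
  invisible(path)
}

#' Write reads to FASTQ (fixed Q40 qualities)
#'
#' @param reads data.frame from [sample_reads()] (id, seq) or character
#'   vector.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  if (!is.data.frame(reads))
    reads <- data.frame(id = sprintf("r%06d", seq_along(reads)), seq = reads)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n",
                    vapply(nchar(reads$seq), strrep, character(1), x = "I")),
             con)
  invisible(path)
}

#' Write a pileup table as TSV (1-based positions, stated in the header)
#'
#' @param pileup a pileup data.frame (0-based `pos` internally).
#' @param path output path.
#' @export
write_pileup <- function(pileup, path) {
  out <- pileup
  out$pos <- out$pos + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based", con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pileup TSV written by [write_pileup()]
#'
#' @param path input path.
#' @return a pileup data.frame (0-based positions).
#' @export
read_pileup <- function(path) {
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  x$pos <- x$pos - 1L
  class(x) <- c("pileup", "data.frame")
  x
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df data.frame with chrom/contig, start, end columns.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  chrom <- df$chrom %||% df$contig
  write.table(data.frame(chrom, df$start, df$end),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a JSON run manifest (seed and config echo)
#'
#' @param cfg a [sim_config()].
#' @param path output path.
#' @export
write_manifest <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Plot windowed SNP-index / delta tracks for one chromosome
#'
#' Three stacked panels (female index, male index, delta with confidence
#' band), in the conventional QTL-seq style.
#'
#' @param windows output of [sliding_window()].
#' @param records per-site records (dots).
#' @param chrom chromosome to plot.
#' @export
plot_qtlseq <- function(windows, records, chrom) {
  w <- windows[windows$chrom == chrom & !windows$empty, , drop = FALSE]
  r <- records[records$chrom == chrom, , drop = FALSE]
  mid <- (w$start + w$end) / 2
  op <- graphics::par(mfrow = c(3, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(r$pos, r$index_female, pch = ".", col = "grey50", ylim = c(0, 1),
       xlab = "", ylab = "index (female)")
  graphics::lines(mid, w$mean_index_female, col = "red", lwd = 2)
  plot(r$pos, r$index_male, pch = ".", col = "grey50", ylim = c(0, 1),
       xlab = "", ylab = "index (male)")
  graphics::lines(mid, w$mean_index_male, col = "red", lwd = 2)
  plot(r$pos, r$delta, pch = ".", col = "grey50", ylim = c(-1, 1),
       xlab = "position (bp)", ylab = "delta index")
  graphics::lines(mid, w$mean_delta, col = "red", lwd = 2)
  if (!is.null(w$mean_ci_hi)) {
    graphics::lines(mid, w$mean_ci_hi, col = "brown")
    graphics::lines(mid, w$mean_ci_lo, col = "brown")
  }
  invisible(NULL)
}
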