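#' Materialize the two haplotype sequences of an F1 individual
#'
#' Splices each recombinant gamete from the parental haplotype sequences at
#' its crossover breakpoints; the W insertion is inherited atomically with
#' the W haplotype at the sex locus.
#'
#' @param ind one individual of an `f1_population`.
#' @param parents the `parents` attribute of the population.
#' @param chroms chromosomes to materialize (default all).
#' @return named character vector, two sequences per chromosome
#'   (`<chrom>_f`, `<chrom>_m` for the female- and male-derived gametes).
#' @export
f1_haplotypes <- function(ind, parents, chroms = NULL) {
  cl <- parents$female$chrom_lengths
  chroms <- chroms %||% names(cl)
  out <- character(0)
  for (ch in chroms) {
    for (side in c("f", "m")) {
      par <- if (side == "f") parents$female else parents$male
      g <- ind$gametes[[ch]][[side]]
      bounds <- c(0, ceiling(g$breaks), cl[[ch]])
      segs <- character(length(bounds) - 1L)
      for (i in seq_along(segs)) {
        src <- if ((i - 1L) %% 2L == 0L) g$start else 3L - g$start
        segs[i] <- substr(par$haplotypes[[ch]][src], bounds[i] + 1L,
                          bounds[i + 1L])
      }
      s <- paste(segs, collapse = "")
      if (side == "f" && !is.null(par$w_chrom) && ch == par$w_chrom &&
          gamete_source(g, par$w_pos) == par$w_hap &&
          nchar(par$w_insert) > 0) {
        p <- par$w_pos
        s <- paste0(substr(s, 1, p), par$w_insert, substr(s, p + 1, nchar(s)))
      }
      out[paste0(ch, "_", side)] <- s
    }
  }
  out
}

#' Combine two parental assemblies into a dual reference
#'
#' @param asm_female,asm_male named character vectors of contig sequences.
#' @return list of class `combined_ref`: `seqs` (named character vector),
#'   `source` ("female-asm"/"male-asm" per contig).
#' @export
combine_references <- function(asm_female, asm_male) {
  if (!length(asm_female) || !length(asm_male)) stop("empty assembly")
  nf <- names(asm_female); nm <- names(asm_male)
  clash <- intersect(nf, nm)
  nf[nf %in% clash] <- paste0("F|", nf[nf %in% clash])
  nm[nm %in% clash] <- paste0("M|", nm[nm %in% clash])
  seqs <- c(setNames(asm_female, nf), setNames(asm_male, nm))
  structure(list(seqs = seqs,
                 source = setNames(rep(c("female-asm", "male-asm"),
                                       c(length(nf), length(nm))),
                                   names(seqs))),
            class = "combined_ref")
}

#' Map reads to a reference with a uniqueness-aware mini-mapper
#'
#' Exact-seed (both read ends and the middle), Hamming-extended, no indels.
#' All placements tied at the best mismatch count are counted; one is
#' reported (uniform-random tie-break using R's RNG). `unique` is the analog
#' of MAPQ 60: exactly one best placement.
#'
#' @param reads character vector of read sequences (or the data.frame from
#'   [sample_reads()]).
#' @param ref a `combined_ref` or named character vector of contigs.
#' @param seed_len exact seed length (default 31; must be <= read length).
#' @param max_mismatch maximum Hamming distance for a reported placement.
#' @return data.frame: read (index), contig, pos (0-based), strand,
#'   mismatches, n_best, unique, qwidth. Unmapped reads are omitted.
#' @export
map_reads <- function(reads, ref, seed_len = 31, max_mismatch = 3) {
  if (is.data.frame(reads)) reads <- reads$seq
  seqs <- if (inherits(ref, "combined_ref")) ref$seqs else ref
  res <- cpp_map_reads(reads, unname(seqs), seed_len, max_mismatch)
  res$contig <- names(seqs)[res$contig]
  res$strand <- ifelse(res$strand == 0, "+", "-")
  res$unique <- res$n_best == 1L
  res
}

# Per-base coverage vectors for one contig from an alignment table.
coverage_tracks <- function(aln, contig, len) {
  a <- aln[aln$contig == contig, , drop = FALSE]
  cov <- function(x) {
    v <- numeric(len + 1L)
    if (nrow(x)) {
      s <- x$pos + 1L                      # first covered base (1-based)
      e <- pmin(x$pos + x$qwidth, len) + 1L # first base past the read
      v <- tabulate(s, nbins = len + 1L) - tabulate(e, nbins = len + 1L)
    }
    cumsum(v)[seq_len(len)]
  }
  list(total = cov(a), unique = cov(a[a$unique, , drop = FALSE]))
}

#' Bulk-specific genomic regions from dual-bulk alignments
#'
#' For each contig and each bulk, reports maximal runs of bases where the
#' bulk's own unique-read depth is at least `min_self_depth`, the other
#' bulk's depth (all reported placements) is at most `max_other_depth`, and
#' at least `min_frac_unique` of the bulk's own reads overlapping the base
#' are unique (the per-position MAPQ-60 fraction track).
#'
#' @param aln_female,aln_male alignment tables from [map_reads()] against the
#'   same reference.
#' @param ref the `combined_ref` (or named character vector).
#' @param min_frac_unique minimum fraction of unique overlapping reads
#'   (default 0.9).
#' @param max_other_depth maximum tolerated other-bulk depth (default 0).
#' @param min_self_depth minimum own unique depth (default 1).
#' @return data.frame: contig, start, end, length, bulk, mean_depth_self,
#'   mean_depth_other, frac_unique.
#' @export
specific_regions <- function(aln_female, aln_male, ref,
                             min_frac_unique = 0.9, max_other_depth = 0,
                             min_self_depth = 1) {
  seqs <- if (inherits(ref, "combined_ref")) ref$seqs else ref
  out <- list()
  for (contig in names(seqs)) {
    len <- nchar(seqs[[contig]])
    trf <- coverage_tracks(aln_female, contig, len)
    trm <- coverage_tracks(aln_male, contig, len)
    for (bulk in c("female", "male")) {
      self <- if (bulk == "female") trf else trm
      other <- if (bulk == "female") trm else trf
      frac <- ifelse(self$total > 0, self$unique / self$total, 0)
      ok <- self$unique >= min_self_depth & other$total <= max_other_depth &
        frac >= min_frac_unique
      if (!any(ok)) next
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      sel <- which(r$values)
      for (j in sel) {
        i0 <- starts[j]; i1 <- ends[j]
        out[[length(out) + 1L]] <- data.frame(
          contig = contig, start = i0 - 1L, end = i1, length = i1 - i0 + 1L,
          bulk = bulk,
          mean_depth_self = mean(self$total[i0:i1]),
          mean_depth_other = mean(other$total[i0:i1]),
          frac_unique = mean(frac[i0:i1]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      bulk = character(0), mean_depth_self = numeric(0),
                      mean_depth_other = numeric(0), frac_unique = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' N-statistic of a length distribution
#'
#' Smallest length among the largest fragments whose cumulative sum first
#' reaches `fraction` of the total (N50 for `fraction = 0.5`, N20 for 0.2).
#'
#' @param lengths numeric vector of fragment lengths.
#' @param fraction fraction of the total length, in (0, 1).
#' @return the N-statistic (bp).
#' @export
n_statistic <- function(lengths, fraction) {
  if (!length(lengths)) stop("empty length list")
  stopifnot(fraction > 0, fraction < 1)
  s <- sort(lengths, decreasing = TRUE)
  unname(s[which(cumsum(s) >= fraction * sum(s))[1]])
}

#' Select contigs carrying large bulk-specific fragments
#'
#' Contigs having at least one specific region strictly longer than
#' `min_fragment_bp`; the default threshold is the N20 of the bulk's
#' specific-region lengths.
#'
#' @param regions output of [specific_regions()].
#' @param bulk which bulk's regions to use (default "female").
#' @param min_fragment_bp length threshold; regions must be strictly larger.
#' @return character vector of contig ids.
#' @export
select_specific_contigs <- function(regions, bulk = "female",
                                    min_fragment_bp = NULL) {
  r <- regions[regions$bulk == bulk, , drop = FALSE]
  if (!nrow(r)) return(character(0))
  thr <- min_fragment_bp %||% n_statistic(r$length, 0.2)
  unique(r$contig[r$length > thr])
}

#' Anchor contigs on a target sequence by chained exact matches
#'
#' Each contig is cut into non-overlapping chunks which are placed exactly
#' (zero mismatches) on the target with the mini-mapper; the best colinear
#' chain (same target, same strand, consistent diagonal) gives the anchor.
#' Matched length sums the chunk lengths only, so N-gaps and diverged
#' segments are excluded.
#'
#' @param contig_seqs named character vector of query contigs.
#' @param target_seqs named character vector of target sequences.
#' @param chunk chunk size (bp, default 100).
#' @param min_match_bp minimum total matched bases for a reported anchor.
#' @param band diagonal tolerance (bp) for chaining (default 5000, so that
#'   chains continue across reference N-gaps and small indels).
#' @return data.frame: contig, target, tstart, tend, qstart, qend, strand,
#'   matched_len, n_chunks. Unanchored contigs are omitted.
#' @export
anchor_contigs <- function(contig_seqs, target_seqs, chunk = 100,
                           min_match_bp = 200, band = 5000) {
  out <- list()
  for (ctg in names(contig_seqs)) {
    s <- contig_seqs[[ctg]]
    L <- nchar(s)
    starts <- seq(0L, max(0L, L - chunk), by = chunk)
    pieces <- substring(s, starts + 1L, pmin(starts + chunk, L))
    keep <- nchar(pieces) >= min(chunk, 31L)
    starts <- starts[keep]; pieces <- pieces[keep]
    if (!length(pieces)) next
    aln <- map_reads(pieces, target_seqs, seed_len = min(31L, chunk),
                     max_mismatch = 0)
    aln <- aln[aln$unique, , drop = FALSE]
    if (!nrow(aln)) next
    aln$qstart <- starts[aln$read]
    aln$diag <- ifelse(aln$strand == "+", aln$pos - aln$qstart,
                       aln$pos + aln$qstart)
    key <- paste(aln$contig, aln$strand)
    best <- NULL; best_len <- 0
    for (k in unique(key)) {
      a <- aln[key == k, , drop = FALSE]
      a <- a[order(a$diag), , drop = FALSE]
      grp <- cumsum(c(1L, diff(a$diag) > band))
      for (g in unique(grp)) {
        b <- a[grp == g, , drop = FALSE]
        ml <- sum(b$qwidth)
        if (ml > best_len) { best_len <- ml; best <- b }
      }
    }
    if (is.null(best) || best_len < min_match_bp) next
    strand <- best$strand[1]
    qs <- min(best$qstart); qe <- max(best$qstart + best$qwidth)
    out[[length(out) + 1L]] <- data.frame(
      contig = ctg, target = best$contig[1],
      tstart = min(best$pos), tend = max(best$pos + best$qwidth),
      qstart = qs, qend = qe, strand = strand, matched_len = best_len,
      n_chunks = nrow(best), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(contig = character(0), target = character(0),
                      tstart = integer(0), tend = integer(0),
                      qstart = integer(0), qend = integer(0),
                      strand = character(0), matched_len = integer(0),
                      n_chunks = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Delineate the W-linked interval from anchored female-specific regions
#'
#' Maps each female-specific region through its contig's anchor onto the
#' target coordinate system and takes the minimal covering interval. If
#' alignments of a ZZ-selected bulk are supplied, target bases covered by
#' that bulk are removed before taking the span (this can only narrow the
#' interval).
#'
#' @param anchors output of [anchor_contigs()] for the selected contigs.
#' @param regions output of [specific_regions()] (female rows are used).
#' @param zz_bulk_alignments optional [map_reads()] table of a ZZ-genotype
#'   bulk against the target.
#' @param target_lengths named lengths of the target sequences (required if
#'   `zz_bulk_alignments` is given).
#' @return list of class `w_region_call`: chrom, start, end, contigs,
#'   regions (mapped region table); or an empty call (`start` NA) if no
#'   female-specific region is anchored.
#' @export
delineate_w_interval <- function(anchors, regions, zz_bulk_alignments = NULL,
                                 target_lengths = NULL) {
  fr <- regions[regions$bulk == "female" &
                  regions$contig %in% anchors$contig, , drop = FALSE]
  empty <- list(chrom = NA_character_, start = NA_real_, end = NA_real_,
                contigs = character(0), regions = NULL)
  class(empty) <- "w_region_call"
  if (!nrow(fr)) return(empty)
  m <- match(fr$contig, anchors$contig)
  a <- anchors[m, , drop = FALSE]
  plus <- a$strand == "+"
  t1 <- ifelse(plus, a$tstart + (fr$start - a$qstart),
               a$tstart + (a$qend - fr$end))
  t2 <- t1 + (fr$end - fr$start)
  keep <- t2 > a$tstart & t1 < a$tend
  fr <- fr[keep, , drop = FALSE]; a <- a[keep, , drop = FALSE]
  t1 <- pmax(t1[keep], a$tstart); t2 <- pmin(t2[keep], a$tend)
  if (!nrow(fr)) return(empty)
  tgt <- a$target[1]
  sel <- a$target == tgt
  fr <- fr[sel, , drop = FALSE]; t1 <- t1[sel]; t2 <- t2[sel]
  mapped <- data.frame(contig = fr$contig, target = tgt, tstart = t1,
                       tend = t2, length = t2 - t1,
                       stringsAsFactors = FALSE)
  if (!is.null(zz_bulk_alignments)) {
    stopifnot(!is.null(target_lengths))
    len <- target_lengths[[tgt]]
    zz <- zz_bulk_alignments[zz_bulk_alignments$contig == tgt, , drop = FALSE]
    covered <- logical(len)
    if (nrow(zz)) {
      for (i in seq_len(nrow(zz))) {
        s <- zz$pos[i] + 1L
        e <- min(zz$pos[i] + zz$qwidth[i], len)
        covered[s:e] <- TRUE
      }
    }
    keep_base <- logical(len)
    for (i in seq_len(nrow(mapped)))
      keep_base[(mapped$tstart[i] + 1L):mapped$tend[i]] <- TRUE
    keep_base <- keep_base & !covered
    if (!any(keep_base)) return(empty)
    span <- range(which(keep_base))
    start <- span[1] - 1L; end <- span[2]
  } else {
    start <- min(mapped$tstart); end <- max(mapped$tend)
  }
  structure(list(chrom = tgt, start = start, end = end,
                 contigs = unique(mapped$contig), regions = mapped),
            class = "w_region_call")
}

#' @export
print.w_region_call <- function(x, ...) {
  if (is.na(x$start)) cat("w_region_call: empty (no anchored regions)\n")
  else cat(sprintf("w_region_call: %s:%d-%d (%d bp) from %d contig(s)\n",
                   x$chrom, x$start, x$end, x$end - x$start,
                   length(x$contigs)))
  invisible(x)
}
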