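#' Non-reference SNP-index of a pileup
#'
#' Fraction of reads at each site that differ from the reference base.
#' Sites with zero depth get index `NA`.
#'
#' @param pileup a pileup data.frame (chrom, pos, ref, A, C, G, T, depth).
#' @return numeric vector of indices.
#' @export
snp_index <- function(pileup) {
  cnt <- as.matrix(pileup[, BASES])
  refc <- cnt[cbind(seq_len(nrow(pileup)), match(pileup$ref, BASES))]
  d <- pileup$depth
  ifelse(d > 0, (d - refc) / d, NA_real_)
}

# Count of a designated base per site.
base_count <- function(pileup, base) {
  as.matrix(pileup[, BASES])[cbind(seq_len(nrow(pileup)),
                                   match(base, BASES))]
}

#' Build a parent-substituted reference
#'
#' At every site whose SNP-index is exactly 1 (all reads differ from the
#' reference base) with depth at least `min_depth`, the reference base is
#' replaced by the parent's consensus (most frequent) base; every other
#' position is left unchanged.
#'
#' @param ref_seqs named character vector of reference sequences.
#' @param parent_pileup pileup of the parent against `ref_seqs`.
#' @param min_depth minimum depth for a substitution (default 5).
#' @return list: `seqs` (substituted reference), `substitutions` (data.frame
#'   chrom, pos, ref, new).
#' @export
substitute_reference <- function(ref_seqs, parent_pileup, min_depth = 5) {
  if (!all(unique(parent_pileup$chrom) %in% names(ref_seqs)))
    stop("pileup/reference chromosome mismatch")
  idx <- snp_index(parent_pileup)
  sel <- !is.na(idx) & idx == 1 & parent_pileup$depth >= min_depth
  cnt <- as.matrix(parent_pileup[sel, BASES, drop = FALSE])
  newb <- BASES[max.col(cnt, ties.method = "first")]
  subs <- data.frame(chrom = parent_pileup$chrom[sel],
                     pos = parent_pileup$pos[sel],
                     ref = parent_pileup$ref[sel], new = newb,
                     stringsAsFactors = FALSE)
  seqs <- ref_seqs
  for (ch in unique(subs$chrom)) {
    s <- subs[subs$chrom == ch, ]
    seqs[[ch]] <- apply_subs(seqs[[ch]], s$pos, s$new)
  }
  list(seqs = seqs, substitutions = subs)
}

#' Classify parent-specific heterozygous sites
#'
#' A site is heterozygous in one parent and informative if its biallelic
#' SNP-index (alternate / (reference + alternate)) lies inside `band` in that
#' parent, the other parent has zero non-reference reads, and both parents
#' have depth at least `min_parent_depth`. The alternate allele is the most
#' frequent non-reference base of the heterozygous parent.
#'
#' @param pileup_p3,pileup_p4 parent pileups against the same (substituted)
#'   reference, at the same positions.
#' @param band inclusive heterozygous index band (default `c(0.4, 0.6)`).
#' @param min_parent_depth minimum depth in both parents (default 16,
#'   the literal reading of "more than 15").
#' @return data.frame of classified sites: chrom, pos, ref, alt, het_parent
#'   ("P3"/"P4"), index_het, depth_p3, depth_p4.
#' @export
classify_het_sites <- function(pileup_p3, pileup_p4, band = c(0.4, 0.6),
                               min_parent_depth = 16) {
  key3 <- paste(pileup_p3$chrom, pileup_p3$pos)
  key4 <- paste(pileup_p4$chrom, pileup_p4$pos)
  common <- intersect(key3, key4)
  p3 <- pileup_p3[match(common, key3), , drop = FALSE]
  p4 <- pileup_p4[match(common, key4), , drop = FALSE]
  n <- nrow(p3)
  cnt3 <- as.matrix(p3[, BASES]); cnt4 <- as.matrix(p4[, BASES])
  ref_i <- match(p3$ref, BASES)
  nonref3 <- cnt3; nonref3[cbind(seq_len(n), ref_i)] <- -1L
  nonref4 <- cnt4; nonref4[cbind(seq_len(n), ref_i)] <- -1L
  alt3 <- BASES[max.col(nonref3, ties.method = "first")]
  alt4 <- BASES[max.col(nonref4, ties.method = "first")]
  refc3 <- cnt3[cbind(seq_len(n), ref_i)]
  refc4 <- cnt4[cbind(seq_len(n), ref_i)]
  nr3 <- p3$depth - refc3
  nr4 <- p4$depth - refc4
  bi3 <- refc3 + base_count(p3, alt3)
  bi4 <- refc4 + base_count(p4, alt4)
  i3 <- ifelse(bi3 > 0, base_count(p3, alt3) / bi3, NA_real_)
  i4 <- ifelse(bi4 > 0, base_count(p4, alt4) / bi4, NA_real_)
  depth_ok <- p3$depth >= min_parent_depth & p4$depth >= min_parent_depth
  is_p3 <- depth_ok & !is.na(i3) & i3 >= band[1] & i3 <= band[2] & nr4 == 0
  is_p4 <- depth_ok & !is.na(i4) & i4 >= band[1] & i4 <= band[2] & nr3 == 0
  out <- rbind(
    data.frame(chrom = p3$chrom[is_p3], pos = p3$pos[is_p3],
               ref = p3$ref[is_p3], alt = alt3[is_p3],
               het_parent = rep("P3", sum(is_p3)),
               index_het = i3[is_p3], depth_p3 = p3$depth[is_p3],
               depth_p4 = p4$depth[is_p3], stringsAsFactors = FALSE),
    data.frame(chrom = p4$chrom[is_p4], pos = p4$pos[is_p4],
               ref = p4$ref[is_p4], alt = alt4[is_p4],
               het_parent = rep("P4", sum(is_p4)),
               index_het = i4[is_p4], depth_p3 = p3$depth[is_p4],
               depth_p4 = p4$depth[is_p4], stringsAsFactors = FALSE))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Bulk SNP-index and delta-SNP-index at classified heterozygous sites
#'
#' The index at a site is alternate count / (reference + alternate count);
#' reads carrying a third base are excluded from numerator and denominator.
#' Sites with biallelic depth below `min_bulk_depth` in either bulk (or
#' absent from a bulk pileup) are dropped. Delta is female minus male.
#'
#' @param pileup_female,pileup_male bulk pileups against the appropriate
#'   parent-substituted reference.
#' @param het_sites output of [classify_het_sites()], usually filtered to one
#'   `het_parent`.
#' @param min_bulk_depth minimum biallelic depth per bulk (default 6).
#' @return data.frame: chrom, pos, ref, alt, het_parent, index_female,
#'   index_male, delta, depth_female, depth_male.
#' @export
bulk_snp_index <- function(pileup_female, pileup_male, het_sites,
                           min_bulk_depth = 6) {
  keyh <- paste(het_sites$chrom, het_sites$pos)
  kf <- paste(pileup_female$chrom, pileup_female$pos)
  km <- paste(pileup_male$chrom, pileup_male$pos)
  mf <- match(keyh, kf); mm <- match(keyh, km)
  keep <- !is.na(mf) & !is.na(mm)
  hs <- het_sites[keep, , drop = FALSE]
  pf <- pileup_female[mf[keep], , drop = FALSE]
  pm <- pileup_male[mm[keep], , drop = FALSE]
  rf <- base_count(pf, hs$ref); af <- base_count(pf, hs$alt)
  rm_ <- base_count(pm, hs$ref); am <- base_count(pm, hs$alt)
  df <- rf + af; dm <- rm_ + am
  ok <- df >= min_bulk_depth & dm >= min_bulk_depth
  out <- data.frame(chrom = hs$chrom[ok], pos = hs$pos[ok], ref = hs$ref[ok],
                    alt = hs$alt[ok], het_parent = hs$het_parent[ok],
                    index_female = af[ok] / df[ok],
                    index_male = am[ok] / dm[ok],
                    delta = af[ok] / df[ok] - am[ok] / dm[ok],
                    depth_female = df[ok], depth_male = dm[ok],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulation-based null confidence limits for SNP-index and delta
#'
#' For each alignment depth, repeats `reps` times: draw a bulk of
#' `bulk_size` F1 individuals in which each individual is heterozygous at an
#' unlinked site with probability 1/2; the bulk allele-pool alternate
#' fraction is k/(2 * bulk_size); read counts are binomial at the given
#' depth. Two bulks are drawn independently; per-level empirical quantiles of
#' the index and of delta form the confidence table.
#'
#' Common random numbers (shared uniforms across depths, counts via
#' `qbinom`) keep the half-widths weakly decreasing in depth up to
#' Monte-Carlo noise.
#'
#' @param depths integer vector of alignment depths to tabulate.
#' @param bulk_size individuals per bulk (default 50).
#' @param n_progeny size of the F1 population the bulks are drawn from
#'   (recorded; under the unlinked null it does not change the distribution).
#' @param reps simulation replicates per depth (default 10000).
#' @param levels confidence levels (default 95% and 99%).
#' @param seed optional seed for the whole simulation.
#' @param resample "replicate" redraws the bulk each replicate (default);
#'   "site" additionally redraws it for every depth.
#' @return data.frame of class `ci_table`: depth, level, index_lo, index_hi,
#'   delta_lo, delta_hi.
#' @export
null_ci <- function(depths, bulk_size = 50, n_progeny = 253, reps = 10000,
                    levels = c(0.95, 0.99), seed = NULL,
                    resample = c("replicate", "site")) {
  if (reps < 1) stop("reps must be >= 1")
  if (bulk_size > n_progeny) stop("bulk_size must be <= n_progeny")
  resample <- match.arg(resample)
  if (!is.null(seed)) set.seed(seed)
  if (reps == 1) warning("reps = 1: degenerate confidence bounds (lo = hi)")
  depths <- sort(unique(as.integer(depths)))
  kf <- rbinom(reps, bulk_size, 0.5)
  km <- rbinom(reps, bulk_size, 0.5)
  uf <- runif(reps); um <- runif(reps)
  rows <- list()
  for (d in depths) {
    if (resample == "site") {
      kf <- rbinom(reps, bulk_size, 0.5); km <- rbinom(reps, bulk_size, 0.5)
      uf <- runif(reps); um <- runif(reps)
    }
    idxf <- qbinom(uf, d, kf / (2 * bulk_size)) / d
    idxm <- qbinom(um, d, km / (2 * bulk_size)) / d
    delta <- idxf - idxm
    for (lv in levels) {
      a <- (1 - lv) / 2
      qi <- quantile(idxf, c(a, 1 - a), names = FALSE, type = 1)
      qd <- quantile(delta, c(a, 1 - a), names = FALSE, type = 1)
      rows[[length(rows) + 1L]] <- data.frame(
        depth = d, level = lv, index_lo = qi[1], index_hi = qi[2],
        delta_lo = qd[1], delta_hi = qd[2])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "bulk_size") <- bulk_size
  attr(out, "n_progeny") <- n_progeny
  attr(out, "reps") <- reps
  class(out) <- c("ci_table", "data.frame")
  out
}

#' Attach per-site confidence bounds from a null CI table
#'
#' Each site's bound is taken at the depth bin closest to
#' `min(depth_female, depth_male)` (the limiting sample).
#'
#' @param records output of [bulk_snp_index()].
#' @param ci_table output of [null_ci()].
#' @param level confidence level to use (must be present in `ci_table`).
#' @return `records` with `ci_lo` and `ci_hi` columns (delta bounds).
#' @export
attach_ci <- function(records, ci_table, level = 0.95) {
  ct <- ci_table[abs(ci_table$level - level) < 1e-9, , drop = FALSE]
  if (!nrow(ct)) stop("level not present in ci_table")
  d <- pmin(records$depth_female, records$depth_male)
  bin <- ct$depth[vapply(d, function(x) which.min(abs(ct$depth - x)),
                         integer(1))]
  m <- match(bin, ct$depth)
  records$ci_lo <- ct$delta_lo[m]
  records$ci_hi <- ct$delta_hi[m]
  records
}

#' Sliding-window averages of SNP-index records
#'
#' Windows start at 0, step, 2*step, ... and are emitted while start is less
#' than the chromosome length; the window end is clipped to the chromosome.
#' Means are arithmetic means over contained sites; windows without sites are
#' flagged empty. If per-site `ci_lo`/`ci_hi` columns are present (see
#' [attach_ci()]) their window means are included.
#'
#' @param records output of [bulk_snp_index()] (optionally with CI columns).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window_bp window size (default 1 Mb).
#' @param step_bp increment (default 50 kb).
#' @return data.frame: chrom, start, end, n_sites, mean_index_female,
#'   mean_index_male, mean_delta, (mean_ci_lo, mean_ci_hi), empty.
#' @export
sliding_window <- function(records, chrom_lengths, window_bp = 1e6,
                           step_bp = 5e4) {
  if (step_bp <= 0) stop("step_bp must be positive")
  has_ci <- all(c("ci_lo", "ci_hi") %in% names(records))
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = step_bp)
    ends <- pmin(starts + window_bp, L)
    r <- records[records$chrom == ch, , drop = FALSE]
    df <- data.frame(chrom = ch, start = starts, end = ends,
                     n_sites = 0L, mean_index_female = NA_real_,
                     mean_index_male = NA_real_, mean_delta = NA_real_,
                     stringsAsFactors = FALSE)
    if (has_ci) { df$mean_ci_lo <- NA_real_; df$mean_ci_hi <- NA_real_ }
    for (i in seq_along(starts)) {
      inw <- r$pos >= starts[i] & r$pos < ends[i]
      df$n_sites[i] <- sum(inw)
      if (any(inw)) {
        df$mean_index_female[i] <- mean(r$index_female[inw])
        df$mean_index_male[i] <- mean(r$index_male[inw])
        df$mean_delta[i] <- mean(r$delta[inw])
        if (has_ci) {
          df$mean_ci_lo[i] <- mean(r$ci_lo[inw])
          df$mean_ci_hi[i] <- mean(r$ci_hi[inw])
        }
      }
    }
    df$empty <- df$n_sites == 0L
    out[[ch]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call candidate sex-linked regions from windowed delta-SNP-index
#'
#' Windows whose mean delta lies outside the window-averaged confidence
#' bounds are significant; overlapping significant windows, or significant
#' windows separated by at most `merge_gap_bp`, merge into maximal intervals.
#'
#' @param windows output of [sliding_window()] on CI-attached records.
#' @param merge_gap_bp maximal gap between merged significant windows
#'   (default 0: only overlapping/adjacent windows merge).
#' @return data.frame: chrom, start, end, sign (+1/-1), n_windows, peak_delta.
#' @export
call_regions <- function(windows, merge_gap_bp = 0) {
  stopifnot(all(c("mean_ci_lo", "mean_ci_hi") %in% names(windows)))
  sig <- !windows$empty &
    (windows$mean_delta > windows$mean_ci_hi |
       windows$mean_delta < windows$mean_ci_lo)
  w <- windows[sig, , drop = FALSE]
  if (!nrow(w))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), sign = integer(0),
                      n_windows = integer(0), peak_delta = numeric(0)))
  w$sign <- ifelse(w$mean_delta > 0, 1L, -1L)
  out <- list()
  for (ch in unique(w$chrom)) {
    x <- w[w$chrom == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    cur <- x[1, ]
    acc <- list()
    n_w <- 1L; peak <- cur$mean_delta
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start[i] <= cur$end + merge_gap_bp && x$sign[i] == cur$sign) {
        cur$end <- max(cur$end, x$end[i])
        n_w <- n_w + 1L
        if (abs(x$mean_delta[i]) > abs(peak)) peak <- x$mean_delta[i]
      } else {
        acc[[length(acc) + 1L]] <- data.frame(
          chrom = ch, start = cur$start, end = cur$end, sign = cur$sign,
          n_windows = n_w, peak_delta = peak, stringsAsFactors = FALSE)
        cur <- x[i, ]; n_w <- 1L; peak <- cur$mean_delta
      }
    }
    acc[[length(acc) + 1L]] <- data.frame(
      chrom = ch, start = cur$start, end = cur$end, sign = cur$sign,
      n_windows = n_w, peak_delta = peak, stringsAsFactors = FALSE)
    out <- c(out, acc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' End-to-end QTL-seq on a synthetic cross
#'
#' Convenience pipeline: simulate parent and bulk pileups from an
#' `f1_population`, substitute the reference with the homozygous-different
#' parent alleles, classify parent-specific heterozygous sites, compute bulk
#' indices with simulation-based confidence limits, run the sliding window,
#' and call candidate regions. Bulks are the first `cfg$bulk_size` female-
#' and male-phenotype individuals.
#'
#' @param pop an [cross_f1()] population.
#' @param het_parent which parent's heterozygous sites to scan ("P3" finds
#'   W-linked regions).
#' @param level confidence level for calling (default 0.95).
#' @param reps null-simulation replicates (default 10000).
#' @param window_bp,step_bp sliding-window geometry.
#' @param seed seed for the CI simulation.
#' @return list: het_sites, records (CI-attached), windows, regions, truth.
#' @export
qtlseq_run <- function(pop, het_parent = "P3", level = 0.95, reps = 10000,
                       window_bp = 1e6, step_bp = 5e4, seed = NULL) {
  cfg <- attr(pop, "config")
  parents <- attr(pop, "parents")
  truth <- attr(pop, "truth")
  ref <- parents$reference %||% attr(truth, "reference")
  phen <- vapply(pop, `[[`, character(1), "phenotype")
  fem <- bulk_members(pop, which(phen == "female")[seq_len(cfg$bulk_size)])
  mal <- bulk_members(pop, which(phen == "male")[seq_len(cfg$bulk_size)])
  p3_pile <- sample_parent_pileup(parents$female, truth, ref, cfg)
  sub <- substitute_reference(ref, p3_pile, min_depth = 5)
  p3s <- sample_parent_pileup(parents$female, truth, sub$seqs, cfg)
  p4s <- sample_parent_pileup(parents$male, truth, sub$seqs, cfg)
  het <- classify_het_sites(p3s, p4s)
  het <- het[het$het_parent == het_parent, , drop = FALSE]
  pf <- sample_bulk_pileup(fem, sub$seqs, cfg)
  pm <- sample_bulk_pileup(mal, sub$seqs, cfg)
  rec <- bulk_snp_index(pf, pm, het)
  ct <- null_ci(unique(pmin(rec$depth_female, rec$depth_male)),
                bulk_size = cfg$bulk_size, n_progeny = cfg$n_f1,
                reps = reps, levels = unique(c(level, 0.95, 0.99)),
                seed = seed)
  rec <- attach_ci(rec, ct, level = level)
  win <- sliding_window(rec, cfg$chrom_lengths, window_bp, step_bp)
  regions <- call_regions(win)
  list(het_sites = het, records = rec, windows = win, regions = regions,
       ci_table = ct, truth = truth)
}
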