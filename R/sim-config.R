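#' Configuration for a synthetic ZW/ZZ cross
#'
#' Describes the simulated world: two highly heterozygous parents (a ZW female
#' and a ZZ male), a female-specific W insertion at a fixed locus with an
#' optional surrounding band of elevated Z/W divergence, an F1 population with
#' labile sex expression in ZW individuals, and shotgun sampling parameters.
#'
#' Defaults mirror the cross design the analyses are built for: 253 F1
#' progeny, phenotype bulks of 50, mean bulk depth 13 reads per site, and a
#' 50-kb female-specific insertion. Per-bp heterozygosity of 0.002 per parent
#' is of the order observed in highly heterozygous outcrossing crops.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp). The
#'   chromosome carrying `w_locus` acts as the sex chromosome pair.
#' @param het_rate_p3,het_rate_p4 per-bp probability of a parent-specific
#'   heterozygous site in the female (P3) / male (P4) parent.
#' @param shared_snp_rate per-bp probability of a site heterozygous in both
#'   parents (uninformative for mapping).
#' @param hom_diff_rate per-bp probability of a site where both parents are
#'   homozygous for a non-reference base (drives reference substitution).
#' @param w_insert_len length (bp) of the female-specific W insertion.
#' @param w_locus list with `chrom` and `pos` (0-based bp): insertion point of
#'   the W segment on the female parent's W haplotype.
#' @param w_flank_len half-width (bp) of the sex-determining region (SDR)
#'   around the insertion point. Inside the SDR every female-parent
#'   heterozygous site represents Z/W divergence: its alternate allele sits
#'   on the W haplotype.
#' @param w_flank_snp_rate per-bp probability of an additional W-linked
#'   heterozygous site inside the SDR (elevated Z/W divergence density, on
#'   top of `het_rate_p3`).
#' @param n_f1 F1 population size.
#' @param bulk_size individuals per phenotype bulk.
#' @param depth mean read depth per site for a bulk pileup (Poisson mean).
#' @param parent_depth mean read depth per site for a parent pileup.
#' @param read_len read length (bp) for shotgun read sampling.
#' @param error_rate per-base probability of a substitution sequencing error
#'   (uniform over the three other bases; no indel errors).
#' @param xover_rate expected crossovers per chromosome per meiosis
#'   (Poisson count, uniform positions, no interference).
#' @param lability named numeric vector `c(male=, monoecious=, nonflowering=)`:
#'   probabilities that a ZW individual expresses each non-female phenotype;
#'   ZW is female with the remaining probability. ZZ is always male.
#' @param emit_sequences if `FALSE`, no nucleotide sequences are generated
#'   (genotype-only simulations; much faster for linkage studies).
#' @param seed optional integer seed applied by [simulate_parents()].
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(chrom_lengths = c(chr01 = 3e6, chr02 = 3e6),
                       het_rate_p3 = 0.002,
                       het_rate_p4 = 0.002,
                       shared_snp_rate = 5e-4,
                       hom_diff_rate = 5e-4,
                       w_insert_len = 50000,
                       w_locus = list(chrom = "chr02", pos = 1.5e6),
                       w_flank_len = 6e5,
                       w_flank_snp_rate = 0.005,
                       n_f1 = 253,
                       bulk_size = 50,
                       depth = 13,
                       parent_depth = 40,
                       read_len = 100,
                       error_rate = 0.001,
                       xover_rate = 1,
                       lability = c(male = 0.03, monoecious = 0.04,
                                    nonflowering = 0.10),
                       emit_sequences = TRUE,
                       seed = NULL) {
  cfg <- list(chrom_lengths = chrom_lengths, het_rate_p3 = het_rate_p3,
              het_rate_p4 = het_rate_p4, shared_snp_rate = shared_snp_rate,
              hom_diff_rate = hom_diff_rate, w_insert_len = w_insert_len,
              w_locus = w_locus, w_flank_len = w_flank_len,
              w_flank_snp_rate = w_flank_snp_rate, n_f1 = n_f1,
              bulk_size = bulk_size, depth = depth,
              parent_depth = parent_depth, read_len = read_len,
              error_rate = error_rate, xover_rate = xover_rate,
              lability = lability, emit_sequences = emit_sequences,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$chrom_lengths) >= 1, !is.null(names(cfg$chrom_lengths)))
  if (any(cfg$chrom_lengths <= 0)) stop("zero-length chromosome")
  rates <- c(cfg$het_rate_p3, cfg$het_rate_p4, cfg$shared_snp_rate,
             cfg$hom_diff_rate, cfg$w_flank_snp_rate, cfg$error_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  lab <- cfg$lability
  stopifnot(all(c("male", "monoecious", "nonflowering") %in% names(lab)))
  if (any(lab < 0) || sum(lab) > 1)
    stop("lability probabilities must be non-negative and sum to <= 1")
  if (cfg$bulk_size > cfg$n_f1) stop("bulk_size must be <= n_f1")
  wl <- cfg$w_locus
  if (!wl$chrom %in% names(cfg$chrom_lengths))
    stop("w_locus chromosome not in chrom_lengths")
  if (wl$pos < 0 || wl$pos >= cfg$chrom_lengths[[wl$chrom]])
    stop("w_locus out of range")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", length(x$chrom_lengths), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp total\n")
  cat("  W insertion:", x$w_insert_len, "bp at", x$w_locus$chrom, "pos",
      x$w_locus$pos, "\n")
  cat("  F1:", x$n_f1, " bulks:", x$bulk_size, " bulk depth:", x$depth, "\n")
  invisible(x)
}
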