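#' End-to-end W-region identification on a synthetic cross
#'
#' Materializes the haplotypes of a female (ZW) and a male (ZZ) phenotype
#' bulk, samples shotgun reads, maps both bulks to the combined dual-parent
#' reference (each parent's two haplotypes as "assembly" contigs), computes
#' bulk-specific regions, selects female-specific contigs, anchors them on
#' the W-carrying haplotype and delineates the W interval.
#'
#' @param pop an [cross_f1()] population.
#' @param depth expected per-haplotype-copy coverage of the bulk reads
#'   (default 0.35: a bulk of 50 then covers a W-specific base ~17x).
#' @param min_fragment_bp contig-selection threshold; default one read
#'   length (`NULL` uses the N20 rule of [select_specific_contigs()]).
#' @param use_zz_bulk if `TRUE`, the male-bulk alignments against the anchor
#'   target are used to trim the delineated interval.
#' @return list: regions, selected contigs, anchors, call (a
#'   `w_region_call`), truth interval, alignments.
#' @export
wregion_run <- function(pop, depth = 0.35, min_fragment_bp = NULL,
                        use_zz_bulk = FALSE) {
  cfg <- attr(pop, "config")
  parents <- attr(pop, "parents")
  truth <- attr(pop, "truth")
  phen <- vapply(pop, `[[`, character(1), "phenotype")
  fem <- bulk_members(pop, which(phen == "female")[seq_len(cfg$bulk_size)])
  mal <- bulk_members(pop, which(phen == "male")[seq_len(cfg$bulk_size)])
  pool_haps <- function(bulk) {
    out <- character(0)
    for (i in seq_along(bulk)) {
      h <- f1_haplotypes(bulk[[i]], parents)
      names(h) <- paste0("ind", i, "_", names(h))
      out <- c(out, h)
    }
    out
  }
  reads_f <- sample_reads(pool_haps(fem), depth, cfg$read_len,
                          cfg$error_rate)
  reads_m <- sample_reads(pool_haps(mal), depth, cfg$read_len,
                          cfg$error_rate)
  chroms <- names(cfg$chrom_lengths)
  asm_f <- setNames(
    unlist(lapply(chroms, function(ch)
      c(materialize_haplotype(parents$female, ch, 1),
        materialize_haplotype(parents$female, ch, 2)))),
    unlist(lapply(chroms, function(ch) paste0("P3_", ch, "_h", 1:2))))
  asm_m <- setNames(
    unlist(lapply(chroms, function(ch) parents$male$haplotypes[[ch]])),
    unlist(lapply(chroms, function(ch) paste0("P4_", ch, "_h", 1:2))))
  ref <- combine_references(asm_f, asm_m)
  aln_f <- map_reads(reads_f, ref)
  aln_m <- map_reads(reads_m, ref)
  regions <- specific_regions(aln_f, aln_m, ref)
  thr <- min_fragment_bp %||% cfg$read_len
  sel <- select_specific_contigs(regions, min_fragment_bp = thr)
  wch <- parents$female$w_chrom
  target <- setNames(asm_f[paste0("P3_", wch, "_h2")], "W_hap")
  anchors <- anchor_contigs(asm_f[intersect(sel, names(asm_f))], target)
  zz_aln <- NULL
  if (use_zz_bulk) zz_aln <- map_reads(reads_m, target)
  call <- delineate_w_interval(anchors, regions, zz_aln,
                               setNames(nchar(target), names(target)))
  list(regions = regions, selected = sel, anchors = anchors, call = call,
       truth_interval = attr(truth, "w_interval"),
       aln_female = aln_f, aln_male = aln_m)
}
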