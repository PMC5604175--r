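#' In silico PCR
#'
#' Exact primer matching: every forward-primer match paired with every
#' downstream reverse-complemented reverse-primer match within
#' `max_product` yields an amplicon, inclusive of both primer sites.
#'
#' @param template template sequence (ACGTN string).
#' @param forward,reverse primer sequences 5'->3'.
#' @param max_product maximum amplicon length (default 3000).
#' @return data.frame: start, end (0-based half-open on template), length,
#'   seq. Empty if no amplification.
#' @export
insilico_pcr <- function(template, forward, reverse, max_product = 3000) {
  stopifnot(nzchar(forward), nzchar(reverse),
            grepl("^[ACGT]+$", forward), grepl("^[ACGT]+$", reverse))
  fpos <- find_all(template, forward)
  rpos <- find_all(template, revcomp(reverse))
  out <- list()
  for (f in fpos) {
    ends <- rpos[rpos >= f + nchar(forward)] + nchar(reverse)
    ends <- ends[ends - f <= max_product]
    for (e in ends)
      out[[length(out) + 1L]] <- data.frame(
        start = f, end = e, length = e - f,
        seq = substr(template, f + 1, e), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), seq = character(0)))
  do.call(rbind, out)
}

# fragment lengths of one amplicon after digestion at all site occurrences
digest_fragments <- function(amplicon, enzyme_site, cut_offset) {
  sites <- find_all(amplicon, enzyme_site)
  cuts <- sites + cut_offset
  diff(c(0, cuts, nchar(amplicon)))
}

#' CAPS genotyping of a diploid template
#'
#' Amplifies each haplotype with [insilico_pcr()] and digests the amplicons
#' with a restriction enzyme. Per haplotype the allele is "A" (uncleaved) or
#' "B" (cleaved); the genotype is A/A, A/B or B/B. If only one haplotype
#' amplifies the genotype is called from that haplotype alone and flagged
#' hemizygous; if neither amplifies the call is "no-amp".
#'
#' @param hap1,hap2 haplotype template sequences.
#' @param forward,reverse primer pair.
#' @param enzyme_site recognition sequence (default EcoRI, GAATTC).
#' @param cut_offset cut position within the site (default 1: G^AATTC).
#' @param max_product as in [insilico_pcr()].
#' @return list of class `caps_result`: genotype, hemizygous, per-haplotype
#'   amplicon lengths and fragment lengths.
#' @export
caps_genotype <- function(hap1, hap2, forward, reverse,
                          enzyme_site = "GAATTC", cut_offset = 1,
                          max_product = 3000) {
  res <- lapply(list(hap1, hap2), function(h) {
    amp <- insilico_pcr(h, forward, reverse, max_product)
    if (!nrow(amp)) return(NULL)
    frags <- lapply(amp$seq, digest_fragments, enzyme_site = enzyme_site,
                    cut_offset = cut_offset)
    list(amplicons = amp$length, fragments = frags,
         allele = if (any(vapply(frags, length, integer(1)) > 1)) "B" else "A")
  })
  amped <- !vapply(res, is.null, logical(1))
  genotype <- if (!any(amped)) "no-amp" else {
    al <- vapply(res[amped], `[[`, character(1), "allele")
    if (length(al) == 1) paste(al, al, sep = "/") else
      paste(sort(al), collapse = "/")
  }
  structure(list(genotype = genotype, hemizygous = sum(amped) == 1,
                 haplotypes = res), class = "caps_result")
}

#' @export
print.caps_result <- function(x, ...) {
  cat("CAPS genotype:", x$genotype,
      if (x$hemizygous) "(hemizygous)" else "", "\n")
  invisible(x)
}

#' Genotype inference from a dominant presence/absence marker
#'
#' Under the ZW model with a female-specific dominant marker: amplification
#' implies ZW, absence implies ZZ; a failed positive control voids the call.
#'
#' @param marker_amplified logical vector: marker band present.
#' @param control_amplified logical vector: positive control band present.
#' @return character vector: "ZW", "ZZ" or "failed".
#' @export
dominant_genotype <- function(marker_amplified, control_amplified) {
  ifelse(!control_amplified, "failed",
         ifelse(marker_amplified, "ZW", "ZZ"))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Probability-mass criterion: the two-sided p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (within a relative tolerance
#' of 1e-7, the common convention). Computed in log space.
#'
#' @param t a 2x2 matrix (or something coercible) of non-negative counts.
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(t) {
  t <- matrix(as.numeric(t), 2, 2)
  if (any(t < 0) || any(t != round(t))) stop("counts must be non-negative integers")
  r1 <- sum(t[1, ]); c1 <- sum(t[, 1]); n <- sum(t)
  if (n == 0) return(1)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  obs <- logp[x == t[1, 1]]
  keep <- logp <= obs + log(1 + 1e-7)
  mx <- max(logp[keep])
  min(1, exp(mx + log(sum(exp(logp[keep] - mx)))))
}

#' Marker-phenotype concordance report
#'
#' Cross-tabulates dominant-marker genotype calls against sex phenotypes,
#' per season and collapsed over individuals with a consistent multi-season
#' phenotype; individuals whose phenotype changed between seasons are
#' tabulated separately. Under the ZW model, concordance counts ZW calls in
#' non-male plants and ZZ calls in males.
#'
#' @param calls data.frame: id, genotype ("ZW"/"ZZ"/"failed").
#' @param phenotypes data.frame: id, season, sex
#'   ("male"/"female"/"monoecious"/"nonflowering").
#' @return list of class `concordance_report`: per_season (list of tables
#'   with p-values), consistent (table over consistently-phenotyped
#'   plants), inconsistent_ids, unphenotyped_ids, concordance (fraction
#'   over consistent flowering plants).
#' @export
concordance_report <- function(calls, phenotypes) {
  if (!nrow(calls)) stop("empty input")
  calls <- calls[calls$genotype %in% c("ZW", "ZZ"), , drop = FALSE]
  unphen <- setdiff(calls$id, phenotypes$id)
  tab_one <- function(ids, sex) {
    g <- calls$genotype[match(ids, calls$id)]
    male <- sex == "male"
    t <- matrix(c(sum(g == "ZW" & !male), sum(g == "ZW" & male),
                  sum(g == "ZZ" & !male), sum(g == "ZZ" & male)),
                2, 2, byrow = TRUE,
                dimnames = list(genotype = c("ZW", "ZZ"),
                                phenotype = c("not_male", "male")))
    p <- if (all(rowSums(t) > 0) && all(colSums(t) > 0)) fisher_exact(t)
    else NA_real_
    list(table = t, p = p,
         concordance = (t["ZW", "not_male"] + t["ZZ", "male"]) / sum(t))
  }
  per_season <- list()
  for (s in unique(phenotypes$season)) {
    ph <- phenotypes[phenotypes$season == s, , drop = FALSE]
    ph <- ph[ph$id %in% calls$id, , drop = FALSE]
    per_season[[as.character(s)]] <- tab_one(ph$id, ph$sex)
  }
  sx <- split(phenotypes$sex, phenotypes$id)
  consistent_ids <- names(sx)[vapply(sx, function(v)
    length(unique(v)) == 1, logical(1))]
  consistent_ids <- intersect(consistent_ids, calls$id)
  inconsistent_ids <- setdiff(intersect(names(sx), calls$id), consistent_ids)
  cons_sex <- vapply(sx[consistent_ids], `[[`, character(1), 1)
  consistent <- tab_one(consistent_ids, cons_sex)
  structure(list(per_season = per_season, consistent = consistent,
                 inconsistent_ids = inconsistent_ids,
                 unphenotyped_ids = unphen,
                 concordance = consistent$concordance),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance (consistent plants):",
      sprintf("%.3f", x$concordance),
      sprintf("(Fisher p = %.3g)\n", x$consistent$p))
  print(x$consistent$table)
  if (length(x$inconsistent_ids))
    cat(length(x$inconsistent_ids), "plants with inconsistent phenotype\n")
  invisible(x)
}
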