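#' Simulate two heterozygous parents of a ZW x ZZ cross
#'
#' Generates an ancestral reference sequence per chromosome, places
#' parent-specific heterozygous sites, shared heterozygous sites and sites
#' homozygous-different in both parents by independent per-bp draws, and
#' inserts a female-specific W segment (plus an elevated-divergence band of
#' fully W-linked heterozygous sites around it) on one haplotype of the
#' female parent.
#'
#' Internally all coordinates are 0-based half-open against the ancestral
#' reference; the W insertion is kept separate from the reference-coordinate
#' backbone and spliced in only when a haplotype is materialized, so
#' reference-based bookkeeping (pileups, truth table) never shifts.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `female` and `male` (class `parent_genome`),
#'   `truth` (class `truth_table`: data.frame of variants plus attributes
#'   `w_interval`, the inserted segment in W-haplotype coordinates, and
#'   `reference`, the ancestral sequences), and `reference`.
#' @export
simulate_parents <- function(cfg) {
  validate_sim_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  chroms <- names(cfg$chrom_lengths)
  ref <- if (cfg$emit_sequences) {
    setNames(vapply(cfg$chrom_lengths, random_dna, character(1)), chroms)
  } else setNames(rep(NA_character_, length(chroms)), chroms)

  draw_sites <- function(L, rate) {
    n <- rbinom(1, L, rate)
    if (n == 0) integer(0) else sort(sample.int(L, n)) - 1L
  }

  tt <- list()
  for (ch in chroms) {
    L <- cfg$chrom_lengths[[ch]]
    cat_pos <- list(p3het = draw_sites(L, cfg$het_rate_p3),
                    p4het = draw_sites(L, cfg$het_rate_p4),
                    shared = draw_sites(L, cfg$shared_snp_rate),
                    homdiff = draw_sites(L, cfg$hom_diff_rate))
    if (ch == cfg$w_locus$chrom && cfg$w_flank_len > 0 &&
        cfg$w_flank_snp_rate > 0) {
      lo <- max(0L, as.integer(cfg$w_locus$pos - cfg$w_flank_len))
      hi <- min(L - 1L, as.integer(cfg$w_locus$pos + cfg$w_flank_len))
      span <- hi - lo + 1L
      n <- rbinom(1, span, cfg$w_flank_snp_rate)
      flank <- if (n == 0) integer(0) else lo + sort(sample.int(span, n)) - 1L
      cat_pos$wflank <- flank
    } else cat_pos$wflank <- integer(0)
    df <- data.frame(
      chrom = rep(ch, sum(lengths(cat_pos))),
      pos = unlist(cat_pos, use.names = FALSE),
      category = rep(c("p3het", "p4het", "shared", "homdiff", "p3het"),
                     lengths(cat_pos)),
      w_linked = rep(c(FALSE, FALSE, FALSE, FALSE, TRUE), lengths(cat_pos)),
      stringsAsFactors = FALSE)
    # collisions across categories: keep the first occurrence
    df <- df[!duplicated(df$pos), , drop = FALSE]
    df <- df[order(df$pos), , drop = FALSE]
    tt[[ch]] <- df
  }
  truth <- do.call(rbind, tt)
  rownames(truth) <- NULL
  n <- nrow(truth)

  if (cfg$emit_sequences && n > 0) {
    truth$ref <- unlist(lapply(chroms, function(ch)
      base_at(ref[[ch]], truth$pos[truth$chrom == ch])), use.names = FALSE)
  } else {
    truth$ref <- if (n) sample(BASES, n, replace = TRUE) else character(0)
  }
  truth$alt <- if (n) {
    vapply(truth$ref, function(b) sample(setdiff(BASES, b), 1), character(1),
           USE.NAMES = FALSE)
  } else character(0)

  # inside the SDR, all female-het sites are Z/W divergence: alt on W
  in_sdr <- truth$chrom == cfg$w_locus$chrom &
    abs(truth$pos - cfg$w_locus$pos) <= cfg$w_flank_len
  truth$w_linked <- truth$w_linked | (in_sdr & truth$category == "p3het")

  # which parent haplotype carries the alternate allele (0 = none, 3 = both)
  truth$alt_hap_p3 <- rep(0L, n)
  truth$alt_hap_p4 <- rep(0L, n)
  is_p3 <- truth$category == "p3het"
  truth$alt_hap_p3[is_p3] <- ifelse(truth$w_linked[is_p3], 2L,
                                    sample(1:2, sum(is_p3), replace = TRUE))
  is_p4 <- truth$category == "p4het"
  truth$alt_hap_p4[is_p4] <- sample(1:2, sum(is_p4), replace = TRUE)
  is_sh <- truth$category == "shared"
  truth$alt_hap_p3[is_sh] <- sample(1:2, sum(is_sh), replace = TRUE)
  truth$alt_hap_p4[is_sh] <- sample(1:2, sum(is_sh), replace = TRUE)
  is_hd <- truth$category == "homdiff"
  truth$alt_hap_p3[is_hd] <- 3L
  truth$alt_hap_p4[is_hd] <- 3L

  w_insert <- if (cfg$emit_sequences) random_dna(cfg$w_insert_len) else
    NA_character_

  build_parent <- function(which_parent, sex) {
    haps <- NULL
    if (cfg$emit_sequences) {
      haps <- lapply(setNames(chroms, chroms), function(ch) {
        sel <- truth$chrom == ch
        ah <- if (which_parent == "p3") truth$alt_hap_p3[sel] else
          truth$alt_hap_p4[sel]
        pos <- truth$pos[sel]; alt <- truth$alt[sel]
        h1 <- apply_subs(ref[[ch]], pos[ah %in% c(1L, 3L)],
                         alt[ah %in% c(1L, 3L)])
        h2 <- apply_subs(ref[[ch]], pos[ah %in% c(2L, 3L)],
                         alt[ah %in% c(2L, 3L)])
        c(h1, h2)
      })
    }
    structure(list(name = if (which_parent == "p3") "P3" else "P4",
                   sex_genotype = sex, haplotypes = haps,
                   chrom_lengths = cfg$chrom_lengths,
                   w_insert = if (sex == "ZW") w_insert else NULL,
                   w_pos = if (sex == "ZW") as.integer(cfg$w_locus$pos) else NULL,
                   w_chrom = if (sex == "ZW") cfg$w_locus$chrom else NULL,
                   w_hap = if (sex == "ZW") 2L else NULL),
              class = "parent_genome")
  }
  female <- build_parent("p3", "ZW")
  male <- build_parent("p4", "ZZ")

  w_interval <- list(chrom = cfg$w_locus$chrom,
                     start = as.integer(cfg$w_locus$pos),
                     end = as.integer(cfg$w_locus$pos + cfg$w_insert_len))
  attr(truth, "w_interval") <- w_interval
  attr(truth, "w_locus") <- cfg$w_locus
  class(truth) <- c("truth_table", "data.frame")
  list(female = female, male = male, truth = truth, reference = ref)
}

#' Materialize one parental haplotype sequence
#'
#' Splices the W insertion into the W-carrying haplotype; other haplotypes are
#' returned as stored.
#'
#' @param parent a `parent_genome`.
#' @param chrom chromosome name.
#' @param hap haplotype index (1 or 2).
#' @return a single sequence string.
#' @export
materialize_haplotype <- function(parent, chrom, hap) {
  s <- parent$haplotypes[[chrom]][hap]
  if (!is.null(parent$w_chrom) && chrom == parent$w_chrom &&
      hap == parent$w_hap && nchar(parent$w_insert) > 0) {
    p <- parent$w_pos # 0-based insertion point: insert before this base
    s <- paste0(substr(s, 1, p), parent$w_insert,
                substr(s, p + 1, nchar(s)))
  }
  s
}

# A gamete: per chromosome, crossover breakpoints (0-based, sorted) plus the
# haplotype (1/2) transmitted left of the first breakpoint.
make_gamete <- function(chrom_lengths, xover_rate) {
  lapply(chrom_lengths, function(L) {
    nx <- rpois(1, xover_rate)
    list(breaks = sort(runif(nx, 0, L)), start = sample(1:2, 1))
  })
}

# Source haplotype (1/2) of a gamete at 0-based positions `pos`.
gamete_source <- function(gam, pos) {
  k <- findInterval(pos, gam$breaks)
  ifelse(k %% 2 == 0, gam$start, 3L - gam$start)
}

#' Simulate an F1 population from a ZW x ZZ cross
#'
#' Each individual receives one recombinant gamete from each parent
#' (Poisson crossover count per chromosome, uniform positions, no
#' interference). The sex genotype is ZW if the female parent transmitted the
#' W-carrying haplotype at the sex locus, else ZZ. ZZ individuals are always
#' male; ZW individuals express female/male/monoecious/non-flowering
#' phenotypes according to `cfg$lability`.
#'
#' @param parents result of [simulate_parents()] (or a list with `female`
#'   and `male` `parent_genome`s).
#' @param cfg the [sim_config()].
#' @return an object of class `f1_population`: a list of individuals, each
#'   with `gametes` (list chrom -> list(f, m)), `sex_genotype`, `phenotype`;
#'   attributes `parents`, `truth`, `config`.
#' @export
cross_f1 <- function(parents, cfg) {
  female <- parents$female; male <- parents$male
  if (female$sex_genotype == male$sex_genotype)
    stop("parents must be one ZW and one ZZ genotype")
  lab <- cfg$lability
  p_pheno <- c(female = 1 - sum(lab), male = lab[["male"]],
               monoecious = lab[["monoecious"]],
               nonflowering = lab[["nonflowering"]])
  cl <- cfg$chrom_lengths
  inds <- vector("list", cfg$n_f1)
  for (i in seq_len(cfg$n_f1)) {
    gf <- make_gamete(cl, cfg$xover_rate)
    gm <- make_gamete(cl, cfg$xover_rate)
    src_w <- gamete_source(gf[[female$w_chrom]], female$w_pos)
    sexg <- if (src_w == female$w_hap) "ZW" else "ZZ"
    pheno <- if (sexg == "ZZ") "male" else
      sample(names(p_pheno), 1, prob = p_pheno)
    inds[[i]] <- list(
      gametes = lapply(setNames(names(cl), names(cl)),
                       function(ch) list(f = gf[[ch]], m = gm[[ch]])),
      sex_genotype = sexg, phenotype = pheno)
  }
  structure(inds, class = "f1_population", parents = parents,
            truth = parents$truth, config = cfg)
}

#' @export
print.f1_population <- function(x, ...) {
  cat("f1_population:", length(x), "individuals;",
      sum(vapply(x, `[[`, character(1), "sex_genotype") == "ZW"), "ZW\n")
  print(table(phenotype = vapply(x, `[[`, character(1), "phenotype")))
  invisible(x)
}

#' Subset an F1 population into a bulk, keeping simulation attributes
#'
#' @param pop an `f1_population`.
#' @param idx indices or logical selector of individuals.
#' @return an `f1_population` containing the selected individuals.
#' @export
bulk_members <- function(pop, idx) {
  structure(unclass(pop)[idx], class = "f1_population",
            parents = attr(pop, "parents"), truth = attr(pop, "truth"),
            config = attr(pop, "config"))
}

# Logical matrix [site x haplotype] of alternate-allele carriage over the
# pooled haplotypes (2 per individual) of a set of F1 individuals, at the
# truth-table sites of one chromosome subset (or all).
hap_alt_matrix <- function(individuals, truth) {
  n <- length(individuals)
  out <- matrix(FALSE, nrow(truth), 2L * n)
  for (ch in unique(truth$chrom)) {
    sel <- which(truth$chrom == ch)
    pos <- truth$pos[sel]
    ah3 <- truth$alt_hap_p3[sel]
    ah4 <- truth$alt_hap_p4[sel]
    for (i in seq_len(n)) {
      g <- individuals[[i]]$gametes[[ch]]
      sf <- gamete_source(g$f, pos)
      sm <- gamete_source(g$m, pos)
      out[sel, 2L * i - 1L] <- sf == ah3 | ah3 == 3L
      out[sel, 2L * i] <- sm == ah4 | ah4 == 3L
    }
  }
  out
}

# Sequencing-error model: flip each TRUE-indexed base to one of the 3 other
# bases with probability e. bases: character vector.
apply_seq_errors <- function(bases, e) {
  if (e <= 0 || length(bases) == 0) return(bases)
  hit <- which(runif(length(bases)) < e)
  if (length(hit)) {
    shift <- sample.int(3, length(hit), replace = TRUE)
    idx <- (match(bases[hit], BASES) - 1L + shift) %% 4L + 1L
    bases[hit] <- BASES[idx]
  }
  bases
}

#' Sample a per-site allele-count pileup from a bulk
#'
#' A shortcut producing the per-site counts an aligner + pileup caller would
#' yield: at every truth-table site, total depth is Poisson(`cfg$depth`),
#' each read is drawn from a uniformly random individual's uniformly random
#' haplotype, and each read base is flipped to a uniformly random other base
#' with probability `cfg$error_rate`.
#'
#' @param bulk an `f1_population` (e.g. from [bulk_members()]).
#' @param ref_seqs named character vector of reference sequences used to
#'   report the `ref` base column (pass a substituted reference to genotype
#'   against it); `NULL` uses the truth-table ancestral base.
#' @param cfg the [sim_config()]; `depth` may be overridden.
#' @param depth mean depth per site; defaults to `cfg$depth`.
#' @return data.frame (class `pileup`): chrom, pos (0-based), ref, A, C, G, T,
#'   depth.
#' @export
sample_bulk_pileup <- function(bulk, ref_seqs = NULL, cfg = attr(bulk, "config"),
                               depth = cfg$depth) {
  if (length(bulk) == 0) stop("empty bulk")
  truth <- attr(bulk, "truth")
  alt_mat <- hap_alt_matrix(bulk, truth)
  f_alt <- rowMeans(alt_mat)
  pileup_from_freq(truth, f_alt, ref_seqs, depth, cfg$error_rate)
}

#' Sample a per-site allele-count pileup from a single (parent) genome
#'
#' @param parent a `parent_genome`.
#' @param truth the truth table from [simulate_parents()].
#' @param ref_seqs as in [sample_bulk_pileup()].
#' @param cfg the [sim_config()].
#' @param depth mean depth; defaults to `cfg$parent_depth`.
#' @return a `pileup` data.frame.
#' @export
sample_parent_pileup <- function(parent, truth, ref_seqs = NULL, cfg,
                                 depth = cfg$parent_depth) {
  ah <- if (parent$name == "P3") truth$alt_hap_p3 else truth$alt_hap_p4
  f_alt <- c(0, 0.5, 0.5, 1)[ah + 1L]
  pileup_from_freq(truth, f_alt, ref_seqs, depth, cfg$error_rate)
}

# Shared pileup sampler: per site, depth ~ Poisson(depth); alt reads binomial
# with the site's pooled alternate fraction; per-base errors applied.
pileup_from_freq <- function(truth, f_alt, ref_seqs, depth, error_rate) {
  n <- nrow(truth)
  d <- rpois(n, depth)
  site <- rep.int(seq_len(n), d)
  is_alt <- runif(length(site)) < f_alt[site]
  bases <- ifelse(is_alt, truth$alt[site], truth$ref[site])
  bases <- apply_seq_errors(bases, error_rate)
  counts <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  if (length(site)) {
    tab <- tabulate((site - 1L) * 4L + match(bases, BASES), nbins = n * 4L)
    counts <- matrix(tab, n, 4, byrow = TRUE, dimnames = list(NULL, BASES))
  }
  ref_base <- truth$ref
  if (!is.null(ref_seqs)) {
    ref_base <- unlist(lapply(unique(truth$chrom), function(ch)
      base_at(ref_seqs[[ch]], truth$pos[truth$chrom == ch])),
      use.names = FALSE)
  }
  out <- data.frame(chrom = truth$chrom, pos = truth$pos, ref = ref_base,
                    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
                    T = counts[, "T"], depth = as.integer(d),
                    stringsAsFactors = FALSE)
  class(out) <- c("pileup", "data.frame")
  out
}

#' Sample fixed-length shotgun reads from a set of sequences
#'
#' Reads are uniformly positioned, taken from either strand with probability
#' 1/2, with per-base substitution errors. The expected per-base coverage of
#' the supplied sequence set equals `depth`, i.e. the total number of emitted
#' bases is Poisson with mean `depth * sum(nchar(seqs))`.
#'
#' @param seqs named character vector of source sequences (e.g. all pooled
#'   haplotypes of a bulk).
#' @param depth expected per-base coverage of the pooled set.
#' @param read_len read length (bp); must not exceed the shortest sequence.
#' @param error_rate per-base substitution error probability.
#' @return data.frame: id, seq, source, start (0-based on source), strand.
#' @export
sample_reads <- function(seqs, depth, read_len, error_rate = 0) {
  lens <- nchar(seqs)
  if (read_len > min(lens)) stop("read_len exceeds shortest sequence")
  n_reads <- rpois(1, depth * sum(lens) / read_len)
  if (n_reads == 0)
    return(data.frame(id = character(0), seq = character(0),
                      source = character(0), start = integer(0),
                      strand = character(0)))
  nstarts <- lens - read_len + 1L
  src <- sample.int(length(seqs), n_reads, replace = TRUE,
                    prob = nstarts / sum(nstarts))
  start <- floor(runif(n_reads) * nstarts[src])
  rd <- substring(seqs[src], start + 1L, start + read_len)
  rev <- runif(n_reads) < 0.5
  rd[rev] <- revcomp(rd[rev])
  if (error_rate > 0) {
    flat <- unlist(strsplit(rd, "", fixed = TRUE), use.names = FALSE)
    flat <- apply_seq_errors(flat, error_rate)
    m <- matrix(flat, nrow = n_reads, byrow = TRUE)
    rd <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  data.frame(id = sprintf("r%06d", seq_len(n_reads)), seq = unname(rd),
             source = names(seqs)[src] %||% as.character(src),
             start = as.integer(start),
             strand = ifelse(rev, "-", "+"), stringsAsFactors = FALSE)
}

#' In silico double-digest RAD tag extraction
#'
#' One tag per strand-oriented occurrence of the first (rare) recognition
#' site, extending from the cut junction (taken at the 3' end of the site on
#' the tag's strand) toward the nearest downstream occurrence of the second
#' (frequent) site, truncated to `tag_len`.
#'
#' @param seqs named character vector of sequences.
#' @param site1 rare-cutter recognition sequence (default PacI, TTAATTAA).
#' @param site2 frequent-cutter recognition sequence (default NlaIII, CATG).
#' @param tag_len maximum tag length (bp).
#' @return data.frame: chrom, start, end (0-based half-open, forward-strand
#'   coordinates), strand, seq.
#' @export
digest_radtags <- function(seqs, site1 = "TTAATTAA", site2 = "CATG",
                           tag_len = 95) {
  stopifnot(nzchar(site1), nzchar(site2))
  out <- list()
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    L <- nchar(s)
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") s else revcomp(s)
      s1 <- find_all(subject, site1)
      if (!length(s1)) next
      s2 <- find_all(subject, site2)
      jct <- s1 + nchar(site1)
      nxt <- s2[findInterval(jct - 1L, s2) + 1L] # first site2 start >= jct
      end <- ifelse(is.na(nxt), jct + tag_len,
                    pmin(nxt + nchar(site2), jct + tag_len))
      end <- pmin(end, L)
      keep <- end > jct
      jct <- jct[keep]; end <- end[keep]
      if (!length(jct)) next
      tag <- substring(subject, jct + 1L, end)
      if (strand == "+") {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = jct, end = end, strand = strand, seq = tag,
          stringsAsFactors = FALSE)
      } else {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = L - end, end = L - jct, strand = strand,
          seq = tag, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      seq = character(0)))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}
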