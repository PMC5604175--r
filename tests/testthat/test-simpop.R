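test_that("config validation rejects inconsistent worlds", {
  expect_error(small_cfg(chrom_lengths = c(chr01 = 0)), "zero-length")
  expect_error(small_cfg(w_locus = list(chrom = "chr01", pos = 5e5)),
               "out of range")
  expect_error(small_cfg(bulk_size = 100, n_f1 = 50), "bulk_size")
  expect_error(small_cfg(lability = c(male = 0.6, monoecious = 0.3,
                                      nonflowering = 0.3)), "lability")
  expect_error(small_cfg(error_rate = 1.5), "rates")
})

test_that("degenerate parents: no heterozygosity, no insertion", {
  cfg <- small_cfg(chrom_lengths = c(chr01 = 5000, chr02 = 5000),
                   w_locus = list(chrom = "chr02", pos = 2500),
                   het_rate_p3 = 0, het_rate_p4 = 0, shared_snp_rate = 0,
                   hom_diff_rate = 0, w_insert_len = 0, w_flank_len = 0,
                   w_flank_snp_rate = 0, seed = 5)
  p <- simulate_parents(cfg)
  expect_equal(nrow(p$truth), 0)
  expect_identical(p$female$haplotypes$chr01[1], p$female$haplotypes$chr01[2])
  expect_identical(p$female$haplotypes$chr01[1], p$male$haplotypes$chr01[1])
  expect_identical(materialize_haplotype(p$female, "chr02", 2),
                   p$female$haplotypes$chr02[2])
})

test_that("W insertion lengthens exactly one female haplotype", {
  cfg <- small_cfg(chrom_lengths = c(chr02 = 20000),
                   w_locus = list(chrom = "chr02", pos = 10000),
                   w_insert_len = 5000, seed = 6)
  p <- simulate_parents(cfg)
  hapZ <- materialize_haplotype(p$female, "chr02", 1)
  hapW <- materialize_haplotype(p$female, "chr02", 2)
  expect_equal(nchar(hapW) - nchar(hapZ), 5000)
  expect_equal(nchar(materialize_haplotype(p$male, "chr02", 2)), 20000)
  wi <- attr(p$truth, "w_interval")
  expect_identical(substr(hapW, wi$start + 1, wi$end), p$female$w_insert)
})

test_that("heterozygous site counts follow the stated binomial placement", {
  cfg <- sim_config(chrom_lengths = c(chr01 = 1e6),
                    w_locus = list(chrom = "chr01", pos = 5e5),
                    het_rate_p3 = 0.005, het_rate_p4 = 0,
                    shared_snp_rate = 0, hom_diff_rate = 0,
                    w_insert_len = 0, w_flank_len = 0, w_flank_snp_rate = 0,
                    emit_sequences = FALSE, seed = 101)
  p <- simulate_parents(cfg)
  n <- sum(p$truth$category == "p3het")
  env <- c(qbinom(0.005, 1e6, 0.005), qbinom(0.995, 1e6, 0.005))
  expect_gte(n, env[1])
  expect_lte(n, env[2])
})

test_that("F1 cross: counts, forced phenotypes, W transmission", {
  cfg <- small_cfg(n_f1 = 253, bulk_size = 50, emit_sequences = FALSE,
                   seed = 7)
  p <- simulate_parents(cfg)
  pop <- cross_f1(p, cfg)
  expect_length(pop, 253)
  sexg <- vapply(pop, `[[`, character(1), "sex_genotype")
  phen <- vapply(pop, `[[`, character(1), "phenotype")
  expect_true(all(phen[sexg == "ZZ"] == "male"))
  expect_true(all(phen[sexg == "ZW"] == "female")) # lability all zero
  expect_error(cross_f1(list(female = p$male, male = p$male), cfg),
               "ZW and one ZZ")
})

test_that("ZW phenotype frequencies follow the lability multinomial", {
  cfg <- small_cfg(n_f1 = 10000, bulk_size = 50, emit_sequences = FALSE,
                   lability = c(male = 0.1, monoecious = 0.05,
                                nonflowering = 0.05), seed = 8)
  p <- simulate_parents(cfg)
  pop <- cross_f1(p, cfg)
  sexg <- vapply(pop, `[[`, character(1), "sex_genotype")
  phen <- vapply(pop, `[[`, character(1), "phenotype")
  nzw <- sum(sexg == "ZW")
  env <- binom_envelope <- function(pr) c(qbinom(0.005, nzw, pr),
                                          qbinom(0.995, nzw, pr))
  probs <- c(female = 0.8, male = 0.1, monoecious = 0.05,
             nonflowering = 0.05)
  for (ph in names(probs)) {
    cnt <- sum(phen[sexg == "ZW"] == ph)
    e <- binom_envelope(probs[[ph]])
    expect_gte(cnt, e[1])
    expect_lte(cnt, e[2])
  }
  # W transmission itself: central 99% binomial interval
  e <- c(qbinom(0.005, 10000, 0.5), qbinom(0.995, 10000, 0.5))
  expect_gte(nzw, e[1]); expect_lte(nzw, e[2])
})

test_that("bulk pileups: counts sum to depth and honour genotypes", {
  cfg <- small_cfg(chrom_lengths = c(chr02 = 5000),
                   w_locus = list(chrom = "chr02", pos = 2500),
                   w_insert_len = 0, w_flank_len = 1000,
                   w_flank_snp_rate = 0.01, het_rate_p3 = 0,
                   het_rate_p4 = 0.01, shared_snp_rate = 0,
                   hom_diff_rate = 0, xover_rate = 0, n_f1 = 40,
                   bulk_size = 10, error_rate = 0, seed = 9)
  p <- simulate_parents(cfg)
  pop <- cross_f1(p, cfg)
  sexg <- vapply(pop, `[[`, character(1), "sex_genotype")
  zw <- bulk_members(pop, which(sexg == "ZW")[1:10])
  pu <- sample_bulk_pileup(zw, NULL, cfg)
  expect_equal(pu$A + pu$C + pu$G + pu$T, pu$depth)
  expect_error(sample_bulk_pileup(bulk_members(pop, integer(0)), NULL, cfg),
               "empty bulk")

  # fully W-linked site, all-ZW bulk, no errors, huge depth:
  # alternate fraction inside the exact 99% Binomial(depth, 0.5) envelope
  truth <- attr(pop, "truth")
  wsites <- which(truth$w_linked)
  pu2 <- sample_bulk_pileup(zw, NULL, cfg, depth = 1e5)
  i <- wsites[1]
  altc <- pu2[i, truth$alt[i]]
  d <- pu2$depth[i]
  expect_gte(altc, qbinom(0.005, d, 0.5))
  expect_lte(altc, qbinom(0.995, d, 0.5))

  # an all-homozygous-reference sample, no errors: alternate count 0
  # (male parent carries no W-linked alternate alleles)
  pum <- sample_parent_pileup(p$male, truth, NULL, cfg, depth = 50)
  alt_at_w <- mapply(function(j, a) pum[j, a], wsites, truth$alt[wsites])
  expect_true(all(alt_at_w == 0))
})

test_that("sequencing errors hit one specific other base at rate e/3", {
  cfg <- small_cfg(chrom_lengths = c(chr02 = 2000),
                   w_locus = list(chrom = "chr02", pos = 1000),
                   het_rate_p3 = 0.01, het_rate_p4 = 0, shared_snp_rate = 0,
                   hom_diff_rate = 0, w_insert_len = 0, w_flank_len = 0,
                   w_flank_snp_rate = 0, error_rate = 0.01, seed = 10)
  p <- simulate_parents(cfg)
  # male parent is homozygous reference at p3het sites: any non-reference
  # base there is error; one designated base ~ Binomial(depth, e/3)
  pu <- sample_parent_pileup(p$male, p$truth, NULL, cfg, depth = 2e5)
  i <- 1
  other <- setdiff(c("A", "C", "G", "T"), p$truth$ref[i])[1]
  cnt <- pu[i, other]
  d <- pu$depth[i]
  expect_gte(cnt, qbinom(0.005, d, 0.01 / 3))
  expect_lte(cnt, qbinom(0.995, d, 0.01 / 3))
})

test_that("shotgun reads are faithful substrings with Poisson yield", {
  set.seed(11)
  g <- setNames(paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
                      collapse = ""), "g1")
  reads <- sample_reads(g, depth = 30, read_len = 100, error_rate = 0)
  expect_true(all(nchar(reads$seq) == 100))
  total <- sum(nchar(reads$seq))
  lam <- 30 * 1e5
  expect_gte(total, qpois(0.005, lam / 100) * 100)
  expect_lte(total, qpois(0.995, lam / 100) * 100)
  # every read (or its reverse complement) is an exact substring
  for (i in sample(nrow(reads), 25)) {
    hit <- grepl(reads$seq[i], g, fixed = TRUE) ||
      grepl(revcomp(reads$seq[i]), g, fixed = TRUE)
    expect_true(hit)
  }
  expect_error(sample_reads(g, 1, read_len = 2e5), "read_len")
})

test_that("RAD digestion: coordinates, strand orientation, degenerate input", {
  expect_equal(nrow(digest_radtags(c(x = strrep("ACGT", 30)))), 0)
  # one PacI at offset 10, one NlaIII at offset 40 in a 60-bp sequence:
  # tag runs from the junction (18) to the end of the CATG site (44)
  s <- paste0(strrep("G", 10), "TTAATTAA", strrep("A", 22), "CATG",
              strrep("G", 16))
  expect_equal(nchar(s), 60)
  tags <- digest_radtags(c(x = s), tag_len = 95)
  fwd <- tags[tags$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$start, 18)
  expect_equal(fwd$end, 44)
  expect_identical(fwd$seq, substr(s, 19, 44))
  # property: every + tag is immediately preceded by the site; every - tag
  # immediately followed by its reverse complement
  set.seed(12)
  g <- c(r = paste(sample(c("A", "C", "G", "T"), 5e4, replace = TRUE,
                          prob = c(.3, .2, .2, .3)), collapse = ""))
  tt <- digest_radtags(g, tag_len = 60)
  for (i in seq_len(nrow(tt))) {
    if (tt$strand[i] == "+")
      expect_identical(unname(substr(g, tt$start[i] - 7, tt$start[i])),
                       "TTAATTAA")
    else
      expect_identical(unname(substr(g, tt$end[i] + 1, tt$end[i] + 8)),
                       revcomp("TTAATTAA"))
  }
})

test_that("same seed reproduces parents, cross and pileups byte-identically", {
  run <- function() {
    cfg <- small_cfg(chrom_lengths = c(chr02 = 20000),
                     w_locus = list(chrom = "chr02", pos = 10000),
                     w_insert_len = 1000, n_f1 = 10, bulk_size = 5, seed = 33)
    p <- simulate_parents(cfg)
    pop <- cross_f1(p, cfg)
    pu <- sample_bulk_pileup(bulk_members(pop, 1:5), NULL, cfg)
    list(p$truth, p$female$haplotypes, pu,
         vapply(pop, `[[`, character(1), "phenotype"))
  }
  expect_identical(run(), run())
})
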