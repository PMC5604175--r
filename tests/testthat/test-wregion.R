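test_that("reference combination counts contigs and resolves name clashes", {
  f <- c(ctg1 = "ACGTACGTAC", a = "AAAACCCCGG", b = "TTTTGGGGAA")
  m <- c(ctg1 = "ACGTACGTAC", x = "CCCCAAAATT", y = "GGGGTTTTCC",
         z = "ACACACACAC")
  cr <- combine_references(f, m)
  expect_length(cr$seqs, 7)
  expect_true(all(c("F|ctg1", "M|ctg1") %in% names(cr$seqs)))
  expect_equal(unname(cr$source[["F|ctg1"]]), "female-asm")
  expect_error(combine_references(character(0), m), "empty")
  # source labels round-trip through FASTA write/read
  tf <- tempfile(fileext = ".fa")
  write_fasta(cr$seqs, tf)
  back <- read_fasta(tf)
  expect_identical(back, cr$seqs)
})

test_that("mini-mapper: uniqueness, duplication, strand behaviour", {
  set.seed(30)
  a <- random_dna(4000)
  dup <- random_dna(500)
  ref <- c(c1 = paste0(a, dup), c2 = paste0(dup, random_dna(1000)))
  # read from the unique part of c1
  r1 <- substr(a, 101, 200)
  # read from the duplicated segment
  r2 <- substr(dup, 11, 110)
  aln <- map_reads(c(r1, r2, revcomp(r1)), ref)
  expect_equal(nrow(aln), 3)
  expect_true(aln$unique[aln$read == 1])
  expect_equal(aln$n_best[aln$read == 2], 2)
  expect_false(aln$unique[aln$read == 2])
  fwd <- aln[aln$read == 1, ]; rev <- aln[aln$read == 3, ]
  expect_equal(fwd$pos, rev$pos)
  expect_equal(fwd$pos, 100)
  expect_setequal(c(fwd$strand, rev$strand), c("+", "-"))
})

test_that("mapper agrees with the brute-force Hamming oracle", {
  set.seed(31)
  ref <- c(k1 = random_dna(6000), k2 = random_dna(4000))
  n <- 300
  src <- sample(1:2, n, replace = TRUE)
  start <- ifelse(src == 1, sample(5901, n, replace = TRUE),
                  sample(3901, n, replace = TRUE))
  reads <- substring(ref[src], start, start + 99)
  flip <- runif(n) < 0.5
  reads[flip] <- revcomp(reads[flip])
  aln <- map_reads(reads, ref, seed_len = 31, max_mismatch = 3)
  expect_equal(nrow(aln), n)
  chk <- zwmap:::cpp_scan_reads(
    reads, unname(ref), 3L,
    match(aln$contig, names(ref))[order(aln$read)],
    aln$pos[order(aln$read)],
    as.integer(aln$strand[order(aln$read)] == "-"))
  expect_equal(chk$best_mm, aln$mismatches[order(aln$read)])
  expect_equal(chk$n_best, aln$n_best[order(aln$read)])
  expect_true(all(chk$cand_ok))
})

test_that("specific regions: runs, boundaries and bulk-label symmetry", {
  aln_f <- data.frame(read = 1:3, contig = "c1", pos = c(0, 50, 100),
                      strand = "+", mismatches = 0, n_best = 1,
                      unique = TRUE, qwidth = 100)
  aln_m <- data.frame(read = 1, contig = "c1", pos = 300, strand = "+",
                      mismatches = 0, n_best = 1, unique = TRUE, qwidth = 50)
  ref <- c(c1 = strrep("A", 500))
  reg <- specific_regions(aln_f, aln_m, ref)
  f <- reg[reg$bulk == "female", ]
  expect_equal(nrow(f), 1)
  expect_equal(c(f$start, f$end), c(0, 200))
  m <- reg[reg$bulk == "male", ]
  expect_equal(c(m$start, m$end), c(300, 350))
  # a single other-bulk read splits the run when max_other_depth = 0
  aln_m2 <- rbind(aln_m, data.frame(read = 2, contig = "c1", pos = 80,
                                    strand = "+", mismatches = 0,
                                    n_best = 1, unique = TRUE, qwidth = 10))
  reg2 <- specific_regions(aln_f, aln_m2, ref)
  f2 <- reg2[reg2$bulk == "female", ]
  expect_equal(nrow(f2), 2)
  expect_equal(f2$start, c(0, 90))
  # ... and is tolerated when max_other_depth = 1
  reg3 <- specific_regions(aln_f, aln_m2, ref, max_other_depth = 1)
  expect_equal(nrow(reg3[reg3$bulk == "female", ]), 1)
  # symmetry: swapping the bulks swaps labels, identical coordinates
  swp <- specific_regions(aln_m, aln_f, ref)
  swf <- swp[swp$bulk == "male", ]
  expect_equal(swf[, c("start", "end")], f[, c("start", "end")],
               ignore_attr = TRUE)
  # non-unique self reads depress the uniqueness fraction below 0.9
  aln_f3 <- aln_f
  aln_f3$unique <- c(TRUE, FALSE, FALSE)
  aln_f3$n_best <- c(1, 2, 2)
  reg4 <- specific_regions(aln_f3, aln_m, ref)
  expect_true(all(reg4$end[reg4$bulk == "female"] <= 100))
})

test_that("N-statistic matches hand computations and degenerate input", {
  expect_equal(n_statistic(c(8, 5, 3, 2), 0.5), 5)
  expect_equal(n_statistic(c(8, 5, 3, 2), 0.2), 8)
  expect_equal(n_statistic(42, 0.9), 42)
  expect_error(n_statistic(numeric(0), 0.5), "empty")
})

test_that("specific-contig selection uses a strict length threshold", {
  reg <- data.frame(contig = c("a", "b", "c"), start = 0,
                    end = c(42, 43, 10), length = c(42, 43, 10),
                    bulk = "female")
  expect_setequal(select_specific_contigs(reg, min_fragment_bp = 42), "b")
  expect_equal(select_specific_contigs(reg[0, ]), character(0))
  # default threshold: N20 of the region lengths
  expect_setequal(select_specific_contigs(reg),
                  reg$contig[reg$length > n_statistic(reg$length, 0.2)])
})

test_that("anchoring places exact substrings and chains across N-gaps", {
  set.seed(32)
  target <- c(chr = random_dna(8000))
  ctg <- substr(target, 2001, 3000)
  anc <- anchor_contigs(c(q = ctg), target)
  expect_equal(nrow(anc), 1)
  expect_equal(anc$tstart, 2000)
  expect_equal(anc$tend, 3000)
  expect_equal(anc$matched_len, 1000)
  # contig with no shared sequence: no anchor
  expect_equal(nrow(anchor_contigs(c(q = random_dna(500)), target)), 0)
  # target N-gap: chain spans it, matched length excludes it
  left <- substr(target, 1001, 1400)
  right <- substr(target, 1401, 1800)
  gapped <- c(chrN = paste0(substr(target, 1, 1400), strrep("N", 1000),
                            substr(target, 1401, 8000)))
  ctg2 <- paste0(left, right) # contiguous 800 bp straddling the gap
  anc2 <- anchor_contigs(c(q2 = ctg2), gapped)
  expect_equal(nrow(anc2), 1)
  expect_equal(anc2$tend - anc2$tstart, 800 + 1000) # spans the gap
  expect_equal(anc2$matched_len, 800) # but excludes it
})

test_that("W-interval delineation: span, empty call, ZZ-bulk trimming", {
  anchors <- data.frame(contig = c("a", "b"), target = "chr",
                        tstart = c(1000, 5000), tend = c(2000, 6000),
                        qstart = 0, qend = 1000, strand = "+",
                        matched_len = 1000, n_chunks = 10)
  regions <- data.frame(contig = c("a", "b", "zz"),
                        start = c(100, 200, 0), end = c(300, 400, 50),
                        length = c(200, 200, 50), bulk = "female")
  call <- delineate_w_interval(anchors, regions)
  expect_equal(call$start, 1100)
  expect_equal(call$end, 5400)
  expect_setequal(call$contigs, c("a", "b"))
  # no anchored female-specific regions: empty call
  none <- delineate_w_interval(anchors, regions[regions$contig == "zz", ])
  expect_true(is.na(none$start))
  # a ZZ bulk can only narrow the interval
  zz <- data.frame(read = 1, contig = "chr", pos = 5100, strand = "+",
                   mismatches = 0, n_best = 1, unique = TRUE, qwidth = 400)
  trimmed <- delineate_w_interval(anchors, regions, zz,
                                  target_lengths = c(chr = 8000))
  expect_gte(trimmed$start, call$start)
  expect_lte(trimmed$end, call$end)
  expect_equal(trimmed$end, 1300)
})
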