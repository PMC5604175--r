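test_that("two-point statistics match the closed form and a naive oracle", {
  # n = 100 with 10 recombinants
  x <- rep(1, 100)
  y <- c(rep(1, 90), rep(0, 10))
  tp <- two_point(x, y)
  expect_equal(tp$rf, 0.1)
  expect_equal(tp$lod, 90 * log10(1.8) + 10 * log10(0.2), tolerance = 1e-12)
  expect_equal(tp$lod, 15.98483, tolerance = 1e-5)
  # identical vectors: rf 0, LOD n*log10(2)
  tp0 <- two_point(x, x)
  expect_equal(tp0$rf, 0)
  expect_equal(tp0$lod, 100 * log10(2), tolerance = 1e-12)
  # naive recombinant counting oracle on random vectors with missing calls
  set.seed(40)
  for (i in 1:20) {
    a <- sample(c(0, 1, NA), 80, replace = TRUE, prob = c(.45, .45, .1))
    b <- sample(c(0, 1, NA), 80, replace = TRUE, prob = c(.45, .45, .1))
    ok <- which(!is.na(a) & !is.na(b))
    if (!length(ok)) next
    r <- sum(a[ok] != b[ok])
    tp <- two_point(a, b)
    expect_equal(tp$n_informative, length(ok))
    expect_equal(tp$n_recombinant, r)
    # the matrix version agrees with the scalar version
    m <- rbind(a, b)
    tpm <- two_point_matrix(m)
    expect_equal(tpm$rf[1, 2], tp$rf)
    expect_equal(tpm$lod[1, 2], tp$lod, tolerance = 1e-12)
    expect_equal(tpm$lod_flipped[1, 2], tp$lod_flipped, tolerance = 1e-12)
  }
  expect_error(two_point(c(NA, 1), c(0, NA)), "informative")
})

test_that("segregation filter equals the exact central binomial interval", {
  # central 95% interval of Binomial(150, 0.5) is [63, 87]
  expect_true(segregation_filter(75, 150))
  expect_true(segregation_filter(63, 150))
  expect_true(segregation_filter(87, 150))
  expect_false(segregation_filter(60, 150))
  expect_false(segregation_filter(62, 150))
  expect_false(segregation_filter(88, 150))
  expect_error(segregation_filter(1, 0), "n must be")
})

test_that("SNP marker selection: band boundaries, calls and thinning", {
  n_pos <- 3
  # site 1: P1 index 0.2 (boundary), P2 index 1 -> eligible (P1 het)
  # site 2: P2 index 0.1 -> ineligible
  # site 3: eligible, 4 kb from site 1 on the same scaffold -> thinned
  p1 <- make_pileup("s1", c(1000, 2000, 5000), rep("A", 3),
                    A = c(16, 20, 10), G = c(4, 2, 10))
  p2 <- make_pileup("s1", c(1000, 2000, 5000), rep("A", 3),
                    G = c(20, 0, 0), A = c(0, 18, 20))
  f1 <- lapply(1:160, function(i) {
    het <- i %% 2 == 0 # exact 1:1 segregation
    make_pileup("s1", c(1000, 2000, 5000), rep("A", 3),
                A = if (het) c(3, 3, 3) else c(5, 5, 5),
                G = if (het) c(3, 3, 3) else c(0, 0, 0))
  })
  names(f1) <- sprintf("f1_%03d", seq_along(f1))
  ms <- select_snp_markers(p1, p2, f1, spacing_bp = 1e4)
  expect_equal(nrow(ms$info), 1) # sites 1 and 3 in one 10-kb bin; 2 dropped
  expect_true(ms$info$pos %in% c(1000, 5000))
  # wider spacing bins keep both eligible sites
  ms2 <- select_snp_markers(p1, p2, f1, spacing_bp = 1e3)
  expect_equal(nrow(ms2$info), 2)
})

test_that("PA marker call rules and informativeness threshold", {
  set.seed(41)
  n_ind <- 130
  # marker 1: clean 1:1 segregation, all informative
  d1 <- ifelse(runif(n_ind) < 0.5, 5, 0)
  # marker 2: depth 2 individuals are missing -> informative 119 < 120
  d2 <- d1; d2[1:11] <- 2
  # marker 3: informative exactly 120 -> retained
  d3 <- d1; d3[1:10] <- 1
  info <- data.frame(id = c("m1", "m2", "m3"), scaffold = "s",
                     pos = c(0, 20000, 40000), parent = "P1")
  ms <- select_pa_markers(rbind(d1, d2, d3), info)
  expect_setequal(ms$info$id, c("m1", "m3"))
  expect_equal(unname(ms$info$n_informative[ms$info$id == "m3"]), 120)
  calls <- ms$calls["m1", ]
  expect_true(all(calls[d1 == 5] == 1))
  expect_true(all(calls[d1 == 0] == 0))
})

test_that("scaffold splitting cuts at the integer midpoint and partitions", {
  # markers at 100 kb and 300 kb with rf 0.4 between them
  set.seed(42)
  a <- rep(c(0, 1), 50)
  b <- a; flip <- sample(100, 40); b[flip] <- 1 - b[flip]
  calls <- rbind(a, b)
  rownames(calls) <- c("mA", "mB")
  ms <- marker_set(data.frame(id = c("mA", "mB"), scaffold = "s7",
                              pos = c(100000, 300000)), calls)
  sp <- split_scaffolds(ms, c(s7 = 500000))
  expect_equal(nrow(sp$pieces), 2)
  expect_equal(sp$pieces$end[1], 200000)
  expect_equal(sp$pieces$start[2], 200000)
  # pieces partition the scaffold exactly
  expect_equal(sp$pieces$start[1], 0)
  expect_equal(sp$pieces$end[2], 500000)
  expect_equal(sp$ms$info$pos, c(100000, 100000)) # piece-relative
  # low rf: scaffold intact
  ms2 <- marker_set(data.frame(id = c("mA", "mB"), scaffold = "s7",
                               pos = c(100000, 300000)), rbind(a, a))
  sp2 <- split_scaffolds(ms2, c(s7 = 500000))
  expect_equal(nrow(sp2$pieces), 1)
  expect_equal(sp2$pieces$piece, "s7")
})

test_that("repulsion conversion flips complements and terminates", {
  set.seed(43)
  n <- 100
  base <- rbinom(n, 1, 0.5)
  near <- base; near[sample(n, 10)] <- 1 - near[sample(n, 10)]
  rep1 <- 1 - near # repulsion-coded neighbour, raw rf ~ 0.9
  calls <- rbind(base, near, rep1)
  rownames(calls) <- c("k1", "k2", "k3")
  ms <- marker_set(data.frame(id = rownames(calls), scaffold = "s",
                              pos = c(0, 1e4, 2e4)), calls)
  raw <- two_point(calls["k1", ], calls["k3", ])
  expect_gt(raw$rf, 0.5)
  conv <- convert_repulsion(ms)
  tp <- two_point(conv$calls["k1", ], conv$calls["k3", ])
  expect_equal(tp$rf, 1 - raw$rf) # complement arithmetic
  expect_lt(tp$rf, 0.5)
  expect_equal(sort(unique(conv$info$phase)), c("coupling", "repulsion"))
  # post-state: no pair in repulsion at LOD >= 3
  tpm <- two_point_matrix(conv$calls)
  bad <- tpm$rf > 0.5 & tpm$lod_flipped >= 3
  diag(bad) <- FALSE
  expect_false(any(bad))
  # involution: complementing twice restores the original calls
  expect_identical(1 - (1 - calls), calls)
})

test_that("grouping recovers chromosomes; Haldane distances are exact", {
  set.seed(44)
  n <- 200
  c1 <- sim_bc_markers(n, c(0, 10, 20, 30, 40))
  c2 <- sim_bc_markers(n, c(0, 12, 25, 37, 50))
  calls <- rbind(c1, c2)
  rownames(calls) <- sprintf("m%02d", 1:10)
  info <- data.frame(id = rownames(calls),
                     scaffold = rep(c("scafA", "scafB"), each = 5),
                     pos = rep(seq(0, 4e5, 1e5), 2))
  ms <- marker_set(info, calls)
  lm <- build_groups_and_order(ms)
  expect_length(lm, 2)
  membership <- lapply(lm, function(g) sort(g$id))
  expect_setequal(
    vapply(membership, paste, character(1), collapse = ","),
    c(paste(sprintf("m%02d", 1:5), collapse = ","),
      paste(sprintf("m%02d", 6:10), collapse = ",")))
  expect_true(all(vapply(lm, function(g) !is.unsorted(g$cM), logical(1))))
  # rf 0.1 between adjacent markers: Haldane gives -50*ln(0.8) = 11.157 cM
  a <- rep(c(0, 1), 50)
  b <- a; b[seq(1, 100, 10)] <- 1 - b[seq(1, 100, 10)]
  cc <- a; cc[seq(2, 100, 10)] <- 1 - cc[seq(2, 100, 10)]
  m3 <- rbind(a, b, cc)
  rownames(m3) <- c("x1", "x2", "x3")
  ms3 <- marker_set(data.frame(id = rownames(m3), scaffold = "s",
                               pos = c(0, 1e4, 2e4)), m3)
  lm3 <- build_groups_and_order(ms3, rf_max = 0.3)
  d <- diff(lm3[[1]]$cM)
  expect_equal(d[1], -50 * log(1 - 2 * 0.1), tolerance = 1e-9)
  # 2-marker cluster is discarded
  lm2 <- build_groups_and_order(
    marker_set(data.frame(id = c("y1", "y2"), scaffold = "s",
                          pos = c(0, 1)), rbind(a, a)))
  expect_length(lm2, 0)
})

test_that("map merging pairs by shared scaffolds with documented tie-break", {
  lg <- function(ids, scafs) data.frame(id = ids, scaffold = scafs,
                                        pos = 0, cM = seq_along(ids))
  map1 <- structure(list(LG1 = lg(c("a1", "a2", "a3"), c("s1", "s2", "s3")),
                         LG2 = lg(c("b1", "b2", "b3"), c("s4", "s5", "s6"))),
                    class = "linkage_map")
  map2 <- structure(list(LG1 = lg(c("c1", "c2", "c3"), c("s4", "s5", "s7")),
                         LG2 = lg(c("d1", "d2", "d3"), c("s2", "s1", "s8"))),
                    class = "linkage_map")
  merged <- merge_maps(map1, map2)
  expect_length(merged, 2)
  m1 <- merged[[which(vapply(merged, `[[`, character(1), "id") == "chr1")]]
  expect_equal(m1$lg_p2, "LG2")
  # P1 order wins conflicts; P2-only scaffold s8 inserted after its
  # nearest shared predecessor (s1) in P2 order
  expect_equal(m1$scaffolds, c("s1", "s8", "s2", "s3"))
  # every scaffold appears exactly once across chromosomes
  all_scafs <- unlist(lapply(merged, `[[`, "scaffolds"))
  expect_equal(anyDuplicated(all_scafs), 0)
  expect_setequal(all_scafs, paste0("s", 1:8))
  # tie in shared counts resolves to the lower-numbered second-map group
  map2b <- structure(list(LG1 = lg("e1", "s1"), LG2 = lg("f1", "s2")),
                     class = "linkage_map")
  merged2 <- merge_maps(map1["LG1"], map2b)
  expect_equal(merged2[[1]]$lg_p2, "LG1")
})

test_that("pseudo-molecules: lengths, orientation, AGP round trip", {
  set.seed(45)
  s1 <- random_dna(10000); s2 <- random_dna(20000)
  pm <- build_pseudomolecules(list(chr1 = c("a", "b")),
                              c(a = s1, b = s2), gap_n = 1000)
  expect_equal(nchar(pm$seqs[["chr1"]]), 31000)
  # single piece: unchanged
  pm1 <- build_pseudomolecules(list(chr1 = "a"), c(a = s1))
  expect_identical(unname(pm1$seqs[["chr1"]]), s1)
  # reverse orientation inserts the reverse complement
  spec <- list(chr1 = data.frame(scaffold = c("a", "b"),
                                 orientation = c("+", "-")))
  pm2 <- build_pseudomolecules(spec, c(a = s1, b = s2), gap_n = 500)
  expect_identical(substr(pm2$seqs[["chr1"]], 10501, 30500), revcomp(s2))
  # AGP round trip reproduces piece coordinates and sequences
  agp <- pm2$agp
  for (i in which(agp$type == "W")) {
    sub <- substr(pm2$seqs[[agp$object[i]]], agp$object_beg[i],
                  agp$object_end[i])
    src <- c(a = s1, b = s2)[[agp$component[i]]]
    if (agp$orientation[i] == "-") src <- revcomp(src)
    expect_identical(sub, src)
  }
  expect_error(build_pseudomolecules(list(chr1 = "zz"), c(a = s1)),
               "missing scaffold")
})
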