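#' Place RAD tags on scaffolds and apply mapping filters
#'
#' Tags are placed with the mini-mapper; multi-mapping or unmappable tags are
#' discarded (the MAPQ < 60 analog; the mapper allows no indels, so
#' indel-containing alignments cannot occur), and positions supported by a
#' single tag are discarded.
#'
#' @param tags data.frame with `seq` (and optionally `id`) or character
#'   vector of tag sequences.
#' @param scaffolds named character vector of scaffold sequences.
#' @param seed_len,max_mismatch mapper parameters.
#' @param min_tags_per_pos minimum tags sharing a position (default 2).
#' @return data.frame of retained placements: id, scaffold, pos, strand.
#' @export
align_tags <- function(tags, scaffolds, seed_len = 31, max_mismatch = 3,
                       min_tags_per_pos = 2) {
  seqs <- if (is.data.frame(tags)) tags$seq else tags
  ids <- if (is.data.frame(tags) && !is.null(tags$id)) tags$id else
    sprintf("tag%05d", seq_along(seqs))
  aln <- map_reads(seqs, scaffolds, seed_len, max_mismatch)
  aln <- aln[aln$unique, , drop = FALSE]
  key <- paste(aln$contig, aln$pos)
  n_at <- table(key)
  aln <- aln[n_at[key] >= min_tags_per_pos, , drop = FALSE]
  data.frame(id = ids[aln$read], scaffold = aln$contig, pos = aln$pos,
             strand = aln$strand, stringsAsFactors = FALSE)
}

#' Binomial segregation filter for 1:1 markers
#'
#' Keeps a marker iff its heterozygote count lies in the exact central
#' (1 - alpha) interval of Binomial(n, 1/2), both bounds inclusive.
#'
#' @param n_het heterozygote count(s).
#' @param n informative individuals.
#' @param alpha significance level (default 0.05).
#' @return logical vector (keep).
#' @export
segregation_filter <- function(n_het, n, alpha = 0.05) {
  if (any(n < 1)) stop("n must be >= 1")
  lo <- qbinom(alpha / 2, n, 0.5)
  hi <- qbinom(1 - alpha / 2, n, 0.5)
  n_het >= lo & n_het <= hi
}

# One marker per spacing interval, preferring most informative calls then
# highest depth. info needs scaffold, pos, n_informative, depth columns.
thin_markers <- function(info, spacing_bp) {
  bin <- paste(info$scaffold, floor(info$pos / spacing_bp))
  ord <- order(bin, -info$n_informative, -info$depth, info$pos)
  keep_first <- !duplicated(bin[ord])
  sort(ord[keep_first])
}

#' Select SNP-type pseudo-testcross markers
#'
#' Positions with a biallelic SNP-index inside `band` in one parent and
#' exactly 0 or 1 in the other are parent-specific heterozygous markers.
#' F1 calls: alternate allele observed => heterozygous; no alternate with
#' coverage => homozygous; no coverage => missing. Markers failing the 1:1
#' segregation filter are dropped; finally one marker per `spacing_bp` is
#' kept (most informative F1, then deepest).
#'
#' @param pileup_p1,pileup_p2 parent pileups at placed-tag positions.
#' @param f1_pileups list of per-individual pileups at the same positions.
#' @param band inclusive heterozygous band (default `c(0.2, 0.8)`).
#' @param spacing_bp thinning interval (default 10 kb).
#' @param alpha segregation-filter level (default 0.05).
#' @return a `marker_set`: list(info, calls) where calls is a markers x
#'   individuals matrix (1 het, 0 hom, NA missing).
#' @export
select_snp_markers <- function(pileup_p1, pileup_p2, f1_pileups,
                               band = c(0.2, 0.8), spacing_bp = 1e4,
                               alpha = 0.05) {
  key1 <- paste(pileup_p1$chrom, pileup_p1$pos)
  key2 <- paste(pileup_p2$chrom, pileup_p2$pos)
  common <- intersect(key1, key2)
  p1 <- pileup_p1[match(common, key1), , drop = FALSE]
  p2 <- pileup_p2[match(common, key2), , drop = FALSE]
  n <- nrow(p1)
  ref_i <- match(p1$ref, BASES)
  cnt1 <- as.matrix(p1[, BASES]); cnt2 <- as.matrix(p2[, BASES])
  nonref1 <- cnt1; nonref1[cbind(seq_len(n), ref_i)] <- -1L
  alt <- BASES[max.col(nonref1, ties.method = "first")]
  altc1 <- base_count(p1, alt); refc1 <- cnt1[cbind(seq_len(n), ref_i)]
  altc2 <- base_count(p2, alt); refc2 <- cnt2[cbind(seq_len(n), ref_i)]
  i1 <- ifelse(refc1 + altc1 > 0, altc1 / (refc1 + altc1), NA_real_)
  i2 <- ifelse(refc2 + altc2 > 0, altc2 / (refc2 + altc2), NA_real_)
  p1_het <- !is.na(i1) & i1 >= band[1] & i1 <= band[2] &
    !is.na(i2) & (i2 == 0 | i2 == 1)
  p2_het <- !is.na(i2) & i2 >= band[1] & i2 <= band[2] &
    !is.na(i1) & (i1 == 0 | i1 == 1)
  sel <- which(p1_het | p2_het)
  if (!length(sel)) return(empty_marker_set())
  info <- data.frame(id = paste0("snp_", p1$chrom[sel], "_", p1$pos[sel]),
                     scaffold = p1$chrom[sel], pos = p1$pos[sel],
                     parent = ifelse(p1_het[sel], "P1", "P2"), type = "SNP",
                     ref = p1$ref[sel], alt = alt[sel],
                     phase = "unknown", stringsAsFactors = FALSE)
  keysel <- common[sel]
  calls <- vapply(f1_pileups, function(pu) {
    kk <- paste(pu$chrom, pu$pos)
    m <- match(keysel, kk)
    a <- base_count(pu[m, , drop = FALSE], info$alt)
    d <- pu$depth[m]
    ifelse(is.na(d) | d == 0, NA_real_, as.numeric(a > 0))
  }, numeric(length(sel)))
  calls <- matrix(calls, nrow = length(sel),
                  dimnames = list(info$id, names(f1_pileups)))
  finish_marker_set(info, calls, alpha, spacing_bp)
}

#' Select presence/absence (dominant) pseudo-testcross markers
#'
#' For tag positions private to one parent's heterozygous haplotype, F1
#' individuals are called from tag depth: depth >= `min_het_depth` =>
#' heterozygous, depth 0 => homozygous, otherwise missing. Markers with
#' fewer than `min_informative` called individuals are dropped, then the
#' segregation filter and thinning are applied as for SNP markers.
#'
#' @param f1_depths markers x individuals matrix of tag depths.
#' @param info data.frame with id, scaffold, pos, parent for each row of
#'   `f1_depths`.
#' @param min_het_depth depth called heterozygous (default 3).
#' @param min_informative minimum called individuals (default 120).
#' @param spacing_bp,alpha as in [select_snp_markers()].
#' @return a `marker_set`.
#' @export
select_pa_markers <- function(f1_depths, info, min_het_depth = 3,
                              min_informative = 120, spacing_bp = 1e4,
                              alpha = 0.05) {
  calls <- ifelse(f1_depths >= min_het_depth, 1,
                  ifelse(f1_depths == 0, 0, NA))
  rownames(calls) <- info$id
  info$type <- "PA"
  info$phase <- "unknown"
  inf_n <- rowSums(!is.na(calls))
  keep <- inf_n >= min_informative
  info <- info[keep, , drop = FALSE]
  calls <- calls[keep, , drop = FALSE]
  if (!nrow(info)) return(empty_marker_set())
  finish_marker_set(info, calls, alpha, spacing_bp)
}

empty_marker_set <- function() {
  structure(list(info = data.frame(), calls = matrix(numeric(0), 0, 0)),
            class = "marker_set")
}

finish_marker_set <- function(info, calls, alpha, spacing_bp) {
  info$n_informative <- rowSums(!is.na(calls))
  info$depth <- info$depth %||% info$n_informative
  keep <- segregation_filter(rowSums(calls == 1, na.rm = TRUE),
                             pmax(info$n_informative, 1L), alpha) &
    info$n_informative >= 1
  info <- info[keep, , drop = FALSE]
  calls <- calls[keep, , drop = FALSE]
  if (nrow(info)) {
    sel <- thin_markers(info, spacing_bp)
    info <- info[sel, , drop = FALSE]
    calls <- calls[sel, , drop = FALSE]
  }
  rownames(info) <- NULL
  structure(list(info = info, calls = calls), class = "marker_set")
}

#' Build a marker set directly from genotype calls
#'
#' @param info data.frame: id, scaffold, pos (0-based bp) per marker.
#' @param calls markers x individuals matrix (1 het, 0 hom, NA).
#' @return a `marker_set`.
#' @export
marker_set <- function(info, calls) {
  stopifnot(nrow(info) == nrow(calls))
  info$type <- info$type %||% "SNP"
  info$parent <- info$parent %||% "P1"
  info$phase <- "unknown"
  info$n_informative <- rowSums(!is.na(calls))
  rownames(calls) <- info$id
  structure(list(info = info, calls = calls), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat("marker_set:", nrow(x$info), "markers x", ncol(x$calls),
      "individuals\n")
  invisible(x)
}

#' Two-point recombination fraction and LOD (backcross model)
#'
#' Informative individuals are those called in both markers; het-het and
#' hom-hom pairs score parental, the rest recombinant. LOD is the backcross
#' two-point statistic n_par*log10(2(1-rf)) + n_rec*log10(2*rf), with the
#' 0*log(0) terms dropped.
#'
#' @param x,y genotype call vectors (1/0/NA).
#' @return list: n_informative, n_recombinant, rf, lod, lod_flipped
#'   (the same statistic on complemented coding, used for repulsion pairs).
#' @export
two_point <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 1) stop("no shared informative individuals")
  r <- sum(x[ok] != y[ok])
  list(n_informative = n, n_recombinant = r, rf = r / n,
       lod = lod_backcross(n, r), lod_flipped = lod_backcross(n, n - r))
}

lod_backcross <- function(n, r) {
  rf <- r / n
  lod <- 0
  if (n - r > 0) lod <- lod + (n - r) * log10(2 * (1 - rf))
  if (r > 0) lod <- lod + r * log10(2 * rf)
  lod
}

#' All pairwise two-point statistics of a marker set
#'
#' @param calls markers x individuals call matrix.
#' @return list of matrices: n (informative), r (recombinant), rf, lod,
#'   lod_flipped.
#' @export
two_point_matrix <- function(calls) {
  obs <- !is.na(calls)
  H <- (calls == 1) & obs; H[is.na(H)] <- FALSE
  O <- (calls == 0) & obs; O[is.na(O)] <- FALSE
  mode(H) <- "numeric"; mode(O) <- "numeric"
  n <- tcrossprod(obs * 1)
  r <- tcrossprod(H, O) + tcrossprod(O, H)
  rf <- ifelse(n > 0, r / n, NA_real_)
  safelog <- function(m) ifelse(m > 0, log10(m), 0)
  lod <- (n - r) * safelog(2 * (1 - rf)) + r * safelog(2 * rf)
  rr <- n - r
  rff <- ifelse(n > 0, rr / n, NA_real_)
  lodf <- (n - rr) * safelog(2 * (1 - rff)) + rr * safelog(2 * rff)
  list(n = n, r = r, rf = rf, lod = lod, lod_flipped = lodf)
}

#' Split scaffolds where the recombination fraction jumps
#'
#' Scanning placed markers in coordinate order, a cut is placed at the
#' integer midpoint between the first adjacent pair whose rf exceeds the
#' threshold; the scan restarts after the cut. In `"anchor"` mode rf is
#' measured against the segment's initial marker instead of the previous
#' marker.
#'
#' @param ms a `marker_set`.
#' @param scaffold_lengths named lengths (bp) of the scaffolds.
#' @param rf_threshold cut threshold (default 0.25).
#' @param mode "adjacent" (default) or "anchor".
#' @return list: `pieces` (data.frame scaffold, piece, start, end),
#'   `markers` (info with piece ids and piece-relative positions), `ms`
#'   (marker_set with scaffold column replaced by piece ids).
#' @export
split_scaffolds <- function(ms, scaffold_lengths, rf_threshold = 0.25,
                            mode = c("adjacent", "anchor")) {
  mode <- match.arg(mode)
  info <- ms$info
  pieces <- list(); assign_piece <- character(nrow(info))
  newpos <- info$pos
  for (sc in unique(info$scaffold)) {
    idx <- which(info$scaffold == sc)
    idx <- idx[order(info$pos[idx])]
    L <- scaffold_lengths[[sc]]
    cuts <- integer(0)
    if (length(idx) >= 2) {
      anchor <- 1L
      i <- 1L
      while (i < length(idx)) {
        a <- if (mode == "adjacent") idx[i] else idx[anchor]
        b <- idx[i + 1L]
        tp <- two_point(ms$calls[a, ], ms$calls[b, ])
        if (tp$rf > rf_threshold) {
          cuts <- c(cuts, (info$pos[idx[i]] + info$pos[b]) %/% 2L)
          anchor <- i + 1L
        }
        i <- i + 1L
      }
    }
    bounds <- c(0L, cuts, L)
    for (p in seq_len(length(bounds) - 1L)) {
      pid <- if (length(bounds) == 2L) sc else paste0(sc, ".", p)
      pieces[[length(pieces) + 1L]] <- data.frame(
        scaffold = sc, piece = pid, start = bounds[p], end = bounds[p + 1L],
        stringsAsFactors = FALSE)
      inpiece <- idx[info$pos[idx] >= bounds[p] &
                       info$pos[idx] < bounds[p + 1L]]
      assign_piece[inpiece] <- pid
      newpos[inpiece] <- info$pos[inpiece] - bounds[p]
    }
  }
  pieces <- do.call(rbind, pieces)
  info$piece <- assign_piece
  info$piece_pos <- newpos
  ms2 <- ms
  ms2$info <- info
  ms2$info$scaffold_orig <- ms2$info$scaffold
  ms2$info$scaffold <- info$piece
  ms2$info$pos <- newpos
  list(pieces = pieces, markers = info, ms = ms2)
}

#' Convert repulsion-phase markers by call complementation
#'
#' Iterating LOD thresholds in schedule order (high to low), markers whose
#' rf to the coupled majority exceeds 0.5 with flipped-coding LOD at or
#' above the threshold have their calls complemented. Within each connected
#' component (edges = pairs informative at the threshold) markers are
#' two-coloured by BFS (repulsion edge = opposite colour); the larger colour
#' class keeps its phase.
#'
#' @param ms a `marker_set`.
#' @param lod_schedule decreasing LOD thresholds (default `c(10, 5, 3)`).
#' @return the `marker_set` with phased calls and `phase` set to
#'   "coupling"/"repulsion" (repulsion = calls were complemented).
#' @export
convert_repulsion <- function(ms, lod_schedule = c(10, 5, 3)) {
  calls <- ms$calls
  flipped <- rep(FALSE, nrow(calls))
  for (thr in lod_schedule) {
    repeat {
      tp <- two_point_matrix(calls)
      m <- nrow(calls)
      coup <- tp$rf < 0.5 & tp$lod >= thr
      repl <- tp$rf > 0.5 & tp$lod_flipped >= thr
      diag(coup) <- FALSE; diag(repl) <- FALSE
      if (!any(repl)) break
      adj <- coup | repl
      colr <- rep(NA_integer_, m)
      for (s in seq_len(m)) {
        if (!is.na(colr[s]) || !any(adj[s, ])) next
        colr[s] <- 0L
        queue <- s
        while (length(queue)) {
          v <- queue[1]; queue <- queue[-1]
          nb <- which(adj[v, ])
          for (w in nb) {
            want <- if (repl[v, w]) 1L - colr[v] else colr[v]
            if (is.na(colr[w])) { colr[w] <- want; queue <- c(queue, w) }
          }
        }
      }
      to_flip <- logical(m)
      seen <- rep(FALSE, m)
      for (s in seq_len(m)) {
        if (seen[s] || is.na(colr[s])) next
        comp <- s
        queue <- s; seen[s] <- TRUE
        while (length(queue)) {
          v <- queue[1]; queue <- queue[-1]
          nb <- which(adj[v, ] & !seen)
          seen[nb] <- TRUE
          comp <- c(comp, nb)
          queue <- c(queue, nb)
        }
        n0 <- sum(colr[comp] == 0L); n1 <- sum(colr[comp] == 1L)
        minority <- if (n1 > n0) 0L else 1L
        to_flip[comp[colr[comp] == minority]] <- TRUE
      }
      if (!any(to_flip)) break
      calls[to_flip, ] <- 1 - calls[to_flip, ]
      flipped[to_flip] <- !flipped[to_flip]
    }
  }
  ms$calls <- calls
  ms$info$phase <- ifelse(flipped, "repulsion", "coupling")
  ms
}

# Union-find
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Group phased markers and order them within linkage groups
#'
#' Single-linkage grouping on edges with LOD > `lod_min` and rf < `rf_max`;
#' groups smaller than `min_size` are discarded. Within a group, markers are
#' ordered by greedy nearest-neighbour seriation seeded at the marker with
#' the largest mean rf to the rest (a terminal marker); cM positions
#' accumulate the map function over adjacent rf values.
#'
#' @param ms a phased `marker_set`.
#' @param lod_min,rf_max linkage edge thresholds (defaults 3 and 0.25).
#' @param min_size minimum markers per group (default 3).
#' @param map_fun "haldane" (default) or "kosambi".
#' @return list of class `linkage_map`: each element a data.frame
#'   (id, scaffold, pos, cM) in map order.
#' @export
build_groups_and_order <- function(ms, lod_min = 3, rf_max = 0.25,
                                   min_size = 3,
                                   map_fun = c("haldane", "kosambi")) {
  map_fun <- match.arg(map_fun)
  tp <- two_point_matrix(ms$calls)
  m <- nrow(ms$calls)
  edge <- tp$lod > lod_min & tp$rf < rf_max & tp$n > 0
  diag(edge) <- FALSE
  parent <- seq_len(m)
  for (i in seq_len(m)) for (j in which(edge[i, ] & seq_len(m) > i)) {
    ri <- uf_find(parent, i); rj <- uf_find(parent, j)
    if (ri != rj) parent[rj] <- ri
  }
  root <- vapply(seq_len(m), function(i) uf_find(parent, i), integer(1))
  groups <- split(seq_len(m), root)
  groups <- groups[lengths(groups) >= min_size]
  d_fun <- if (map_fun == "haldane") {
    function(rf) -50 * log(1 - 2 * pmin(rf, 0.499))
  } else {
    function(rf) 25 * log((1 + 2 * pmin(rf, 0.499)) /
                            (1 - 2 * pmin(rf, 0.499)))
  }
  lgs <- list()
  for (g in groups) {
    rf <- tp$rf[g, g, drop = FALSE]
    k <- length(g)
    ord <- if (k == 1) 1L else {
      start <- which.max(rowMeans(rf, na.rm = TRUE))
      path <- start
      left <- setdiff(seq_len(k), start)
      while (length(left)) {
        nxt <- left[which.min(rf[path[length(path)], left])]
        path <- c(path, nxt)
        left <- setdiff(left, nxt)
      }
      path
    }
    gi <- g[ord]
    adj_rf <- if (k > 1)
      tp$rf[cbind(gi[-k], gi[-1])] else numeric(0)
    cm <- cumsum(c(0, d_fun(adj_rf)))
    lgs[[length(lgs) + 1L]] <- data.frame(
      id = ms$info$id[gi], scaffold = ms$info$scaffold[gi],
      pos = ms$info$pos[gi], cM = cm, stringsAsFactors = FALSE)
  }
  # larger groups first, stable ids
  if (length(lgs)) {
    lgs <- lgs[order(-vapply(lgs, nrow, integer(1)))]
    names(lgs) <- paste0("LG", seq_along(lgs))
  }
  structure(lgs, class = "linkage_map")
}

#' Merge two parental linkage maps into chromosomes
#'
#' Linkage-group pairs sharing the largest number of scaffolds are combined
#' greedily (ties: lower-numbered second-map group). Scaffold order follows
#' the first map; scaffolds present only in the second map are inserted
#' after their nearest shared predecessor in the second map's order.
#' Chromosome ids follow the first map's numbering.
#'
#' @param map_p1,map_p2 `linkage_map`s whose entries carry scaffold columns.
#' @return list of merged chromosomes: each a list(id, scaffolds, lg_p1,
#'   lg_p2).
#' @export
merge_maps <- function(map_p1, map_p2) {
  scafs1 <- lapply(map_p1, function(lg) unique(lg$scaffold))
  scafs2 <- lapply(map_p2, function(lg) unique(lg$scaffold))
  n1 <- length(scafs1); n2 <- length(scafs2)
  shared <- matrix(0L, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2))
    shared[i, j] <- length(intersect(scafs1[[i]], scafs2[[j]]))
  pairs <- list()
  avail1 <- rep(TRUE, n1); avail2 <- rep(TRUE, n2)
  repeat {
    sub <- shared
    sub[!avail1, ] <- -1L
    sub[, !avail2] <- -1L
    if (all(sub <= 0)) break
    best <- max(sub)
    hit <- which(sub == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    pairs[[length(pairs) + 1L]] <- c(i, j)
    avail1[i] <- FALSE; avail2[j] <- FALSE
  }
  chroms <- list()
  for (p in pairs) {
    i <- p[1]; j <- p[2]
    ord1 <- scafs1[[i]]
    ord2 <- scafs2[[j]]
    extra <- setdiff(ord2, ord1)
    merged <- ord1
    for (sc in extra) {
      k <- match(sc, ord2)
      pred <- rev(ord2[seq_len(k - 1)])
      anchor <- pred[pred %in% merged][1]
      at <- if (is.na(anchor)) 0L else match(anchor, merged)
      merged <- append(merged, sc, after = at)
    }
    chroms[[length(chroms) + 1L]] <- list(
      id = paste0("chr", i), scaffolds = merged,
      lg_p1 = names(map_p1)[i], lg_p2 = names(map_p2)[j])
  }
  for (i in which(avail1))
    chroms[[length(chroms) + 1L]] <- list(
      id = paste0("chr", i), scaffolds = scafs1[[i]],
      lg_p1 = names(map_p1)[i], lg_p2 = NA_character_)
  for (j in which(avail2))
    chroms[[length(chroms) + 1L]] <- list(
      id = paste0("chrP2_", j), scaffolds = scafs2[[j]],
      lg_p1 = NA_character_, lg_p2 = names(map_p2)[j])
  chroms
}

#' Build pseudo-molecules from ordered, oriented scaffold pieces
#'
#' Pieces are concatenated in order (reverse-complemented where flagged) and
#' joined by runs of `gap_n` Ns; an AGP-style placement table is emitted.
#'
#' @param chrom_scaffolds list: chromosome id -> data.frame(scaffold,
#'   orientation ("+"/"-")), or a plain character vector (all "+").
#' @param scaffold_seqs named character vector of scaffold sequences.
#' @param gap_n gap length between pieces (default 1000).
#' @return list: `seqs` (named character vector of pseudo-molecules), `agp`
#'   (data.frame object, object_beg, object_end, part, type, component,
#'   component_beg, component_end, orientation; 1-based inclusive like AGP).
#' @export
build_pseudomolecules <- function(chrom_scaffolds, scaffold_seqs,
                                  gap_n = 1000) {
  seqs <- character(0); agp <- list()
  for (chrom in names(chrom_scaffolds)) {
    spec <- chrom_scaffolds[[chrom]]
    if (!is.data.frame(spec))
      spec <- data.frame(scaffold = spec, orientation = "+",
                         stringsAsFactors = FALSE)
    missing <- setdiff(spec$scaffold, names(scaffold_seqs))
    if (length(missing))
      stop("missing scaffold sequence: ", paste(missing, collapse = ", "))
    parts <- character(0)
    at <- 0L; partno <- 0L
    for (i in seq_len(nrow(spec))) {
      s <- scaffold_seqs[[spec$scaffold[i]]]
      if (spec$orientation[i] == "-") s <- revcomp(s)
      if (i > 1) {
        partno <- partno + 1L
        agp[[length(agp) + 1L]] <- data.frame(
          object = chrom, object_beg = at + 1L, object_end = at + gap_n,
          part = partno, type = "U", component = "gap",
          component_beg = 1L, component_end = gap_n, orientation = "na",
          stringsAsFactors = FALSE)
        parts <- c(parts, strrep("N", gap_n))
        at <- at + gap_n
      }
      partno <- partno + 1L
      agp[[length(agp) + 1L]] <- data.frame(
        object = chrom, object_beg = at + 1L, object_end = at + nchar(s),
        part = partno, type = "W", component = spec$scaffold[i],
        component_beg = 1L, component_end = nchar(s),
        orientation = spec$orientation[i], stringsAsFactors = FALSE)
      parts <- c(parts, s)
      at <- at + nchar(s)
    }
    seqs[chrom] <- paste(parts, collapse = "")
  }
  list(seqs = seqs, agp = do.call(rbind, agp))
}
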