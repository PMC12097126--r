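# Regulatory context of alternative UTRs: cUTR/aUTR and positional UTR
# segments, PWM scanning and aUTR-vs-cUTR motif enrichment, CLIP-peak
# overlap, miRNA-site density, and transposable-element coverage with
# conservation stratification.

#' Build cUTR/aUTR and positional UTR segments
#'
#' For each gene: cUTR = stop codon to proximal pAS (present in every
#' isoform); aUTR = proximal to distal pAS (multi-pAS genes only). The
#' positional regions partition stop-to-distal exactly: proximal-region =
#' stop to proximal pAS, middle-region = proximal pAS to the last
#' APA-middle pAS (genes with >= 3 pASs), distal-region = the remainder up
#' to the distal pAS. Cleavage bases sit on segment boundaries (excluded on
#' the 3' side). SPA genes contribute a cUTR and proximal-region only.
#'
#' @param pas classified pAS table.
#' @param stop_codons named integer vector: per-gene 0-based UTR start (the
#'   transcript-side stop-codon boundary).
#' @return data.frame gene_id, segment_class, chrom, start, end, strand,
#'   length (0-based half-open coordinates).
#' @export
build_utr_segments <- function(pas, stop_codons) {
  parts <- split(seq_len(nrow(pas)), pas$gene_id)
  seg1 <- function(gene, cls, chrom, strand, lo, hi) {
    data.frame(gene_id = gene, segment_class = cls, chrom = chrom,
               start = lo, end = hi, strand = strand, length = hi - lo,
               stringsAsFactors = FALSE)
  }
  out <- lapply(parts, function(idx) {
    d <- pas[idx, , drop = FALSE]
    d <- d[order(d$rank_5to3), , drop = FALSE]
    g <- d$gene_id[1]; ch <- d$chrom[1]; str <- d$strand[1]
    stop_pos <- stop_codons[[g]]
    if (is.null(stop_pos) || is.na(stop_pos))
      stopf("build_utr_segments: no stop codon for gene %s", g)
    n <- nrow(d)
    # transcript-oriented boundaries; bnd(i) = 5' boundary of pAS i
    if (str == "+") {
      bnd <- d$start
      if (stop_pos >= bnd[1])
        stopf("build_utr_segments: stop codon downstream of proximal pAS for gene %s", g)
      iv <- function(a, b) c(a, b)
    } else {
      bnd <- d$end
      if (stop_pos <= bnd[1])
        stopf("build_utr_segments: stop codon downstream of proximal pAS for gene %s", g)
      iv <- function(a, b) c(b, a)   # transcript 5'->3' maps to decreasing ref
    }
    segs <- list()
    v <- iv(stop_pos, bnd[1])
    segs[[1]] <- seg1(g, "cUTR", ch, str, min(v), max(v))
    v <- iv(stop_pos, bnd[1])
    segs[[2]] <- seg1(g, "proximal-region", ch, str, min(v), max(v))
    if (n >= 2) {
      v <- iv(bnd[1], bnd[n])
      segs[[3]] <- seg1(g, "aUTR", ch, str, min(v), max(v))
      if (n >= 3) {
        v <- iv(bnd[1], bnd[n - 1])
        segs[[4]] <- seg1(g, "middle-region", ch, str, min(v), max(v))
        v <- iv(bnd[n - 1], bnd[n])
        segs[[5]] <- seg1(g, "distal-region", ch, str, min(v), max(v))
      } else {
        v <- iv(bnd[1], bnd[n])
        segs[[4]] <- seg1(g, "distal-region", ch, str, min(v), max(v))
      }
    }
    do.call(rbind, segs)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  bad <- which(res$length <= 0L)
  if (length(bad))
    stopf("build_utr_segments: empty segment for gene %s", res$gene_id[bad[1]])
  res
}

# Integer-encode sequences and score all windows of width w against a
# log-odds matrix; returns per-window scores (NA where the window holds N).
.encode_seq <- function(s) {
  x <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  x
}

#' Scan a sequence for PWM hits by log-odds scoring
#'
#' Windows scoring at least `score_fraction` of the maximum attainable
#' log-odds score are reported; overlapping hits are allowed. Windows
#' containing N are skipped.
#'
#' @param sequence DNA string.
#' @param pwm positions x ACGT probability matrix.
#' @param score_fraction fraction of the maximal score required (default
#'   0.8).
#' @param background background base frequencies (default uniform).
#' @param pseudocount added to PWM probabilities before log-odds (default
#'   1e-3).
#' @return data.frame pos (1-based window start), score.
#' @export
scan_pwm_hits <- function(sequence, pwm, score_fraction = 0.8,
                          background = rep(0.25, 4), pseudocount = 1e-3) {
  lo <- log2((pwm + pseudocount) / (1 + 4 * pseudocount)) -
    matrix(log2(background), nrow(pwm), 4, byrow = TRUE)
  smax <- sum(apply(lo, 1, max))
  thr <- score_fraction * smax
  w <- nrow(pwm)
  code <- .encode_seq(sequence)
  n <- length(code) - w + 1L
  if (n < 1L) return(data.frame(pos = integer(), score = numeric()))
  score <- rep(0, n)
  for (j in seq_len(w)) {
    b <- code[j:(j + n - 1L)]
    v <- lo[j, ][b]
    v[is.na(b)] <- NA_real_
    score <- score + v
  }
  keep <- which(!is.na(score) & score >= thr)
  data.frame(pos = keep, score = score[keep])
}

# Fast gene-level hit indicators for many sequences x many motifs: windows
# are one-hot encoded once per motif width and scored against all log-odds
# matrices by a single matrix product (chunked over motifs to bound memory).
# Returns a logical matrix (sequences x motifs).
.pwm_hit_matrix <- function(seqs, pwms, score_fraction = 0.8,
                            background = rep(0.25, 4), pseudocount = 1e-3,
                            chunk = 200L) {
  codes <- lapply(unname(seqs), .encode_seq)
  lens <- lengths(codes)
  flat <- unlist(codes, use.names = FALSE)
  seq_of <- rep.int(seq_along(codes), lens)
  starts <- cumsum(c(0L, lens[-length(lens)]))
  hit <- matrix(FALSE, length(seqs), length(pwms),
                dimnames = list(names(seqs), names(pwms)))
  widths <- vapply(pwms, nrow, 0L)
  for (w in unique(widths)) {
    ok_seq <- which(lens >= w)
    if (!length(ok_seq)) next
    win_start <- unlist(lapply(ok_seq, function(i)
      starts[i] + seq_len(lens[i] - w + 1L)), use.names = FALSE)
    win_seq <- seq_of[win_start]
    n_win <- length(win_start)
    onehot <- matrix(0, n_win, 4L * w)
    bad <- rep(FALSE, n_win)
    for (j in seq_len(w)) {
      b <- flat[win_start + (j - 1L)]
      nab <- is.na(b)
      bad <- bad | nab
      rows <- which(!nab)
      onehot[cbind(rows, (j - 1L) * 4L + b[rows])] <- 1
    }
    mis <- which(widths == w)
    lo_stack <- vapply(mis, function(mi) {
      lo <- log2((pwms[[mi]] + pseudocount) / (1 + 4 * pseudocount)) -
        matrix(log2(background), w, 4, byrow = TRUE)
      as.vector(t(lo))
    }, numeric(4L * w))
    thr <- vapply(mis, function(mi) {
      lo <- log2((pwms[[mi]] + pseudocount) / (1 + 4 * pseudocount)) -
        matrix(log2(background), w, 4, byrow = TRUE)
      score_fraction * sum(apply(lo, 1, max))
    }, 0)
    for (c0 in seq(1L, length(mis), by = chunk)) {
      ci <- c0:min(c0 + chunk - 1L, length(mis))
      scores <- onehot %*% lo_stack[, ci, drop = FALSE]
      if (any(bad)) scores[bad, ] <- -Inf
      pass <- sweep(scores, 2L, thr[ci], ">=")
      for (jj in seq_along(ci)) {
        h <- pass[, jj]
        if (any(h)) hit[unique(win_seq[h]), mis[ci[jj]]] <- TRUE
      }
    }
  }
  hit
}

#' One-sided or two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric tail probabilities for the table
#' \preformatted{        hit   no-hit
#'   aUTR    a      b
#'   cUTR    c      d}
#' `side = "greater"` tests enrichment of hits in the first row.
#'
#' @param a,b,c,d table counts.
#' @param side "greater", "less" or "two.sided".
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, side = c("greater", "less", "two.sided")) {
  side <- match.arg(side)
  m <- a + b; n <- c + d; k <- a + c
  if (side == "greater")
    return(stats::phyper(a - 1, m, n, k, lower.tail = FALSE))
  if (side == "less")
    return(stats::phyper(a, m, n, k))
  supp <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(supp, m, n, k)
  min(1, sum(dens[dens <= stats::dhyper(a, m, n, k) * (1 + 1e-7)]))
}

#' RBP motif enrichment in aUTRs over cUTRs
#'
#' Per motif, genes are scored for presence (>= 1 log-odds hit) in their
#' aUTR and in their cUTR; the 2x2 table of gene-level indicators is tested
#' with a one-sided Fisher exact test (aUTR-enriched) and Bonferroni
#' corrected over the number of motifs tested.
#'
#' @param autr_seqs,cutr_seqs named character vectors of per-gene aUTR and
#'   cUTR sequences (same genes).
#' @param pwms named list of PWMs.
#' @param score_fraction log-odds threshold fraction (default 0.8).
#' @param alpha Bonferroni-corrected significance level (default 1e-3).
#' @param mode "gene" (indicator, default) or "occurrence" (reserved).
#' @return data.frame motif_id, a (aUTR hit), b, c (cUTR hit), d, odds_ratio,
#'   p, p_bonferroni, significant.
#' @export
motif_enrichment_autr_vs_cutr <- function(autr_seqs, cutr_seqs, pwms,
                                          score_fraction = 0.8, alpha = 1e-3,
                                          mode = c("gene", "occurrence")) {
  mode <- match.arg(mode)
  if (!length(autr_seqs) || !length(cutr_seqs))
    stopf("motif_enrichment_autr_vs_cutr: zero genes")
  genes <- intersect(names(autr_seqs), names(cutr_seqs))
  if (!length(genes)) stopf("motif_enrichment_autr_vs_cutr: no shared genes")
  hits_a <- .pwm_hit_matrix(autr_seqs[genes], pwms, score_fraction)
  hits_c <- .pwm_hit_matrix(cutr_seqs[genes], pwms, score_fraction)
  n_motifs <- length(pwms)
  out <- do.call(rbind, lapply(seq_len(n_motifs), function(mi) {
    a <- sum(hits_a[, mi]); b <- length(genes) - a
    cc <- sum(hits_c[, mi]); d <- length(genes) - cc
    p <- fisher_exact_2x2(a, b, cc, d, side = "greater")
    or <- (a * d) / (b * cc)
    data.frame(motif_id = names(pwms)[mi], a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = p,
               p_bonferroni = min(1, p * n_motifs),
               stringsAsFactors = FALSE)
  }))
  out$significant <- out$p_bonferroni <= alpha
  rownames(out) <- NULL
  out
}

.filter_peaks <- function(peaks, max_padj = NULL, min_lfc = NULL) {
  keep <- rep(TRUE, length(peaks))
  mc <- S4Vectors::mcols(peaks)
  if (!is.null(max_padj) && "padj" %in% names(mc)) keep <- keep & mc$padj < max_padj
  if (!is.null(min_lfc) && "lfc" %in% names(mc)) keep <- keep & mc$lfc > min_lfc
  peaks[keep]
}

#' CLIP-peak overlap with UTR segments of a gene set
#'
#' A gene counts as peak-positive in a segment class when any (filtered)
#' peak overlaps its segment by >= 1 bp. Peak scores are compared between
#' peaks overlapping segments of in-set genes and all other peaks with a
#' Wilcoxon rank-sum test.
#'
#' @param gene_set character vector of gene ids (e.g. PPAU-decreased genes).
#' @param segments UTR segments from [build_utr_segments()].
#' @param peaks GRanges with mcols score (and optionally padj, lfc).
#' @param max_padj,min_lfc optional peak filters applied before overlap.
#' @return list(fraction = data.frame segment_class, n_genes, n_with_peak,
#'   fraction; score_test = list(median_in, median_out, n_in, n_out, p)).
#' @export
peak_overlap_summary <- function(gene_set, segments, peaks,
                                 max_padj = 0.05, min_lfc = 0) {
  peaks <- .filter_peaks(peaks, max_padj, min_lfc)
  segs <- segments[segments$gene_id %in% gene_set, , drop = FALSE]
  frac <- do.call(rbind, lapply(unique(segments$segment_class), function(k) {
    d <- segs[segs$segment_class == k, , drop = FALSE]
    n_genes <- length(unique(d$gene_id))
    if (!nrow(d) || !length(peaks))
      return(data.frame(segment_class = k, n_genes = n_genes, n_with_peak = 0L,
                        fraction = if (n_genes) 0 else NA_real_,
                        stringsAsFactors = FALSE))
    gr <- .df_to_granges(d)
    ov <- GenomicRanges::findOverlaps(gr, peaks, ignore.strand = TRUE)
    gwp <- unique(d$gene_id[S4Vectors::queryHits(ov)])
    data.frame(segment_class = k, n_genes = n_genes,
               n_with_peak = length(gwp), fraction = length(gwp) / n_genes,
               stringsAsFactors = FALSE)
  }))
  rownames(frac) <- NULL
  score_test <- list(median_in = NA_real_, median_out = NA_real_,
                     n_in = 0L, n_out = 0L, p = NA_real_)
  if (length(peaks)) {
    in_gr <- .df_to_granges(segs)
    in_peak <- rep(FALSE, length(peaks))
    if (length(in_gr)) {
      ov <- GenomicRanges::findOverlaps(peaks, in_gr, ignore.strand = TRUE)
      in_peak[unique(S4Vectors::queryHits(ov))] <- TRUE
    }
    sc <- S4Vectors::mcols(peaks)$score
    score_test$n_in <- sum(in_peak); score_test$n_out <- sum(!in_peak)
    sc_in <- sc[in_peak & !is.na(sc)]; sc_out <- sc[!in_peak & !is.na(sc)]
    if (length(sc_in)) score_test$median_in <- stats::median(sc_in)
    if (length(sc_out)) score_test$median_out <- stats::median(sc_out)
    if (length(sc_in) && length(sc_out))
      score_test$p <- stats::wilcox.test(sc_in, sc_out, exact = FALSE)$p.value
  }
  list(fraction = frac, score_test = score_test)
}

#' PPAU by CLIP-peak status across conditions
#'
#' Per condition, compares PPAU between genes with and without peaks
#' (Wilcoxon rank-sum) and reports the interaction-style summary: the
#' difference of the two conditions' (with - without) median differences.
#'
#' @param ppau_df data.frame gene_id, condition, ppau.
#' @param genes_with_peaks character vector of peak-positive genes.
#' @return list(per_condition = data.frame condition, median_with,
#'   median_without, n_with, n_without, p; diff_of_diffs).
#' @export
ppau_by_peak_status <- function(ppau_df, genes_with_peaks) {
  .check_df_cols(ppau_df, c("gene_id", "condition", "ppau"), "ppau_by_peak_status")
  per <- do.call(rbind, lapply(unique(ppau_df$condition), function(cond) {
    d <- ppau_df[ppau_df$condition == cond & !is.na(ppau_df$ppau), ]
    w <- d$gene_id %in% genes_with_peaks
    if (!any(w) || !any(!w)) {
      warnf("ppau_by_peak_status: condition %s has an empty group", cond)
      return(data.frame(condition = cond,
                        median_with = if (any(w)) stats::median(d$ppau[w]) else NA_real_,
                        median_without = if (any(!w)) stats::median(d$ppau[!w]) else NA_real_,
                        n_with = sum(w), n_without = sum(!w), p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(condition = cond,
               median_with = stats::median(d$ppau[w]),
               median_without = stats::median(d$ppau[!w]),
               n_with = sum(w), n_without = sum(!w),
               p = stats::wilcox.test(d$ppau[w], d$ppau[!w], exact = FALSE)$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  dod <- NA_real_
  if (nrow(per) == 2L)
    dod <- (per$median_with[1] - per$median_without[1]) -
      (per$median_with[2] - per$median_without[2])
  list(per_condition = per, diff_of_diffs = dod)
}

#' miRNA binding-site counts and density per UTR segment
#'
#' A site is assigned to the segment containing its midpoint (sites are
#' short; midpoint assignment avoids double counting at boundaries).
#' Density is sites per kb.
#'
#' @param segments UTR segments.
#' @param sites GRanges of miRNA binding sites with mcols score.
#' @param min_score minimum site score (default 50, high-confidence sites).
#' @return list(per_segment = segments with n_sites and density columns;
#'   by_class = data.frame segment_class, n_segments, total_sites,
#'   total_length, density).
#' @export
mirna_site_stats <- function(segments, sites, min_score = 50) {
  sc <- S4Vectors::mcols(sites)$score
  if (!is.null(sc)) sites <- sites[!is.na(sc) & sc >= min_score]
  # site midpoint, 0-based: floor((start0 + end0 - 1) / 2)
  mid0 <- floor((GenomicRanges::start(sites) - 1 + GenomicRanges::end(sites) - 1) / 2)
  mid <- GenomicRanges::GRanges(GenomicRanges::seqnames(sites),
                                IRanges::IRanges(mid0 + 1, width = 1))
  segs <- segments
  n_sites <- integer(nrow(segs))
  if (length(mid)) {
    gr <- .df_to_granges(segs)
    ov <- GenomicRanges::findOverlaps(gr, mid, ignore.strand = TRUE)
    tab <- table(factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(segs))))
    n_sites <- as.integer(tab)
  }
  segs$n_sites <- n_sites
  segs$density <- 1000 * segs$n_sites / segs$length
  by_class <- do.call(rbind, lapply(unique(segs$segment_class), function(k) {
    d <- segs[segs$segment_class == k, ]
    data.frame(segment_class = k, n_segments = nrow(d),
               total_sites = sum(d$n_sites), total_length = sum(d$length),
               density = 1000 * sum(d$n_sites) / sum(d$length),
               stringsAsFactors = FALSE)
  }))
  rownames(by_class) <- NULL
  list(per_segment = segs, by_class = by_class)
}

#' Correlation between isoform expression and miRNA-site counts
#'
#' Isoform classes (short/middle/long) map to the proximal/middle/distal
#' UTR regions; per class, Spearman's rho (ties mid-ranked) between the
#' relative isoform expression and the site count in the corresponding UTR
#' region.
#'
#' @param expr data.frame gene_id, isoform_class (one of "short", "middle",
#'   "long"), expression.
#' @param site_counts data.frame gene_id, isoform_class, n_sites.
#' @return data.frame isoform_class, rho, n (rho NA when undefined, e.g.
#'   constant counts).
#' @export
expression_vs_sites_correlation <- function(expr, site_counts) {
  d <- merge(expr, site_counts, by = c("gene_id", "isoform_class"))
  out <- do.call(rbind, lapply(unique(d$isoform_class), function(k) {
    s <- d[d$isoform_class == k & !is.na(d$expression) & !is.na(d$n_sites), ]
    rho <- if (nrow(s) >= 3 && stats::sd(s$n_sites) > 0 && stats::sd(s$expression) > 0)
      suppressWarnings(stats::cor(s$expression, s$n_sites, method = "spearman"))
    else NA_real_
    data.frame(isoform_class = k, rho = rho, n = nrow(s),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Transposable-element coverage, family composition and stratified stats
#'
#' TE intervals are merged per family before coverage so overlapping copies
#' are not double counted. Coverage fraction = TE bp in segment / segment
#' bp; family composition = family bp / total TE bp within a segment class.
#' Segments are stratified into TE-overlapped (>= 1 bp of any TE) vs
#' TE-depleted; optional miRNA-site density and mean conservation are
#' reported per stratum.
#'
#' @param segments UTR segments.
#' @param tes GRanges of transposable elements with mcols family.
#' @param sites optional miRNA-site GRanges (with score) for stratified
#'   density.
#' @param track optional `cons_track` for stratified conservation.
#' @param min_site_score score filter for `sites` (default 50).
#' @return list(per_segment = segments with te_bp, te_fraction, te_status;
#'   by_class = segment_class-level coverage; families = family bp
#'   composition per class; stratified = per class x TE status: n_segments,
#'   mirna_density, mean_conservation).
#' @export
te_overlap_stats <- function(segments, tes, sites = NULL, track = NULL,
                             min_site_score = 50) {
  fam <- S4Vectors::mcols(tes)$family
  if (is.null(fam)) stopf("te_overlap_stats: TE intervals need a family column")
  merged <- unlist(GenomicRanges::reduce(
    GenomicRanges::split(tes, fam), ignore.strand = TRUE))
  merged_fam <- names(merged)
  names(merged) <- NULL
  seg_gr <- .df_to_granges(segments)
  all_te <- GenomicRanges::reduce(merged, ignore.strand = TRUE)

  cov_bp <- function(targets) {
    ov <- GenomicRanges::findOverlaps(seg_gr, targets, ignore.strand = TRUE)
    if (!length(ov)) return(integer(nrow(segments)))
    inter_w <- GenomicRanges::width(IRanges::pintersect(
      seg_gr[S4Vectors::queryHits(ov)], targets[S4Vectors::subjectHits(ov)],
      ignore.strand = TRUE))
    out <- integer(nrow(segments))
    agg <- rowsum(inter_w, S4Vectors::queryHits(ov))
    out[as.integer(rownames(agg))] <- as.integer(agg)
    out
  }
  segs <- segments
  segs$te_bp <- cov_bp(all_te)
  segs$te_fraction <- segs$te_bp / segs$length
  segs$te_status <- ifelse(segs$te_bp >= 1L, "TE-overlapped", "TE-depleted")

  by_class <- do.call(rbind, lapply(unique(segs$segment_class), function(k) {
    d <- segs[segs$segment_class == k, ]
    data.frame(segment_class = k, total_bp = sum(d$length),
               te_bp = sum(d$te_bp), te_fraction = sum(d$te_bp) / sum(d$length),
               stringsAsFactors = FALSE)
  }))
  rownames(by_class) <- NULL

  families <- do.call(rbind, lapply(unique(segs$segment_class), function(k) {
    idx <- which(segs$segment_class == k)
    sub_gr <- seg_gr[idx]
    do.call(rbind, lapply(unique(merged_fam), function(f) {
      fam_gr <- merged[merged_fam == f]
      ov <- GenomicRanges::findOverlaps(sub_gr, fam_gr, ignore.strand = TRUE)
      bp <- 0L
      if (length(ov))
        bp <- sum(GenomicRanges::width(IRanges::pintersect(
          sub_gr[S4Vectors::queryHits(ov)], fam_gr[S4Vectors::subjectHits(ov)],
          ignore.strand = TRUE)))
      data.frame(segment_class = k, family = f, te_bp = bp,
                 stringsAsFactors = FALSE)
    }))
  }))
  families$fraction_of_te <- stats::ave(families$te_bp, families$segment_class,
                                        FUN = function(x) if (sum(x)) x / sum(x) else NA_real_)
  rownames(families) <- NULL

  stratified <- NULL
  if (!is.null(sites) || !is.null(track)) {
    if (!is.null(sites)) {
      ms <- mirna_site_stats(segs, sites, min_score = min_site_score)$per_segment
      segs$n_sites <- ms$n_sites
    }
    if (!is.null(track)) {
      segs$mean_cons <- vapply(seq_len(nrow(segs)), function(i) {
        v <- conservation_at(track, segs$chrom[i], segs$start[i]:(segs$end[i] - 1L))
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, 0)
    }
    stratified <- do.call(rbind, lapply(unique(segs$segment_class), function(k) {
      do.call(rbind, lapply(c("TE-overlapped", "TE-depleted"), function(st) {
        d <- segs[segs$segment_class == k & segs$te_status == st, ]
        data.frame(segment_class = k, te_status = st, n_segments = nrow(d),
                   mirna_density = if (!is.null(sites) && nrow(d))
                     1000 * sum(d$n_sites) / sum(d$length) else NA_real_,
                   mean_conservation = if (!is.null(track) && nrow(d))
                     mean(d$mean_cons, na.rm = TRUE) else NA_real_,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(stratified) <- NULL
  }
  list(per_segment = segs, by_class = by_class, families = families,
       stratified = stratified)
}
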