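test_that("UTR segments match the worked plus-strand example", {
  pas <- classify_pas(data.frame(
    gene_id = "g", pas_id = c("g:1", "g:2", "g:3"), chrom = "chr1",
    start = c(200L, 300L, 500L), end = c(201L, 301L, 501L), strand = "+",
    stringsAsFactors = FALSE))
  seg <- build_utr_segments(pas, c(g = 100L))
  get <- function(k) unlist(seg[seg$segment_class == k, c("start", "end")],
                            use.names = FALSE)
  expect_equal(get("cUTR"), c(100L, 200L))
  expect_equal(get("aUTR"), c(200L, 500L))
  expect_equal(get("proximal-region"), c(100L, 200L))
  expect_equal(get("middle-region"), c(200L, 300L))
  expect_equal(get("distal-region"), c(300L, 500L))
})

test_that("minus-strand segments mirror the plus-strand case", {
  pas <- classify_pas(data.frame(
    gene_id = "g", pas_id = c("g:1", "g:2", "g:3"), chrom = "chr1",
    start = c(400L, 300L, 100L), end = c(401L, 301L, 101L), strand = "-",
    stringsAsFactors = FALSE))
  seg <- build_utr_segments(pas, c(g = 500L))
  get <- function(k) unlist(seg[seg$segment_class == k, c("start", "end")],
                            use.names = FALSE)
  expect_equal(get("cUTR"), c(401L, 500L))
  expect_equal(get("aUTR"), c(101L, 401L))
  expect_equal(get("middle-region"), c(301L, 401L))
  expect_equal(get("distal-region"), c(101L, 301L))
  # stop codon on the wrong side errors
  expect_error(build_utr_segments(pas, c(g = 300L)), "downstream")
})

test_that("positional regions partition stop-to-distal exactly", {
  cfg <- apa_sim_config(n_genes = 60)
  models <- generate_gene_models(cfg, seed = 3)
  pas <- classify_pas(models$pas, models$stop_codons)
  seg <- build_utr_segments(pas, models$stop_codons)
  for (g in unique(seg$gene_id)) {
    d <- seg[seg$gene_id == g, ]
    regions <- d[d$segment_class %in% c("proximal-region", "middle-region",
                                        "distal-region"), ]
    total <- sum(regions$length)
    dp <- pas[pas$gene_id == g, ]
    distal_len <- max(dp$utr_length)
    expect_equal(total, distal_len)
    # regions are disjoint: summed length equals union length
    gr <- gr0(regions$chrom, regions$start, regions$end)
    expect_equal(sum(GenomicRanges::width(GenomicRanges::reduce(gr))), total)
    # cUTR + aUTR = the same span for APA genes
    if (nrow(dp) > 1) {
      expect_equal(sum(d$length[d$segment_class %in% c("cUTR", "aUTR")]),
                   distal_len)
    }
  }
})

test_that("PWM scanning finds the consensus and respects the threshold", {
  pwm <- matrix(0.01, 6, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm[cbind(1:6, match(strsplit("TGCATG", "")[[1]], colnames(pwm)))] <- 0.97
  hits <- scan_pwm_hits(paste0("AAAA", "TGCATG", "AAAA"), pwm)
  expect_equal(hits$pos, 5L)
  expect_equal(nrow(scan_pwm_hits(strrep("A", 50), pwm)), 0L)
  # exhaustive per-position oracle on a random sequence
  set.seed(51)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  got <- scan_pwm_hits(s, pwm, score_fraction = 0.5)
  lo <- log2((pwm + 1e-3) / (1 + 4e-3) / 0.25)
  thr <- 0.5 * sum(apply(lo, 1, max))
  chars <- strsplit(s, "")[[1]]
  exp_pos <- integer()
  for (p in 1:(300 - 5)) {
    sc <- sum(lo[cbind(1:6, match(chars[p:(p + 5)], colnames(pwm)))])
    if (sc >= thr) exp_pos <- c(exp_pos, p)
  }
  expect_equal(got$pos, exp_pos)
})

test_that("Fisher exact equals closed forms and full enumeration", {
  expect_equal(fisher_exact_2x2(50, 0, 0, 50, "greater"), 1 / choose(100, 50))
  expect_equal(fisher_exact_2x2(10, 10, 10, 10, "two.sided"), 1)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1, "greater"), 5 / 6)
  set.seed(52)
  for (i in 1:200) {
    n <- sample.int(50, 1)
    x <- stats::rmultinom(1, n, rep(0.25, 4))
    a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
    # enumeration oracle over all tables with the observed margins
    m <- a + b; nn <- cc + d; k <- a + cc
    supp <- max(0, k - nn):min(k, m)
    dens <- stats::dhyper(supp, m, nn, k)
    expect_equal(fisher_exact_2x2(a, b, cc, d, "greater"),
                 sum(dens[supp >= a]), tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(a, b, cc, d, "less"),
                 sum(dens[supp <= a]), tolerance = 1e-12)
    two <- sum(dens[dens <= stats::dhyper(a, m, nn, k) * (1 + 1e-7)])
    expect_equal(fisher_exact_2x2(a, b, cc, d, "two.sided"), min(1, two),
                 tolerance = 1e-12)
    # agreement with the reference implementation
    ft <- stats::fisher.test(matrix(c(a, cc, b, d), 2), alternative = "greater")
    expect_equal(fisher_exact_2x2(a, b, cc, d, "greater"), ft$p.value,
                 tolerance = 1e-9)
  }
})

test_that("motif enrichment flags a planted imbalance and not equal rates", {
  pwm <- matrix(0.01, 7, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  pwm[cbind(1:7, match(strsplit("TGCATGC", "")[[1]], colnames(pwm)))] <- 0.97
  set.seed(53)
  mk_seq <- function(n, with_motif) {
    vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
      if (with_motif[i]) {
        p <- sample(1:290, 1)
        substr(s, p, p + 6) <- "TGCATGC"
      }
      s
    }, "")
  }
  genes <- sprintf("g%03d", 1:100)
  autr <- stats::setNames(mk_seq(100, rep(c(TRUE, FALSE), c(80, 20))), genes)
  cutr <- stats::setNames(mk_seq(100, rep(c(TRUE, FALSE), c(10, 90))), genes)
  out <- motif_enrichment_autr_vs_cutr(autr, cutr, list(m = pwm), alpha = 1e-3)
  expect_true(out$significant)
  expect_gte(out$a, 80)
  # hypergeometric oracle for the same table
  expect_equal(out$p, fisher_exact_2x2(out$a, out$b, out$c, out$d, "greater"))

  # identical hit rates: not significant
  autr2 <- stats::setNames(mk_seq(100, rep(c(TRUE, FALSE), 50)), genes)
  cutr2 <- stats::setNames(autr2, genes)
  out2 <- motif_enrichment_autr_vs_cutr(autr2, cutr2, list(m = pwm))
  expect_gt(out2$p, 0.4)
  expect_false(out2$significant)
})

test_that("peak overlap fractions and score comparison behave at the edges", {
  tp <- toy_pas()
  seg <- build_utr_segments(tp$pas, tp$stops)
  autr <- seg[seg$segment_class == "aUTR", ]
  peaks <- gr0(autr$chrom, autr$start, autr$end,
               name = paste0("pk", seq_len(nrow(autr))),
               score = c(9, 8))
  out <- peak_overlap_summary(unique(autr$gene_id), seg, peaks)
  expect_equal(out$fraction$fraction[out$fraction$segment_class == "aUTR"], 1)
  expect_equal(out$score_test$n_out, 0L)

  out0 <- peak_overlap_summary(unique(seg$gene_id), seg,
                               gr0(character(), integer(), integer(),
                                   name = character(), score = numeric()))
  expect_true(all(out0$fraction$n_with_peak == 0L))
  expect_true(is.na(out0$score_test$p))
})

test_that("peak overlap matches a per-base oracle on random instances", {
  set.seed(54)
  for (rep in 1:20) {
    n_seg <- sample(3:6, 1)
    s0 <- sort(sample(seq(0, 9000, by = 300), n_seg))
    seg <- data.frame(gene_id = sprintf("g%d", seq_len(n_seg)),
                      segment_class = "aUTR", chrom = "chr1",
                      start = s0, end = s0 + sample(50:280, n_seg, TRUE),
                      strand = "+", stringsAsFactors = FALSE)
    seg$length <- seg$end - seg$start
    np <- sample(5:15, 1)
    p0 <- sample(0:9500, np)
    peaks <- gr0("chr1", p0, p0 + sample(20:100, np, TRUE),
                 name = sprintf("p%d", 1:np), score = stats::runif(np))
    out <- peak_overlap_summary(seg$gene_id, seg, peaks,
                                max_padj = NULL, min_lfc = NULL)
    # per-base bitmap oracle
    cov <- rep(FALSE, 10000)
    for (i in seq_len(np))
      cov[(p0[i] + 1):min(10000, p0[i] + GenomicRanges::width(peaks)[i])] <- TRUE
    hit <- vapply(seq_len(n_seg), function(i)
      any(cov[(seg$start[i] + 1):seg$end[i]]), TRUE)
    expect_equal(out$fraction$n_with_peak, sum(hit))
  }
})

test_that("PPAU by peak status detects a condition-specific planted shift", {
  set.seed(55)
  genes <- sprintf("g%03d", 1:120)
  with_pk <- genes[1:60]
  mk <- function(cond, shift) data.frame(
    gene_id = genes, condition = cond,
    ppau = pmin(100, pmax(0, 60 + ifelse(genes %in% with_pk, shift, 0) +
                            stats::rnorm(120, 0, 6))))
  df <- rbind(mk("WT", -15), mk("KD", 0))
  out <- ppau_by_peak_status(df, with_pk)
  pWT <- out$per_condition$p[out$per_condition$condition == "WT"]
  pKD <- out$per_condition$p[out$per_condition$condition == "KD"]
  expect_lt(pWT, 0.01)
  expect_gt(pKD, 0.05)
  expect_lt(out$diff_of_diffs, 0)
  # identical group distributions: p is 1; empty group warns
  df2 <- mk("X", 0); df2$ppau <- rep(seq(30, 80, length.out = 60), 2)
  expect_gt(ppau_by_peak_status(df2, with_pk)$per_condition$p, 0.9)
  expect_warning(ppau_by_peak_status(mk("Y", 0), character(0)), "empty")
})

test_that("miRNA site stats use midpoint assignment and per-kb density", {
  seg <- data.frame(gene_id = "g", segment_class = "distal-region",
                    chrom = "chr1", start = 0L, end = 1000L, strand = "+",
                    length = 1000L, stringsAsFactors = FALSE)
  sites <- gr0("chr1", c(100L, 600L), c(107L, 607L),
               name = c("m1", "m2"), score = c(80, 90))
  out <- mirna_site_stats(seg, sites)
  expect_equal(out$per_segment$n_sites, 2L)
  expect_equal(out$per_segment$density, 2)
  # low-score sites are filtered
  sites2 <- gr0("chr1", 300L, 307L, name = "m3", score = 40)
  expect_equal(mirna_site_stats(seg, sites2)$per_segment$n_sites, 0L)
  # a site straddling the boundary is assigned by its midpoint
  straddle <- gr0("chr1", 997L, 1004L, name = "m4", score = 99)  # midpoint 1000
  expect_equal(mirna_site_stats(seg, straddle)$per_segment$n_sites, 0L)
  straddle2 <- gr0("chr1", 995L, 1002L, name = "m5", score = 99) # midpoint 998
  expect_equal(mirna_site_stats(seg, straddle2)$per_segment$n_sites, 1L)
})

test_that("miRNA assignment matches a brute-force midpoint oracle", {
  set.seed(56)
  for (rep in 1:20) {
    n_seg <- 4
    s0 <- sort(sample(seq(0, 8000, by = 500), n_seg))
    seg <- data.frame(gene_id = sprintf("g%d", 1:n_seg),
                      segment_class = sample(c("proximal-region", "distal-region"),
                                             n_seg, TRUE),
                      chrom = "chr1", start = s0,
                      end = s0 + sample(100:450, n_seg, TRUE), strand = "+",
                      stringsAsFactors = FALSE)
    seg$length <- seg$end - seg$start
    np <- 30
    p0 <- sample(0:8500, np)
    w <- sample(5:12, np, replace = TRUE)
    sites <- gr0("chr1", p0, p0 + w, name = sprintf("m%d", 1:np),
                 score = stats::runif(np, 0, 100))
    out <- mirna_site_stats(seg, sites, min_score = 50)
    mid <- floor((p0 + p0 + w - 1) / 2)
    keep <- S4Vectors::mcols(sites)$score >= 50
    oracle <- vapply(seq_len(n_seg), function(i)
      sum(keep & mid >= seg$start[i] & mid < seg$end[i]), 0L)
    expect_equal(out$per_segment$n_sites, oracle)
  }
})

test_that("expression vs site-count correlation has the exact toy values", {
  expr <- data.frame(gene_id = sprintf("g%d", 1:5), isoform_class = "short",
                     expression = c(10, 8, 6, 4, 2))
  cnt <- data.frame(gene_id = sprintf("g%d", 1:5), isoform_class = "short",
                    n_sites = 1:5)
  out <- expression_vs_sites_correlation(expr, cnt)
  expect_equal(out$rho, -1)
  cnt$n_sites <- 3L
  expect_true(is.na(expression_vs_sites_correlation(expr, cnt)$rho))
})

test_that("planted class-specific repression orders the correlations", {
  set.seed(58)
  n <- 150
  strengths <- c(short = 1.5, middle = 0.6, long = 0.2)
  expr <- do.call(rbind, lapply(names(strengths), function(k) {
    sites <- stats::rpois(n, 4)
    data.frame(gene_id = sprintf("g%03d", 1:n), isoform_class = k,
               expression = pmax(0, 10 - strengths[[k]] * sites +
                                   stats::rnorm(n, 0, 2)),
               n_sites = sites, stringsAsFactors = FALSE)
  }))
  out <- expression_vs_sites_correlation(expr[, 1:3], expr[, c(1, 2, 4)])
  rho <- stats::setNames(out$rho, out$isoform_class)
  expect_lt(rho[["short"]], rho[["middle"]])
  expect_lt(rho[["middle"]], rho[["long"]])
  expect_lt(rho[["short"]], -0.5)
})

test_that("TE coverage merges families and matches a bitmap oracle", {
  seg <- data.frame(gene_id = "g", segment_class = "distal-region",
                    chrom = "chr1", start = 0L, end = 1000L, strand = "+",
                    length = 1000L, stringsAsFactors = FALSE)
  tes <- gr0("chr1", c(0L, 250L), c(300L, 500L), name = c("t1", "t2"),
             score = NA_real_, family = c("B1", "B1"))
  out <- te_overlap_stats(seg, tes)
  expect_equal(out$per_segment$te_fraction, 0.5)  # merged, no double counting
  expect_equal(out$by_class$te_fraction, 0.5)
  expect_equal(out$families$fraction_of_te[out$families$family == "B1"], 1)

  set.seed(57)
  for (rep in 1:15) {
    n_seg <- 3
    s0 <- sort(sample(seq(0, 6000, by = 800), n_seg))
    seg <- data.frame(gene_id = sprintf("g%d", 1:n_seg),
                      segment_class = "middle-region", chrom = "chr1",
                      start = s0, end = s0 + sample(200:700, n_seg, TRUE),
                      strand = "+", stringsAsFactors = FALSE)
    seg$length <- seg$end - seg$start
    nt <- 25
    t0 <- sample(0:6500, nt)
    tw <- sample(30:200, nt, replace = TRUE)
    fams <- sample(c("B1", "MIR"), nt, TRUE)
    tes <- gr0("chr1", t0, t0 + tw, name = sprintf("t%d", 1:nt),
               score = NA_real_, family = fams)
    out <- te_overlap_stats(seg, tes)
    cov <- rep(FALSE, 7000)
    for (i in seq_len(nt)) cov[(t0[i] + 1):min(7000, t0[i] + tw[i])] <- TRUE
    for (i in seq_len(n_seg)) {
      bp <- sum(cov[(seg$start[i] + 1):seg$end[i]])
      expect_equal(out$per_segment$te_bp[i], bp)
      expect_equal(out$per_segment$te_status[i],
                   if (bp >= 1) "TE-overlapped" else "TE-depleted")
    }
    # per-family bitmap oracle
    for (f in c("B1", "MIR")) {
      covf <- rep(FALSE, 7000)
      for (i in which(fams == f)) covf[(t0[i] + 1):min(7000, t0[i] + tw[i])] <- TRUE
      bp_f <- sum(vapply(seq_len(n_seg), function(i)
        sum(covf[(seg$start[i] + 1):seg$end[i]]), 0L))
      expect_equal(sum(out$families$te_bp[out$families$family == f]), bp_f)
    }
  }
})

test_that("TE merging is idempotent and fractions stay in [0, 1]", {
  seg <- data.frame(gene_id = "g", segment_class = "distal-region",
                    chrom = "chr1", start = 0L, end = 500L, strand = "+",
                    length = 500L, stringsAsFactors = FALSE)
  tes <- gr0("chr1", c(0L, 0L, 100L), c(600L, 600L, 200L),
             name = c("a", "b", "c"), score = NA_real_,
             family = c("B1", "B1", "B1"))
  out <- te_overlap_stats(seg, tes)
  expect_equal(out$per_segment$te_fraction, 1)
})

test_that("TE-status stratification reports density and conservation", {
  seg <- data.frame(gene_id = c("g1", "g2"),
                    segment_class = "distal-region", chrom = "chr1",
                    start = c(0L, 2000L), end = c(1000L, 3000L), strand = "+",
                    length = 1000L, stringsAsFactors = FALSE)
  tes <- gr0("chr1", 100L, 600L, name = "t", score = NA_real_, family = "B1")
  sites <- gr0("chr1", c(150L, 2500L), c(157L, 2507L), name = c("m1", "m2"),
               score = c(90, 90))
  track <- cons_track(data.frame(chrom = "chr1", start = c(0, 2000),
                                 end = c(1000, 3000), score = c(0.2, 1.4)))
  out <- te_overlap_stats(seg, tes, sites = sites, track = track)
  st <- out$stratified
  ov <- st[st$te_status == "TE-overlapped", ]
  dep <- st[st$te_status == "TE-depleted", ]
  expect_equal(ov$n_segments, 1L)
  expect_equal(ov$mirna_density, 1)
  expect_equal(dep$mirna_density, 1)
  expect_lt(ov$mean_conservation, dep$mean_conservation)
})
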