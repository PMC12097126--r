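# Deterministic synthetic-data generator: gene models, pAS flanking
# sequences with class-conditional polyA-signal and +1-nucleotide
# probabilities, tissue x stage expression with planted PPAU-decreasing
# trajectories, and annotation tracks (miRNA sites, TEs, conservation,
# coding mask, CLIP peaks, PWMs) with planted density differences between
# constitutive and alternative UTR segments. Every draw is governed by the
# (config, seed) pair; a ground-truth manifest records what was planted.

#' Generator configuration
#'
#' Defaults encode the study conditions the pipeline is exercised under:
#' the AATAAA probabilities per pAS class (0.512 SPA / 0.289 proximal /
#' 0.309 middle / 0.435 distal), +1 adenine probabilities (0.85 / 0.83 /
#' 0.78 for proximal / middle / distal; 0.80 for SPA), the fraction of APA
#' genes implied by P(1 pAS) = 0.536, TE coverage targets (0.26 / 0.456 /
#' 0.512 for proximal / middle / distal regions), a linear-in-stage PPAU
#' decline for planted decreasing genes, and a tissue effect three times
#' the stage effect so that samples cluster by tissue first.
#'
#' @param n_genes number of genes (default 300).
#' @param pas_count_probs probabilities for 1..5 pASs per gene.
#' @param tissues,stages sample structure (stage order = developmental
#'   order).
#' @param n_replicates biological replicates per tissue x stage.
#' @param n_decreasing planted PPAU-decreasing genes (drawn from multi-pAS
#'   genes); NULL uses `frac_decreasing`.
#' @param frac_decreasing fraction of genes planted as decreasing when
#'   `n_decreasing` is NULL.
#' @param delta_ppau_total total PPAU decline (0-100 scale) from first to
#'   last stage for decreasing genes.
#' @param ppau_noise_sd per-gene per-stage trajectory noise sd.
#' @param replicate_noise_sd per-replicate PPAU noise sd.
#' @param tissue_effect_sd sd of per-gene tissue offsets on PPAU.
#' @param signal_probs named AATAAA planting probability per pAS class.
#' @param attaaa_prob ATTAAA planting probability (all classes).
#' @param plus_one_a named +1 adenine probability per pAS class.
#' @param mirna_density miRNA sites per kb by UTR region class.
#' @param te_coverage TE bp-coverage target by UTR region class.
#' @param cons_mean_te,cons_mean_nonte,cons_sd conservation score means
#'   inside/outside TEs and their sd.
#' @param utr_len_range min/max total 3'-UTR length (nt).
#' @param min_pas_spacing minimum spacing between pASs (nt).
#' @param cds_len coding-region length upstream of the stop codon (nt).
#' @param expr_meanlog,expr_sdlog,expr_pas_slope log-normal gene TPM:
#'   meanlog gains `expr_pas_slope` per extra pAS (higher expression for
#'   multi-pAS genes).
#' @param motif_consensus consensus of the planted-enriched RBP motif.
#' @param motif_autr_rate,motif_cutr_rate planting rate of the motif in
#'   aUTRs/cUTRs of decreasing genes.
#' @param n_decoy_pwms decoy PWMs (never planted).
#' @param clip_autr_rate,clip_bg_rate CLIP-peak rates for decreasing-gene
#'   aUTRs vs background UTRs.
#' @return a `apa_sim_config` list.
#' @export
apa_sim_config <- function(
    n_genes = 300,
    pas_count_probs = c(0.536, 0.22, 0.13, 0.08, 0.034),
    tissues = c("forebrain", "midbrain", "hindbrain", "liver"),
    stages = c("E10.5", "E12.5", "E14.5", "E16.5"),
    n_replicates = 2,
    n_decreasing = NULL,
    frac_decreasing = 0.2,
    delta_ppau_total = 30,
    ppau_noise_sd = 3,
    replicate_noise_sd = 3,
    tissue_effect_sd = 9,
    signal_probs = c("SPA" = 0.512, "APA-proximal" = 0.289,
                     "APA-middle" = 0.309, "APA-distal" = 0.435),
    attaaa_prob = 0.133,
    plus_one_a = c("SPA" = 0.80, "APA-proximal" = 0.85,
                   "APA-middle" = 0.83, "APA-distal" = 0.78),
    mirna_density = c("proximal-region" = 3, "middle-region" = 2,
                      "distal-region" = 1.5),
    te_coverage = c("proximal-region" = 0.26, "middle-region" = 0.456,
                    "distal-region" = 0.512),
    cons_mean_te = 0, cons_mean_nonte = 1, cons_sd = 0.3,
    utr_len_range = c(200, 3000),
    min_pas_spacing = 100,
    cds_len = 300,
    expr_meanlog = log(5), expr_sdlog = 1, expr_pas_slope = 0.4,
    motif_consensus = "TGCATGC",
    motif_autr_rate = 0.8, motif_cutr_rate = 0.1,
    n_decoy_pwms = 20,
    clip_autr_rate = 0.8, clip_bg_rate = 0.1) {
  cfg <- as.list(environment())
  if (abs(sum(pas_count_probs) - 1) > 1e-9)
    stopf("apa_sim_config: pas_count_probs must sum to 1")
  if (any(unlist(cfg[c("signal_probs", "plus_one_a", "te_coverage")]) < 0) ||
      any(unlist(cfg[c("signal_probs", "plus_one_a", "te_coverage")]) > 1))
    stopf("apa_sim_config: probabilities must lie in [0, 1]")
  structure(cfg, class = "apa_sim_config")
}

#' Generate gene models (pAS positions, stop codons, chromosome layout)
#'
#' Genes are laid out alternately on two toy chromosomes and both strands;
#' total 3'-UTR length is drawn from `utr_len_range` and pASs are spaced at
#' least `min_pas_spacing` nt apart, the distal pAS terminating the UTR.
#'
#' @param config `apa_sim_config`.
#' @param seed RNG seed (mandatory).
#' @return list(genes, pas, stop_codons, chrom_lengths); `pas` is an
#'   (unclassified) pAS table with planned utr_length, score 5.
#' @export
generate_gene_models <- function(config, seed) {
  if (missing(seed)) stopf("generate_gene_models: seed is mandatory")
  set.seed(.derive_seed(seed, 1L))
  n <- config$n_genes
  n_pas <- sample.int(5L, n, replace = TRUE, prob = config$pas_count_probs)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  chrom <- rep(c("chr1", "chr2"), length.out = n)
  sp <- config$min_pas_spacing
  buffer <- 60L
  gap <- 200L
  cursor <- c(chr1 = 0L, chr2 = 0L)
  genes <- vector("list", n)
  pas <- vector("list", n)
  for (i in seq_len(n)) {
    np <- n_pas[i]
    L_min <- max(config$utr_len_range[1], sp * (np + 1L))
    L <- as.integer(round(stats::runif(1, L_min, config$utr_len_range[2])))
    extra <- L - sp * np
    gaps <- if (np > 1) diff(c(0, sort(stats::runif(np - 1)), 1)) * extra else extra
    utr_l <- as.integer(round(sp * seq_len(np) + cumsum(gaps)))
    utr_l[np] <- L
    ch <- chrom[i]
    g0 <- cursor[[ch]] + gap
    if (strand[i] == "+") {
      stop_pos <- g0 + config$cds_len
      pas_start <- stop_pos + utr_l
      g_end <- stop_pos + L + buffer
    } else {
      u0 <- g0 + buffer
      stop_pos <- u0 + L
      pas_start <- stop_pos - utr_l - 1L
      g_end <- stop_pos + config$cds_len
    }
    cursor[[ch]] <- g_end
    gid <- sprintf("g%04d", i)
    genes[[i]] <- data.frame(gene_id = gid, chrom = ch, strand = strand[i],
                             stop_pos = stop_pos, n_pas = np,
                             utr_total = L, stringsAsFactors = FALSE)
    pas[[i]] <- data.frame(gene_id = gid,
                           pas_id = sprintf("%s:pas%d", gid, seq_len(np)),
                           chrom = ch, start = pas_start,
                           end = pas_start + 1L, strand = strand[i],
                           score = 5, utr_length = utr_l,
                           stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  pas <- do.call(rbind, pas)
  rownames(pas) <- NULL
  stop_codons <- stats::setNames(genes$stop_pos, genes$gene_id)
  list(genes = genes, pas = pas, stop_codons = stop_codons,
       chrom_lengths = cursor + gap)
}

.sample_bases <- function(n, prob = rep(0.25, 4)) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob)
}

.comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Generate a genome with planted pAS windows
#'
#' The background is uniform random sequence; the 50 nt upstream of each
#' pAS is drawn U(T)-enriched; a polyA-signal hexamer (AATAAA with the
#' class-conditional probability, else ATTAAA with `attaaa_prob`) is
#' planted at a random upstream offset; the +1 base is adenine with the
#' class-conditional probability. Minus-strand windows are planted as
#' reverse complements on the reference.
#'
#' @param config `apa_sim_config`.
#' @param models from [generate_gene_models()].
#' @param seed RNG seed.
#' @return list(genome = DNAStringSet, truth = per-pAS data.frame of
#'   planted signal, offset and +1 base).
#' @export
generate_sequences <- function(config, models, seed) {
  if (missing(seed)) stopf("generate_sequences: seed is mandatory")
  set.seed(.derive_seed(seed, 2L))
  pas <- classify_pas(models$pas, models$stop_codons)
  chrom_vecs <- lapply(models$chrom_lengths, function(L) .sample_bases(L))
  u_rich <- c(0.20, 0.20, 0.20, 0.40)
  truth <- data.frame(pas_id = pas$pas_id, pas_class = pas$pas_class,
                      planted_signal = "none", planted_offset = NA_integer_,
                      planted_plus_one = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pas))) {
    cls <- pas$pas_class[i]
    up <- .sample_bases(50L, u_rich)
    u <- stats::runif(1)
    sig <- if (u < config$signal_probs[[cls]]) "AATAAA"
           else if (u < config$signal_probs[[cls]] + config$attaaa_prob) "ATTAAA"
           else "none"
    off <- NA_integer_
    if (sig != "none") {
      j <- sample.int(45L, 1L)            # hexamer start within the 50-mer
      up[j:(j + 5L)] <- strsplit(sig, "")[[1]]
      off <- j - 51L
    }
    p1 <- if (stats::runif(1) < config$plus_one_a[[cls]]) "A"
          else sample(c("C", "G", "T"), 1L)
    truth$planted_signal[i] <- sig
    truth$planted_offset[i] <- off
    truth$planted_plus_one[i] <- p1
    ch <- pas$chrom[i]; s <- pas$start[i]
    if (pas$strand[i] == "+") {
      chrom_vecs[[ch]][(s - 49L):s] <- up          # 0-based s-50..s-1
      chrom_vecs[[ch]][s + 2L] <- p1               # 0-based s+1
    } else {
      chrom_vecs[[ch]][(s + 2L):(s + 51L)] <- rev(unname(.comp_base[up]))
      chrom_vecs[[ch]][s] <- .comp_base[[p1]]      # 0-based s-1
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(chrom_vecs, paste, "", collapse = ""))
  names(genome) <- names(chrom_vecs)
  list(genome = genome, truth = truth)
}

#' Generate tissue x stage x replicate expression with planted trajectories
#'
#' Planted decreasing genes (multi-pAS only) decline linearly in PPAU by
#' `delta_ppau_total` across stages; stable genes keep a constant PPAU.
#' Per-gene tissue offsets (sd `tissue_effect_sd`) and per-gene per-tissue
#' stage noise (sd `ppau_noise_sd`, shared between replicates) are added,
#' then independent replicate noise; values are truncated to [1, 99] for
#' multi-pAS genes and the remaining pASs renormalised so PAUs sum to 100
#' exactly. Gene TPM is log-normal with a positive association between pAS
#' count and expression; isoform TPM = gene TPM x PAU / 100.
#'
#' @param config `apa_sim_config`.
#' @param models from [generate_gene_models()].
#' @param seed RNG seed.
#' @return list(quant = quant_table, meta = sample metadata, truth =
#'   list(gene_class, base_ppau = gene x stage planted means,
#'   decreasing_genes)).
#' @export
generate_expression <- function(config, models, seed) {
  if (missing(seed)) stopf("generate_expression: seed is mandatory")
  set.seed(.derive_seed(seed, 3L))
  pas <- classify_pas(models$pas, models$stop_codons)
  genes <- models$genes
  n <- nrow(genes)
  n_stage <- length(config$stages)
  meta <- expand.grid(replicate = seq_len(config$n_replicates),
                      stage_index = seq_len(n_stage) - 1L,
                      tissue = config$tissues,
                      stringsAsFactors = FALSE)
  meta$stage <- config$stages[meta$stage_index + 1L]
  meta$sample_id <- sprintf("%s_%s_r%d", meta$tissue, meta$stage, meta$replicate)
  meta <- meta[, c("sample_id", "tissue", "stage", "stage_index", "replicate")]

  multi <- which(genes$n_pas >= 2L)
  n_dec <- config$n_decreasing %||% round(config$frac_decreasing * n)
  if (n_dec > length(multi))
    stopf("generate_expression: cannot plant %d decreasing genes among %d multi-pAS genes",
          n_dec, length(multi))
  dec_idx <- sort(sample(multi, n_dec))
  gene_class <- rep("stable", n)
  gene_class[dec_idx] <- "decreasing"

  start_ppau <- ifelse(gene_class == "decreasing",
                       stats::runif(n, 60, 85), stats::runif(n, 20, 80))
  start_ppau[genes$n_pas == 1L] <- 100
  decline <- ifelse(gene_class == "decreasing",
                    config$delta_ppau_total / (n_stage - 1L), 0)
  base_ppau <- outer(start_ppau, seq_len(n_stage) - 1L,
                     function(s, k) s - decline * k)
  dimnames(base_ppau) <- list(genes$gene_id, config$stages)

  tissue_off <- matrix(stats::rnorm(n * length(config$tissues),
                                    sd = config$tissue_effect_sd),
                       n, length(config$tissues),
                       dimnames = list(genes$gene_id, config$tissues))
  stage_noise <- array(stats::rnorm(n * n_stage * length(config$tissues),
                                    sd = config$ppau_noise_sd),
                       dim = c(n, n_stage, length(config$tissues)),
                       dimnames = list(genes$gene_id, config$stages,
                                       config$tissues))

  base_tpm <- stats::rlnorm(n, meanlog = config$expr_meanlog +
                              config$expr_pas_slope * (genes$n_pas - 1L),
                            sdlog = config$expr_sdlog)
  # fixed per-gene split of (100 - PPAU) over the non-proximal pASs
  split_w <- lapply(seq_len(n), function(i) {
    k <- genes$n_pas[i] - 1L
    if (k < 1L) return(numeric(0))
    w <- stats::rexp(k); w / sum(w)
  })

  n_samp <- nrow(meta)
  tpm <- matrix(0, nrow(pas), n_samp,
                dimnames = list(paste(pas$gene_id, pas$pas_id, sep = "|"),
                                meta$sample_id))
  gene_rows <- split(seq_len(nrow(pas)), pas$gene_id)
  rep_noise <- matrix(stats::rnorm(n * n_samp, sd = config$replicate_noise_sd),
                      n, n_samp)
  tpm_noise <- matrix(exp(stats::rnorm(n * n_samp, sd = 0.2)), n, n_samp)
  for (j in seq_len(n_samp)) {
    tt <- meta$tissue[j]; si <- meta$stage_index[j] + 1L
    ppau <- base_ppau[, si] + tissue_off[, tt] + stage_noise[, si, tt] + rep_noise[, j]
    ppau <- ifelse(genes$n_pas == 1L, 100, pmin(99, pmax(1, ppau)))
    g_tpm <- base_tpm * tpm_noise[, j]
    for (i in seq_len(n)) {
      rows <- gene_rows[[genes$gene_id[i]]]
      pau <- c(ppau[i], (100 - ppau[i]) * split_w[[i]])
      ord <- order(pas$rank_5to3[rows])
      tpm[rows[ord], j] <- g_tpm[i] * pau / 100
    }
  }
  quant <- quant_table(pas$gene_id, pas$pas_id, tpm)
  list(quant = quant, meta = meta,
       truth = list(gene_class = stats::setNames(gene_class, genes$gene_id),
                    base_ppau = base_ppau,
                    decreasing_genes = genes$gene_id[dec_idx]))
}

# Fill a segment with non-overlapping TE intervals whose total length hits
# the coverage target: TE lengths are drawn until they sum to the target bp
# (last one truncated), then scattered with exponential random gaps scaled
# to fill the remaining free space exactly.
.place_tes <- function(start, end, frac, mean_len = 150) {
  len <- end - start
  target <- round(frac * len)
  if (target < 10L) {
    # short segments: a single TE of the target length, probabilistically
    if (stats::runif(1) > frac || len < 10L) return(NULL)
    s0 <- start + sample.int(max(1L, len - 9L), 1L) - 1L
    return(matrix(c(s0, min(end, s0 + 10L)), 1))
  }
  lens <- integer(0)
  while (sum(lens) < target)
    lens <- c(lens, as.integer(round(stats::runif(1, mean_len * 0.5,
                                                  mean_len * 1.5))))
  lens[length(lens)] <- target - sum(lens[-length(lens)])
  lens <- lens[lens > 0L]
  n <- length(lens)
  free <- len - sum(lens)
  g <- stats::rexp(n + 1L)
  gaps <- floor(g / sum(g) * free)
  starts <- start + cumsum(gaps)[seq_len(n)] + c(0L, cumsum(lens[-n]))
  cbind(starts, starts + lens)
}

#' Generate annotation tracks with planted density structure
#'
#' miRNA sites are placed at class-conditional densities (plus low-score
#' decoy sites exercising the score filter); TEs are placed to hit the
#' class-conditional coverage targets with family composition skewed
#' ancient (MIR/L2) in proximal regions and rodent-specific (B1/B2) in
#' middle/distal regions; conservation is low inside TEs and high outside
#' (coding regions scored separately and masked by the coding BED); CLIP
#' peaks fall preferentially in aUTRs of the planted decreasing genes; one
#' planted-enriched PWM is embedded in decreasing-gene aUTRs and decoy
#' PWMs are never embedded.
#'
#' @param config `apa_sim_config`.
#' @param models from [generate_gene_models()].
#' @param genome DNAStringSet from [generate_sequences()].
#' @param expr_truth `truth` element of [generate_expression()].
#' @param seed RNG seed.
#' @return list(mirna_sites, tes, clip_peaks (GRanges), coding_mask
#'   (GRanges), conservation (cons_track), pwms, genome (with embedded
#'   motifs), segments, truth).
#' @export
generate_annotations <- function(config, models, genome, expr_truth, seed) {
  if (missing(seed)) stopf("generate_annotations: seed is mandatory")
  set.seed(.derive_seed(seed, 4L))
  pas <- classify_pas(models$pas, models$stop_codons)
  segments <- build_utr_segments(pas, models$stop_codons)
  regions <- segments[segments$segment_class %in% names(config$te_coverage), ]

  # --- miRNA sites ------------------------------------------------------
  mir <- list()
  for (i in seq_len(nrow(regions))) {
    lam <- regions$length[i] / 1000 * config$mirna_density[[regions$segment_class[i]]]
    k <- stats::rpois(1, lam)
    k_decoy <- stats::rpois(1, lam * 0.2)
    if (k + k_decoy == 0) next
    s0 <- sort(sample.int(max(1L, regions$length[i] - 7L), k + k_decoy,
                          replace = TRUE)) + regions$start[i] - 1L
    mir[[length(mir) + 1L]] <- data.frame(
      chrom = regions$chrom[i], start = s0, end = s0 + 7L,
      score = c(stats::runif(k, 50, 100), stats::runif(k_decoy, 10, 49)),
      stringsAsFactors = FALSE)
  }
  mir <- if (length(mir)) do.call(rbind, mir) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               score = numeric())
  mirna_sites <- GenomicRanges::GRanges(
    mir$chrom, IRanges::IRanges(mir$start + 1L, mir$end), strand = "*")
  S4Vectors::mcols(mirna_sites)$name <- sprintf("mir_%d", seq_len(nrow(mir)))
  S4Vectors::mcols(mirna_sites)$score <- mir$score

  # --- transposable elements -------------------------------------------
  fam_probs <- list(
    "proximal-region" = c(MIR = 0.40, L2 = 0.30, B1 = 0.15, B2 = 0.15),
    "middle-region" = c(MIR = 0.15, L2 = 0.15, B1 = 0.35, B2 = 0.35),
    "distal-region" = c(MIR = 0.15, L2 = 0.15, B1 = 0.35, B2 = 0.35))
  te <- list()
  for (i in seq_len(nrow(regions))) {
    cls <- regions$segment_class[i]
    ivs <- .place_tes(regions$start[i], regions$end[i], config$te_coverage[[cls]])
    if (is.null(ivs)) next
    fp <- fam_probs[[cls]]
    te[[length(te) + 1L]] <- data.frame(
      chrom = regions$chrom[i], start = ivs[, 1], end = ivs[, 2],
      family = sample(names(fp), nrow(ivs), replace = TRUE, prob = fp),
      stringsAsFactors = FALSE)
  }
  te <- if (length(te)) do.call(rbind, te) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               family = character())
  tes <- GenomicRanges::GRanges(te$chrom, IRanges::IRanges(te$start + 1L, te$end),
                                strand = "*")
  S4Vectors::mcols(tes)$name <- sprintf("te_%d", seq_len(nrow(te)))
  S4Vectors::mcols(tes)$score <- rep(NA_real_, nrow(te))
  S4Vectors::mcols(tes)$family <- te$family

  # --- conservation: low in TEs, high outside, CDS scored separately ----
  cons <- list()
  utr_gr <- GenomicRanges::reduce(.df_to_granges(regions), ignore.strand = TRUE)
  te_gr <- GenomicRanges::reduce(tes, ignore.strand = TRUE)
  te_in_utr <- GenomicRanges::intersect(utr_gr, te_gr, ignore.strand = TRUE)
  non_te <- GenomicRanges::setdiff(utr_gr, te_gr, ignore.strand = TRUE)
  add_cons <- function(gr, mu) {
    if (!length(gr)) return()
    cons[[length(cons) + 1L]] <<- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
      score = stats::rnorm(length(gr), mu, config$cons_sd),
      stringsAsFactors = FALSE)
  }
  add_cons(te_in_utr, config$cons_mean_te)
  add_cons(non_te, config$cons_mean_nonte)
  genes <- models$genes
  cds_start <- ifelse(genes$strand == "+", genes$stop_pos - config$cds_len,
                      genes$stop_pos)
  cds <- data.frame(chrom = genes$chrom, start = cds_start,
                    end = cds_start + config$cds_len,
                    strand = genes$strand, stringsAsFactors = FALSE)
  coding_mask <- .df_to_granges(cbind(cds, name = genes$gene_id, score = NA_real_))
  add_cons(GenomicRanges::reduce(coding_mask, ignore.strand = TRUE), 1.5)
  conservation <- cons_track(do.call(rbind, cons))

  # --- CLIP peaks -------------------------------------------------------
  dec <- expr_truth$decreasing_genes
  autr <- segments[segments$segment_class == "aUTR", ]
  peaks <- list()
  for (i in seq_len(nrow(autr))) {
    is_dec <- autr$gene_id[i] %in% dec
    rate <- if (is_dec) config$clip_autr_rate else config$clip_bg_rate
    if (stats::runif(1) > rate) next
    k <- sample.int(3L, 1L)
    w <- pmin(50L, autr$length[i])
    s0 <- sample.int(max(1L, autr$length[i] - w), k, replace = TRUE) +
      autr$start[i] - 1L
    peaks[[length(peaks) + 1L]] <- data.frame(
      chrom = autr$chrom[i], start = s0, end = s0 + w,
      score = stats::rnorm(k, if (is_dec) 8 else 5, 1.5),
      stringsAsFactors = FALSE)
  }
  pk <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               score = numeric())
  clip_peaks <- GenomicRanges::GRanges(pk$chrom,
                                       IRanges::IRanges(pk$start + 1L, pk$end),
                                       strand = "*")
  S4Vectors::mcols(clip_peaks)$name <- sprintf("peak_%d", seq_len(nrow(pk)))
  S4Vectors::mcols(clip_peaks)$score <- pk$score

  # --- PWMs: one planted-enriched motif + decoys ------------------------
  sharp_pwm <- function(consensus, major = 0.97) {
    b <- strsplit(consensus, "")[[1]]
    m <- matrix((1 - major) / 3, length(b), 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    m[cbind(seq_along(b), match(b, colnames(m)))] <- major
    m
  }
  pwms <- list(planted = sharp_pwm(config$motif_consensus))
  for (k in seq_len(config$n_decoy_pwms)) {
    repeat {
      cons_k <- paste(.sample_bases(nchar(config$motif_consensus)), collapse = "")
      if (cons_k != config$motif_consensus) break
    }
    pwms[[sprintf("decoy_%03d", k)]] <- sharp_pwm(cons_k)
  }
  # embed the planted consensus into decreasing-gene aUTRs (and rarely cUTRs)
  chrom_strs <- stats::setNames(as.character(genome), names(genome))
  embed <- function(seg_row) {
    w <- nchar(config$motif_consensus)
    if (seg_row$length <= w) return()
    s0 <- sample.int(seg_row$length - w, 1L) + seg_row$start - 1L
    piece <- if (seg_row$strand == "+") config$motif_consensus else
      .revcomp_chr(config$motif_consensus)
    str <- chrom_strs[[seg_row$chrom]]
    substr(str, s0 + 1L, s0 + w) <- piece
    chrom_strs[[seg_row$chrom]] <<- str
  }
  motif_truth <- list(autr_genes = character(), cutr_genes = character())
  cutr <- segments[segments$segment_class == "cUTR", ]
  for (g in dec) {
    a <- autr[autr$gene_id == g, ]
    if (nrow(a) && stats::runif(1) < config$motif_autr_rate) {
      embed(a[1, ])
      motif_truth$autr_genes <- c(motif_truth$autr_genes, g)
    }
    cc <- cutr[cutr$gene_id == g, ]
    if (nrow(cc) && stats::runif(1) < config$motif_cutr_rate) {
      embed(cc[1, ])
      motif_truth$cutr_genes <- c(motif_truth$cutr_genes, g)
    }
  }
  genome2 <- Biostrings::DNAStringSet(chrom_strs)
  names(genome2) <- names(chrom_strs)

  list(mirna_sites = mirna_sites, tes = tes, clip_peaks = clip_peaks,
       coding_mask = coding_mask, conservation = conservation, pwms = pwms,
       genome = genome2, segments = segments,
       truth = list(motif = motif_truth,
                    te_coverage_target = config$te_coverage))
}

#' Extract transcript-strand sequences of UTR segments
#'
#' @param genome DNAStringSet.
#' @param segments UTR segments.
#' @param segment_class class to extract (e.g. "aUTR").
#' @return named character vector (gene ids), minus-strand sequences
#'   reverse-complemented.
#' @export
segment_sequences <- function(genome, segments, segment_class) {
  d <- segments[segments$segment_class == segment_class, , drop = FALSE]
  out <- character(nrow(d))
  for (ch in unique(d$chrom)) {
    idx <- which(d$chrom == ch)
    str <- as.character(genome[[ch]])
    raw <- substring(str, d$start[idx] + 1L, d$end[idx])
    minus <- d$strand[idx] == "-"
    raw[minus] <- .revcomp_chr(raw[minus])
    out[idx] <- raw
  }
  stats::setNames(out, d$gene_id)
}

#' Run the full synthetic-data generator
#'
#' Chains gene models, sequences, expression and annotations under one
#' seed; optionally writes the complete file set (pAS BED, stop-codon BED,
#' genome FASTA, quant TSV, sample metadata TSV, miRNA/TE/CLIP/coding
#' BEDs, conservation bedGraph, MEME PWM file, ground-truth TSV). The
#' (config, seed) pair fully determines every byte written.
#'
#' @param config `apa_sim_config`.
#' @param seed RNG seed.
#' @param outdir output directory, or NULL to skip writing.
#' @return list(models, genome, quant, meta, annotations, segments, truth,
#'   files).
#' @export
simulate_apa_dataset <- function(config = apa_sim_config(), seed, outdir = NULL) {
  if (missing(seed)) stopf("simulate_apa_dataset: seed is mandatory")
  models <- generate_gene_models(config, seed)
  seqs <- generate_sequences(config, models, seed)
  expr <- generate_expression(config, models, seed)
  ann <- generate_annotations(config, models, seqs$genome, expr$truth, seed)
  truth <- list(pas = seqs$truth, expression = expr$truth, motif = ann$truth$motif)
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outdir, x)
    files <- c(pas_bed = fp("pas.bed"), stops_bed = fp("stop_codons.bed"),
               genome_fa = fp("genome.fa"), quant_tsv = fp("quant.tsv"),
               meta_tsv = fp("samples.tsv"), mirna_bed = fp("mirna_sites.bed"),
               te_bed = fp("tes.bed"), clip_bed = fp("clip_peaks.bed"),
               coding_bed = fp("coding_mask.bed"),
               cons_bg = fp("conservation.bedGraph"), pwm_meme = fp("motifs.meme"),
               truth_tsv = fp("ground_truth_pas.tsv"))
    p <- models$pas
    writeLines(paste(p$chrom, p$start, p$end, p$pas_id, p$score, p$strand,
                     sep = "\t"), files[["pas_bed"]])
    g <- models$genes
    writeLines(paste(g$chrom, g$stop_pos, g$stop_pos + 1L, g$gene_id, 0,
                     g$strand, sep = "\t"), files[["stops_bed"]])
    write_genome_fasta(ann$genome, files[["genome_fa"]])
    write_quant_table(expr$quant, files[["quant_tsv"]])
    write_tsv_table(expr$meta, files[["meta_tsv"]])
    write_intervals_bed(ann$mirna_sites, files[["mirna_bed"]])
    write_intervals_bed(ann$tes, files[["te_bed"]], family = TRUE)
    write_intervals_bed(ann$clip_peaks, files[["clip_bed"]])
    write_intervals_bed(ann$coding_mask, files[["coding_bed"]])
    write_conservation_bedgraph(ann$conservation, files[["cons_bg"]])
    write_meme_pwms(ann$pwms, files[["pwm_meme"]])
    write_tsv_table(truth$pas, files[["truth_tsv"]])
  }
  list(models = models, genome = ann$genome, quant = expr$quant,
       meta = expr$meta, annotations = ann, segments = ann$segments,
       truth = truth, files = files)
}
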