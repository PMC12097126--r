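# PAU/PPAU quantification, positional pAS classification, and gene-level
# APA statistics (weighted 3'-UTR length, long/short genes, PAU entropy,
# tissue specificity, delta-PPAU, sample clustering, metagene signal).

#' Classify pASs by position within each gene
#'
#' Assigns the 5'-to-3' rank (1 = most proximal in transcript orientation)
#' and the positional class: genes with a single pAS are SPA; in multi-pAS
#' genes the rank-1 site is APA-proximal, the last is APA-distal, and any
#' site in between is APA-middle (possible only with >= 3 sites).
#'
#' @param pas data.frame from [read_pas_bed()] (gene_id, pas_id, chrom,
#'   start, end, strand).
#' @param stop_codons optional named integer vector of 0-based UTR start
#'   positions per gene (the transcript-side boundary of the stop codon);
#'   when given, `utr_length` (stop codon to cleavage site, nt) is added.
#' @return the input with columns rank_5to3, pas_class and (optionally)
#'   utr_length filled, ordered by gene and rank.
#' @export
classify_pas <- function(pas, stop_codons = NULL) {
  .check_df_cols(pas, c("gene_id", "pas_id", "chrom", "start", "strand"),
                 "classify_pas")
  parts <- split(seq_len(nrow(pas)), pas$gene_id)
  out <- lapply(parts, function(idx) {
    d <- pas[idx, , drop = FALSE]
    if (length(unique(d$chrom)) != 1L || length(unique(d$strand)) != 1L)
      stopf("classify_pas: gene %s has pASs on multiple chromosomes or strands",
            d$gene_id[1])
    if (anyDuplicated(d$start))
      stopf("classify_pas: gene %s has two pASs at identical coordinates (ambiguous rank)",
            d$gene_id[1])
    ord <- if (d$strand[1] == "+") order(d$start) else order(-d$start)
    d <- d[ord, , drop = FALSE]
    n <- nrow(d)
    d$rank_5to3 <- seq_len(n)
    d$pas_class <- if (n == 1L) "SPA" else
      c("APA-proximal", rep("APA-middle", max(0L, n - 2L)), "APA-distal")
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(stop_codons)) {
    stop_pos <- stop_codons[res$gene_id]
    if (anyNA(stop_pos))
      stopf("classify_pas: missing stop codon for gene %s",
            res$gene_id[which(is.na(stop_pos))[1]])
    res$utr_length <- as.integer(ifelse(res$strand == "+",
                                        res$start - stop_pos,
                                        stop_pos - res$end))
    bad <- which(res$utr_length <= 0L)
    if (length(bad))
      stopf("classify_pas: stop codon is downstream of pAS %s in transcript orientation",
            res$pas_id[bad[1]])
  }
  res
}

#' Compute polyA-site usage (PAU)
#'
#' PAU_i = 100 * TPM_i / sum of the gene's pAS TPMs, per sample. Usage is
#' only defined for genes passing the expression gate: in samples where the
#' gene's total TPM is below `min_tpm` every PAU of that gene is missing
#' (this includes single-pAS genes with zero expression, which report NA
#' rather than 100).
#'
#' @param quant a `quant_table`.
#' @param min_tpm minimum per-sample gene total TPM for PAU to be defined
#'   (default 0.1).
#' @return a `pau_table`: list with `pau` (matrix on the 0-100 scale, NA
#'   where undefined), `gene_id`, `pas_id`.
#' @export
compute_pau <- function(quant, min_tpm = 0.1) {
  tpm <- quant$tpm
  totals <- rowsum(tpm, quant$gene_id)            # gene x sample
  gene_tot <- totals[quant$gene_id, , drop = FALSE]
  pau <- 100 * tpm / gene_tot
  pau[gene_tot < min_tpm] <- NA_real_
  structure(list(pau = pau, gene_id = quant$gene_id, pas_id = quant$pas_id),
            class = "pau_table")
}

#' @export
print.pau_table <- function(x, ...) {
  cat(sprintf("pau_table: %d pASs x %d samples, %d genes\n",
              nrow(x$pau), ncol(x$pau), length(unique(x$gene_id))))
  invisible(x)
}

#' Write a pau_table as TSV
#'
#' @param x pau_table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pau_table <- function(x, path) {
  df <- data.frame(gene_id = x$gene_id, pas_id = x$pas_id,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(x$pau, check.names = FALSE))
  write_tsv_table(df, path)
}

#' Proximal polyA usage (PPAU) per gene and sample
#'
#' PPAU is the PAU of each gene's rank-1 (most proximal) pAS; missingness
#' propagates. For an SPA gene this is 100 wherever the gene is expressed.
#'
#' @param pau a `pau_table`.
#' @param pas classified pAS table (with rank_5to3).
#' @return gene x sample matrix of PPAU.
#' @export
compute_ppau <- function(pau, pas) {
  prox <- pas[pas$rank_5to3 == 1L, , drop = FALSE]
  key <- paste(prox$gene_id, prox$pas_id, sep = "|")
  missing_keys <- setdiff(key, rownames(pau$pau))
  if (length(missing_keys))
    stopf("compute_ppau: proximal pAS %s absent from PAU table", missing_keys[1])
  m <- pau$pau[key, , drop = FALSE]
  rownames(m) <- prox$gene_id
  m[order(rownames(m)), , drop = FALSE]
}

#' PAU-weighted 3'-UTR length
#'
#' The sum of a gene's isoform 3'-UTR lengths weighted by their PAUs:
#' sum(L_i * PAU_i / 100). Any missing PAU makes the result missing.
#'
#' @param utr_lengths isoform UTR lengths (nt).
#' @param paus PAU values on the 0-100 scale, summing to 100 (checked to
#'   1e-6).
#' @return weighted length in nt, or NA.
#' @export
weighted_utr_length <- function(utr_lengths, paus) {
  if (length(utr_lengths) != length(paus))
    stopf("weighted_utr_length: length mismatch")
  if (anyNA(paus)) return(NA_real_)
  if (abs(sum(paus) - 100) > 1e-6)
    stopf("weighted_utr_length: PAUs must sum to 100 (got %.6f)", sum(paus))
  sum(utr_lengths * paus) / 100
}

#' Weighted 3'-UTR length for every gene and sample
#'
#' @param pau a `pau_table`.
#' @param pas classified pAS table with utr_length.
#' @return gene x sample matrix of weighted lengths (NA where PAU missing).
#' @export
gene_weighted_lengths <- function(pau, pas) {
  key <- paste(pas$gene_id, pas$pas_id, sep = "|")
  m <- pau$pau[key, , drop = FALSE]
  wl <- rowsum(m * pas$utr_length, pas$gene_id) / 100
  na_any <- rowsum(is.na(m) + 0, pas$gene_id) > 0
  wl[na_any] <- NA_real_
  wl[order(rownames(wl)), , drop = FALSE]
}

#' Call tissue-specific long and short genes
#'
#' A gene is "long" in tissue X when its weighted 3'-UTR length there
#' exceeds its weighted length in every other tissue by more than
#' `margin_nt`; "short" is defined symmetrically. With `mode = "majority"`
#' the margin must hold against a majority of the other tissues instead.
#'
#' @param wl gene x tissue matrix of weighted 3'-UTR lengths.
#' @param margin_nt margin in nt (default 100).
#' @param mode "all" (default) or "majority".
#' @return data.frame gene_id, label ("long-in-X", "short-in-X" or
#'   "neither"), tissue, defined_in (number of tissues with defined length).
#' @export
call_long_short_genes <- function(wl, margin_nt = 100, mode = c("all", "majority")) {
  mode <- match.arg(mode)
  res <- data.frame(gene_id = rownames(wl), label = "neither",
                    tissue = NA_character_,
                    defined_in = rowSums(!is.na(wl)),
                    stringsAsFactors = FALSE)
  need <- function(n_other) if (mode == "all") n_other else floor(n_other / 2) + 1
  for (i in seq_len(nrow(wl))) {
    v <- wl[i, ]
    def <- which(!is.na(v))
    if (length(def) < 2L) next
    for (j in def) {
      others <- setdiff(def, j)
      k <- need(length(others))
      if (sum(v[j] > v[others] + margin_nt) >= k) {
        res$label[i] <- paste0("long-in-", colnames(wl)[j])
        res$tissue[i] <- colnames(wl)[j]
        break
      }
      if (sum(v[j] < v[others] - margin_nt) >= k) {
        res$label[i] <- paste0("short-in-", colnames(wl)[j])
        res$tissue[i] <- colnames(wl)[j]
        break
      }
    }
  }
  res
}

#' Shannon entropy of a gene's PAU distribution
#'
#' H = -sum (PAU_i/100) log2 (PAU_i/100) with 0 log 0 = 0. Higher entropy
#' means more complex APA; H ranges from 0 (one pAS takes all usage) to
#' log2(n) (uniform usage).
#'
#' @param paus PAU values on the 0-100 scale summing to 100 (checked to
#'   1e-6).
#' @return entropy in bits.
#' @export
pau_entropy <- function(paus) {
  if (anyNA(paus)) return(NA_real_)
  if (abs(sum(paus) - 100) > 1e-6)
    stopf("pau_entropy: PAUs must sum to 100 (got %.6f)", sum(paus))
  p <- paus / 100
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' PAU entropy for every gene and sample
#'
#' Entropy is missing for a gene-sample whenever any of the gene's PAUs is
#' missing there (no renormalisation over observed pASs).
#'
#' @param pau a `pau_table`.
#' @return gene x sample matrix of entropies (bits).
#' @export
gene_entropy_matrix <- function(pau) {
  m <- pau$pau
  p <- m / 100
  term <- ifelse(!is.na(p) & p > 0, p * log2(p), 0)
  term[is.na(p)] <- NA_real_
  h <- -rowsum(term, pau$gene_id)
  h[h < 0 & h > -1e-12] <- 0
  h[order(rownames(h)), , drop = FALSE]
}

#' Tissue-level PAU entropy
#'
#' Averages per-sample entropy within each tissue: replicate values are
#' first averaged within a stage, then stage means are averaged across the
#' tissue's stages (missing stages skipped).
#'
#' @param entropy gene x sample entropy matrix.
#' @param meta sample metadata (see [read_sample_meta()]).
#' @return gene x tissue matrix of mean entropies.
#' @export
tissue_entropy <- function(entropy, meta) {
  meta <- meta[match(colnames(entropy), meta$sample_id), ]
  tissues <- sort(unique(meta$tissue))
  out <- matrix(NA_real_, nrow(entropy), length(tissues),
                dimnames = list(rownames(entropy), tissues))
  for (tt in tissues) {
    sel <- meta$tissue == tt
    stage_means <- vapply(sort(unique(meta$stage_index[sel])), function(s) {
      cols <- which(sel & meta$stage_index == s)
      rowMeans(entropy[, cols, drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(entropy)))
    stage_means <- matrix(stage_means, nrow = nrow(entropy))
    stage_means[is.nan(stage_means)] <- NA_real_
    out[, tt] <- rowMeans(stage_means, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Tissue-specificity score of gene expression
#'
#' TS = Max(TPM) / Mean(TPM) across samples; 1 for a uniformly expressed
#' gene, up to n for expression confined to one of n samples.
#'
#' @param tpm non-negative TPM vector over >= 2 samples.
#' @return TS score (>= 1), NA if the mean is zero.
#' @export
tissue_specificity <- function(tpm) {
  tpm <- tpm[!is.na(tpm)]
  if (length(tpm) < 2L) stopf("tissue_specificity: need >= 2 samples")
  m <- mean(tpm)
  if (m <= 0) return(NA_real_)
  max(tpm) / m
}

#' Expression class of a gene
#'
#' low: TPM <= 5; intermediate: 5 < TPM < 15; high: TPM >= 15.
#'
#' @param tpm TPM value(s).
#' @return character vector of classes.
#' @export
expression_class <- function(tpm) {
  ifelse(tpm <= 5, "low", ifelse(tpm >= 15, "high", "intermediate"))
}

#' Change in proximal polyA usage between two conditions
#'
#' @param ppau_a,ppau_b PPAU values (0-100 scale) in conditions a and b.
#' @param threshold absolute change called significant (default 20).
#' @return data.frame delta (a - b), significant, direction
#'   ("increase"/"decrease"/"none" reading a relative to b).
#' @export
delta_ppau <- function(ppau_a, ppau_b, threshold = 20) {
  d <- ppau_a - ppau_b
  data.frame(
    delta = d,
    significant = !is.na(d) & abs(d) >= threshold,
    direction = ifelse(is.na(d), NA_character_,
                       ifelse(d > 0, "increase", ifelse(d < 0, "decrease", "none"))),
    stringsAsFactors = FALSE
  )
}

#' Pearson correlation of PAU between two replicates
#'
#' Missing entries are pairwise-deleted.
#'
#' @param pau_rep1,pau_rep2 PAU vectors over the same pASs.
#' @return list(r, n) with the correlation and the number of jointly
#'   defined pASs used.
#' @export
replicate_pau_correlation <- function(pau_rep1, pau_rep2) {
  ok <- !is.na(pau_rep1) & !is.na(pau_rep2)
  n <- sum(ok)
  if (n < 2L) return(list(r = NA_real_, n = n))
  list(r = stats::cor(pau_rep1[ok], pau_rep2[ok]), n = n)
}

#' Hierarchical clustering of samples by PPAU profile
#'
#' Distance is 1 - Pearson correlation on pairwise-complete genes; linkage
#' is average. Samples are ordered by id before clustering so that leaf
#' order is deterministic under ties.
#'
#' @param ppau gene x sample PPAU matrix (>= 3 samples).
#' @return list(hclust, cor) with the dendrogram and the pairwise Pearson
#'   matrix.
#' @export
cluster_samples_by_ppau <- function(ppau) {
  if (ncol(ppau) < 3L) stopf("cluster_samples_by_ppau: need >= 3 samples")
  ppau <- ppau[, order(colnames(ppau)), drop = FALSE]
  r <- stats::cor(ppau, use = "pairwise.complete.obs")
  d <- stats::as.dist(1 - r)
  list(hclust = stats::hclust(d, method = "average"), cor = r)
}

#' Metagene signal profile around pASs
#'
#' For each pAS, per-base track values over the +/- `flank` window in
#' transcript orientation are z-scored within the pAS (mean 0, sd 1 across
#' the window, missing bases skipped), then averaged per position across
#' pASs.
#'
#' @param track a `cons_track`-style coverage track.
#' @param pas classified pAS table (optionally pre-subset, e.g. to
#'   APA-distal sites).
#' @param flank half-window in nt (default 300).
#' @return data.frame offset (-flank..flank), mean_z, n (pASs contributing).
#' @export
metagene_signal <- function(track, pas, flank = 300) {
  offsets <- -flank:flank
  acc <- matrix(NA_real_, nrow(pas), length(offsets))
  for (i in seq_len(nrow(pas))) {
    if (pas$strand[i] == "+") {
      p <- pas$start[i] + offsets
    } else {
      p <- pas$start[i] - offsets
    }
    v <- conservation_at(track, pas$chrom[i], p)
    mu <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (is.finite(s) && s > 0) acc[i, ] <- (v - mu) / s
    else if (is.finite(mu)) acc[i, ] <- ifelse(is.na(v), NA_real_, 0)
  }
  data.frame(offset = offsets,
             mean_z = colMeans(acc, na.rm = TRUE),
             n = colSums(!is.na(acc)))
}
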