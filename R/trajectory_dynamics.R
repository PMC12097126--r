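# Developmental PPAU trajectories: per-gene z-normalisation across ordered
# stages, k-means shape clustering with non-exhaustive (tightness-based)
# assignment, monotone trend scoring, PPAU-decreased gene selection, and
# cross-tissue overlap.

#' Replicate-mean PPAU per gene and stage for one tissue
#'
#' @param ppau gene x sample PPAU matrix.
#' @param meta sample metadata.
#' @param tissue tissue to extract.
#' @return gene x stage matrix (columns ordered by stage_index, named by
#'   stage label).
#' @export
ppau_stage_matrix <- function(ppau, meta, tissue) {
  meta <- meta[match(colnames(ppau), meta$sample_id), ]
  sel <- which(meta$tissue == tissue)
  if (!length(sel)) stopf("ppau_stage_matrix: no samples for tissue %s", tissue)
  stages <- unique(meta[sel, c("stage", "stage_index")])
  stages <- stages[order(stages$stage_index), ]
  out <- vapply(seq_len(nrow(stages)), function(i) {
    cols <- sel[meta$stage_index[sel] == stages$stage_index[i]]
    rowMeans(ppau[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(ppau)))
  out <- matrix(out, nrow = nrow(ppau))
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(rownames(ppau), stages$stage)
  attr(out, "stage_index") <- stages$stage_index
  out
}

#' Standardise PPAU trajectories to z-scores
#'
#' Each gene's trajectory is centred and scaled across stages (sd with
#' denominator n-1). Genes with fewer than `min_stages` defined stages or
#' zero variance are excluded with a reason code.
#'
#' @param mat gene x stage matrix of replicate-mean PPAU.
#' @param min_stages minimum defined stages for trend work (default 3).
#' @return list(z = gene x stage z-matrix of retained genes,
#'   excluded = data.frame gene_id, reason).
#' @export
standardize_trajectories <- function(mat, min_stages = 3) {
  n_def <- rowSums(!is.na(mat))
  sds <- apply(mat, 1, stats::sd, na.rm = TRUE)
  too_few <- n_def < min_stages | n_def < ncol(mat)
  constant <- !too_few & (is.na(sds) | sds == 0)
  keep <- !too_few & !constant
  z <- mat[keep, , drop = FALSE]
  mu <- rowMeans(z)
  z <- (z - mu) / sds[keep]
  excluded <- data.frame(
    gene_id = c(rownames(mat)[too_few], rownames(mat)[constant]),
    reason = c(rep("too_few_stages", sum(too_few)), rep("constant", sum(constant))),
    stringsAsFactors = FALSE
  )
  list(z = z, excluded = excluded)
}

#' Spearman trend score of a trajectory
#'
#' Rank correlation between the trajectory values and the stage index; ties
#' are mid-ranked. Invariant to any strictly monotone transform of the
#' values.
#'
#' @param values trajectory values.
#' @param stages stage indices (default 1..n).
#' @return Spearman's rho.
#' @export
trend_score <- function(values, stages = seq_along(values)) {
  ok <- !is.na(values) & !is.na(stages)
  if (sum(ok) < 3L) return(NA_real_)
  suppressWarnings(stats::cor(values[ok], stages[ok], method = "spearman"))
}

#' Cluster standardized PPAU trajectories
#'
#' k-means on z-trajectories with `n_start` restarts under a fixed seed; k
#' is chosen by mean silhouette width over `k_range` (k = 1 is accepted as
#' a fallback when silhouette is undefined, i.e. the range collapses).
#' Members farther than the tightness radius from their centroid are
#' released as unassigned, emulating non-exhaustive cluster extraction.
#' The radius is per cluster: the mean member-to-centroid distance plus
#' `tightness_mult` times its sd within the cluster.
#'
#' @param z gene x stage z-matrix (>= 10 genes).
#' @param k_range candidate cluster counts (default 2:6); a single value
#'   fixes k.
#' @param seed RNG seed (mandatory; clustering is deterministic given it).
#' @param n_start k-means restarts (default 20).
#' @param tightness_mult multiplier on the within-cluster distance sd
#'   (default 1).
#' @return list(assignment = named integer vector, 0 = unassigned;
#'   centroids = k x stage matrix; k; radius = per-cluster release radii;
#'   silhouette = per-k mean widths).
#' @export
cluster_trajectories <- function(z, k_range = 2:6, seed, n_start = 20,
                                 tightness_mult = 1) {
  if (missing(seed)) stopf("cluster_trajectories: seed is mandatory")
  if (nrow(z) < 10L) stopf("cluster_trajectories: need >= 10 genes")
  z <- z[order(rownames(z)), , drop = FALSE]   # permutation invariance
  k_range <- k_range[k_range < nrow(z)]
  if (!length(k_range)) k_range <- 1L
  sil <- rep(NA_real_, length(k_range))
  fits <- vector("list", length(k_range))
  d <- NULL
  if (any(k_range > 1)) d <- stats::dist(z)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(.derive_seed(seed, k))
    fits[[i]] <- stats::kmeans(z, centers = k, nstart = n_start, iter.max = 100)
    if (k > 1) {
      sw <- cluster::silhouette(fits[[i]]$cluster, d)
      sil[i] <- mean(sw[, "sil_width"])
    }
  }
  best <- if (all(is.na(sil))) 1L else which.max(sil)
  fit <- fits[[best]]
  centroids <- fit$centers
  assign <- fit$cluster
  dist_to_centroid <- sqrt(rowSums((z - centroids[assign, , drop = FALSE])^2))
  mu_d <- tapply(dist_to_centroid, assign, mean)
  sd_d <- tapply(dist_to_centroid, assign, stats::sd)
  sd_d[!is.finite(sd_d)] <- 0
  radius <- mu_d + tightness_mult * sd_d
  assign[dist_to_centroid > radius[as.character(assign)]] <- 0L
  names(assign) <- rownames(z)
  list(assignment = assign, centroids = centroids, k = k_range[best],
       radius = radius, silhouette = stats::setNames(sil, k_range))
}

#' Select genes with a decreasing PPAU pattern
#'
#' Clusters whose centroid has a negative Spearman trend against stage are
#' selected; their assigned members are reported with individual trend
#' scores, and members whose own rho is not negative are dropped (the
#' selected set is guaranteed all-negative). When the raw replicate-mean
#' PPAU matrix is supplied, members must additionally show a significant
#' overall decline: last-stage minus first-stage PPAU <= -`min_delta`
#' (default 20, the usual significance gate for PPAU change). Shape
#' clustering finds trajectories that look decreasing; the delta gate
#' keeps only those whose decline is also large on the PPAU scale.
#'
#' @param clusters result of [cluster_trajectories()].
#' @param z the z-matrix that was clustered.
#' @param stages stage indices (default 1..ncol).
#' @param ppau_mat optional gene x stage replicate-mean PPAU matrix (same
#'   stage order as `z`) for the delta gate.
#' @param min_delta minimum PPAU decline when `ppau_mat` is given.
#' @return list(genes = data.frame gene_id, cluster_id, rho, delta_ppau;
#'   clusters = data.frame cluster_id, centroid_rho, n_members, selected;
#'   summary = list(mean_rho, sd_rho)).
#' @export
select_ppau_decreased <- function(clusters, z, stages = seq_len(ncol(z)),
                                  ppau_mat = NULL, min_delta = 20) {
  cent_rho <- apply(clusters$centroids, 1, trend_score, stages = stages)
  sel_clusters <- which(cent_rho < 0)
  cl_tab <- data.frame(cluster_id = seq_along(cent_rho),
                       centroid_rho = cent_rho,
                       n_members = as.integer(table(factor(clusters$assignment,
                                                           levels = seq_along(cent_rho)))),
                       selected = seq_along(cent_rho) %in% sel_clusters)
  genes <- names(clusters$assignment)[clusters$assignment %in% sel_clusters]
  if (length(genes)) {
    rho <- apply(z[genes, , drop = FALSE], 1, trend_score, stages = stages)
    keep <- !is.na(rho) & rho < 0
    delta <- rep(NA_real_, length(genes))
    if (!is.null(ppau_mat)) {
      delta <- ppau_mat[genes, ncol(ppau_mat)] - ppau_mat[genes, 1]
      keep <- keep & !is.na(delta) & delta <= -min_delta
    }
    gene_df <- data.frame(gene_id = genes[keep],
                          cluster_id = clusters$assignment[genes][keep],
                          rho = rho[keep], delta_ppau = delta[keep],
                          stringsAsFactors = FALSE)
  } else {
    gene_df <- data.frame(gene_id = character(), cluster_id = integer(),
                          rho = numeric(), delta_ppau = numeric(),
                          stringsAsFactors = FALSE)
  }
  rownames(gene_df) <- NULL
  list(genes = gene_df, clusters = cl_tab,
       summary = list(mean_rho = mean(gene_df$rho), sd_rho = stats::sd(gene_df$rho)))
}

#' Cross-tissue overlap of gene sets
#'
#' @param gene_sets named list of character vectors (one per tissue).
#' @param m minimum number of tissues for the "shared" count (default 2).
#' @return list(membership = gene x tissue logical matrix, n_total,
#'   n_shared = genes in >= m sets, fraction_shared, counts_by_k = table of
#'   genes by number of sets containing them).
#' @export
cross_tissue_overlap <- function(gene_sets, m = 2) {
  all_genes <- sort(unique(unlist(gene_sets)))
  mem <- sapply(gene_sets, function(s) all_genes %in% s)
  if (!is.matrix(mem)) mem <- matrix(mem, nrow = length(all_genes),
                                     dimnames = list(NULL, names(gene_sets)))
  rownames(mem) <- all_genes
  k <- rowSums(mem)
  list(membership = mem,
       n_total = length(all_genes),
       n_shared = sum(k >= m),
       fraction_shared = if (length(all_genes)) sum(k >= m) / length(all_genes) else NA_real_,
       counts_by_k = table(k))
}

#' Filter RBPs by co-expression trend across stages
#'
#' Keeps RBPs whose expression trajectory has |Spearman rho| >= `rho_min`
#' against the stage index, in all (default) or any of the given tissues.
#'
#' @param rbp_tpm list (per tissue) of RBP x stage TPM matrices, or a
#'   single matrix (treated as one tissue).
#' @param rho_min minimum |rho| (default 0.7).
#' @param scope "all" or "any" tissue must satisfy the criterion.
#' @return data.frame rbp_id, one rho column per tissue, kept.
#' @export
rbp_coexpression_filter <- function(rbp_tpm, rho_min = 0.7,
                                    scope = c("all", "any")) {
  scope <- match.arg(scope)
  if (is.matrix(rbp_tpm)) rbp_tpm <- list(tissue = rbp_tpm)
  rbps <- rownames(rbp_tpm[[1]])
  rho <- sapply(rbp_tpm, function(m)
    apply(m[rbps, , drop = FALSE], 1, trend_score))
  if (!is.matrix(rho)) rho <- matrix(rho, nrow = length(rbps),
                                     dimnames = list(rbps, names(rbp_tpm)))
  pass <- abs(rho) >= rho_min
  kept <- if (scope == "all") rowSums(pass, na.rm = TRUE) == ncol(pass) &
            !apply(is.na(pass), 1, any)
          else rowSums(pass, na.rm = TRUE) > 0
  out <- data.frame(rbp_id = rbps, rho, kept = kept, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
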