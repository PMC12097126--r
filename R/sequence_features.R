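# Sequence determinants of pAS choice: polyA-signal hexamers in the
# upstream 50 nt, the +1 nucleotide, positional composition and logos,
# conservation profiles with coding masking, and signal x +1A association.
#
# DNA alphabet is used internally (AATAAA); output labels may be rendered
# as RNA (AAUAAA) by the caller.

#' The shipped polyA-signal hexamer catalog
#'
#' Eighteen hexamers reported as functional polyA signals, ordered by
#' priority (strongest first: AATAAA, then ATTAAA). The catalog is shipped
#' as data (`inst/extdata/polya_signals.txt`), seeded from the PolyASite
#' signal compendium; users should verify or substitute their own list via
#' the `catalog` arguments.
#'
#' @return character vector of 18 hexamers in priority order.
#' @export
default_signal_catalog <- function() {
  path <- system.file("extdata", "polya_signals.txt", package = "apadyn")
  cat_ <- readLines(path)
  cat_ <- cat_[!startsWith(cat_, "#") & nzchar(cat_)]
  validate_signal_catalog(cat_)
}

#' Validate a polyA-signal catalog
#'
#' @param catalog character vector of DNA hexamers in priority order.
#' @return the catalog, invisibly checked (all length 6, unique, AATAAA
#'   first and ATTAAA second).
#' @export
validate_signal_catalog <- function(catalog) {
  if (any(nchar(catalog) != 6L)) stopf("signal catalog: all entries must be hexamers")
  if (anyDuplicated(catalog)) stopf("signal catalog: entries must be unique")
  if (catalog[1] != "AATAAA" || catalog[2] != "ATTAAA")
    stopf("signal catalog: AATAAA must be first and ATTAAA second")
  catalog
}

# 0-based half-open slice of a chromosome string, N-padded out of bounds.
.slice_padded <- function(chrom_str, from0, to0) {
  L <- nchar(chrom_str)
  lo <- pmax(from0, 0L)
  hi <- pmin(to0, L)
  core <- ifelse(hi > lo, substring(chrom_str, lo + 1L, hi), "")
  left <- pmax(0L, -from0)
  right <- pmax(0L, to0 - L)
  paste0(strrep("N", left), core, strrep("N", right))
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract sequence windows around pASs
#'
#' Returns, per pAS and in transcript orientation, the 50-nt (default)
#' upstream sequence (positions -flank..-1), the cleavage-site base, and
#' the downstream sequence (+1..+flank); minus-strand windows are
#' reverse-complemented. Windows running off a chromosome end are N-padded.
#'
#' @param genome DNAStringSet.
#' @param pas classified pAS table.
#' @param flank window half-width in nt (default 50).
#' @return data.frame pas_id, gene_id, pas_class, upstream, center,
#'   downstream, plus_one.
#' @export
extract_pas_windows <- function(genome, pas, flank = 50) {
  missing_chr <- setdiff(unique(pas$chrom), names(genome))
  if (length(missing_chr))
    stopf("extract_pas_windows: chromosome %s absent from genome", missing_chr[1])
  up <- character(nrow(pas)); ctr <- character(nrow(pas)); down <- character(nrow(pas))
  for (ch in unique(pas$chrom)) {
    idx <- which(pas$chrom == ch)
    str <- as.character(genome[[ch]])
    s <- pas$start[idx]
    plus <- pas$strand[idx] == "+"
    ip <- idx[plus]; im <- idx[!plus]
    if (length(ip)) {
      sp <- s[plus]
      up[ip] <- .slice_padded(str, sp - flank, sp)
      ctr[ip] <- .slice_padded(str, sp, sp + 1L)
      down[ip] <- .slice_padded(str, sp + 1L, sp + 1L + flank)
    }
    if (length(im)) {
      sm <- s[!plus]
      up[im] <- .revcomp_chr(.slice_padded(str, sm + 1L, sm + 1L + flank))
      ctr[im] <- .revcomp_chr(.slice_padded(str, sm, sm + 1L))
      down[im] <- .revcomp_chr(.slice_padded(str, sm - flank, sm))
    }
  }
  data.frame(
    pas_id = pas$pas_id,
    gene_id = pas$gene_id,
    pas_class = if ("pas_class" %in% names(pas)) pas$pas_class else NA_character_,
    upstream = toupper(up),
    center = toupper(ctr),
    downstream = toupper(down),
    plus_one = substr(toupper(down), 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Assign a polyA signal to each pAS window
#'
#' Scans the upstream sequence for catalog hexamers. When several catalog
#' entries occur, the one earliest in catalog priority wins; among multiple
#' occurrences of that hexamer the one closest to the pAS is reported.
#'
#' @param windows data.frame from [extract_pas_windows()] (uses `upstream`).
#' @param catalog hexamer catalog (default [default_signal_catalog()]).
#' @return data.frame pas_id, signal ("none" if no hit), offset (0-based
#'   start of the hexamer relative to the pAS, e.g. -20; NA for "none").
#' @export
assign_polya_signal <- function(windows, catalog = default_signal_catalog()) {
  validate_signal_catalog(catalog)
  up <- windows$upstream
  w <- nchar(up)
  signal <- rep("none", length(up))
  offset <- rep(NA_integer_, length(up))
  todo <- rep(TRUE, length(up))
  for (h in catalog) {
    if (!any(todo)) break
    hits <- gregexpr(h, up[todo], fixed = TRUE)
    pos <- vapply(hits, function(p) max(p), 0L)   # -1 when absent
    found <- pos > 0L
    ti <- which(todo)[found]
    signal[ti] <- h
    offset[ti] <- pos[found] - w[ti] - 1L         # 1-based pos j -> j - w - 1
    todo[ti] <- FALSE
  }
  data.frame(pas_id = windows$pas_id, signal = signal, offset = offset,
             stringsAsFactors = FALSE)
}

#' PolyA-signal frequencies per positional pAS class
#'
#' @param windows pAS windows with `pas_class`.
#' @param catalog hexamer catalog.
#' @return data.frame pas_class, signal (catalog entries and "none"),
#'   count, frequency; frequencies within a class sum to 1.
#' @export
signal_frequency_by_class <- function(windows, catalog = default_signal_catalog()) {
  asg <- assign_polya_signal(windows, catalog)
  cls <- windows$pas_class
  lev <- c(catalog, "none")
  out <- do.call(rbind, lapply(unique(cls), function(k) {
    s <- factor(asg$signal[cls == k], levels = lev)
    tab <- table(s)
    data.frame(pas_class = k, signal = lev, count = as.integer(tab),
               frequency = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Frequency of adenine at the +1 position per pAS class
#'
#' @param windows pAS windows with `pas_class` and `plus_one`.
#' @return data.frame pas_class, n, freq_a (NA with a warning for an empty
#'   class).
#' @export
plus_one_frequency <- function(windows) {
  cls <- unique(windows$pas_class)
  out <- do.call(rbind, lapply(cls, function(k) {
    p1 <- windows$plus_one[windows$pas_class == k]
    p1 <- p1[p1 %in% c("A", "C", "G", "T")]
    if (!length(p1)) {
      warnf("plus_one_frequency: class %s has no usable windows", k)
      return(data.frame(pas_class = k, n = 0L, freq_a = NA_real_))
    }
    data.frame(pas_class = k, n = length(p1), freq_a = mean(p1 == "A"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.window_char_matrix <- function(windows, max_n_frac = 0.1) {
  full <- paste0(windows$upstream, windows$center, windows$downstream)
  keep <- nchar(full) == max(nchar(full))
  mat <- do.call(rbind, strsplit(full[keep], "", fixed = TRUE))
  n_frac <- rowMeans(mat == "N")
  mat[n_frac <= max_n_frac, , drop = FALSE]
}

#' Positional nucleotide composition around pASs
#'
#' Base frequencies at each position of the -flank..+flank window (the
#' cleavage-site base is position 0). N bases are excluded from each
#' position's denominator; windows with more than `max_n_frac` N are
#' dropped entirely.
#'
#' @param windows pAS windows.
#' @param max_n_frac maximum tolerated N fraction per window (default 0.1).
#' @return data.frame offset, A, C, G, T; each row sums to 1.
#' @export
composition_profile <- function(windows, max_n_frac = 0.1) {
  mat <- .window_char_matrix(windows, max_n_frac)
  if (!nrow(mat)) stopf("composition_profile: no usable windows")
  flank <- (ncol(mat) - 1L) / 2L
  counts <- vapply(c("A", "C", "G", "T"), function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  counts <- matrix(counts, ncol = 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  freq <- counts / rowSums(counts)
  data.frame(offset = -flank:flank, freq, check.names = FALSE)
}

#' Position frequency matrix and information content for logo rendering
#'
#' @param windows pAS windows.
#' @param span integer vector `c(from, to)` of offsets to include (default
#'   the full window).
#' @param max_n_frac maximum tolerated N fraction per window.
#' @return list(pfm = positions x ACGT probability matrix, ic = per-position
#'   information content in bits, 2 - Shannon entropy of the column).
#' @export
position_frequency_matrix <- function(windows, span = NULL, max_n_frac = 0.1) {
  comp <- composition_profile(windows, max_n_frac)
  if (!is.null(span)) comp <- comp[comp$offset >= span[1] & comp$offset <= span[2], ]
  pfm <- as.matrix(comp[, c("A", "C", "G", "T")])
  rownames(pfm) <- comp$offset
  ent <- apply(pfm, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  list(pfm = pfm, ic = 2 - ent)
}

#' Mean conservation profiles around pASs, with coding masking
#'
#' Per-base track values over the +/- `flank` window (transcript
#' orientation); bases overlapping the coding mask and bases with no track
#' value are excluded from all averages (never imputed as 0).
#'
#' @param pas classified pAS table.
#' @param track conservation `cons_track`.
#' @param coding_mask GRanges of protein-coding positions, or NULL.
#' @param flank half-window in nt (default 200).
#' @return list(profile = data.frame pas_class, offset, mean_score, n;
#'   per_pas = data.frame pas_id, pas_class, mean_score, n_used).
#' @export
mean_conservation <- function(pas, track, coding_mask = NULL, flank = 200) {
  mask_track <- NULL
  if (!is.null(coding_mask) && length(coding_mask)) {
    red <- GenomicRanges::reduce(coding_mask, ignore.strand = TRUE)
    mask_track <- cons_track(data.frame(
      chrom = as.character(GenomicRanges::seqnames(red)),
      start = GenomicRanges::start(red) - 1L,
      end = GenomicRanges::end(red),
      score = 1,
      stringsAsFactors = FALSE
    ))
  }
  offsets <- -flank:flank
  vals <- matrix(NA_real_, nrow(pas), length(offsets))
  for (i in seq_len(nrow(pas))) {
    p <- if (pas$strand[i] == "+") pas$start[i] + offsets else pas$start[i] - offsets
    v <- conservation_at(track, pas$chrom[i], p)
    if (!is.null(mask_track)) {
      masked <- !is.na(conservation_at(mask_track, pas$chrom[i], p))
      v[masked] <- NA_real_
    }
    vals[i, ] <- v
  }
  cls <- pas$pas_class
  profile <- do.call(rbind, lapply(unique(cls), function(k) {
    sub <- vals[cls == k, , drop = FALSE]
    data.frame(pas_class = k, offset = offsets,
               mean_score = colMeans(sub, na.rm = TRUE),
               n = colSums(!is.na(sub)), stringsAsFactors = FALSE)
  }))
  profile$mean_score[is.nan(profile$mean_score)] <- NA_real_
  per_pas <- data.frame(pas_id = pas$pas_id, pas_class = cls,
                        mean_score = rowMeans(vals, na.rm = TRUE),
                        n_used = rowSums(!is.na(vals)),
                        stringsAsFactors = FALSE)
  per_pas$mean_score[is.nan(per_pas$mean_score)] <- NA_real_
  rownames(profile) <- NULL
  list(profile = profile, per_pas = per_pas)
}

#' Chi-squared test of independence on a 2x2 table
#'
#' Pearson statistic sum (O - E)^2 / E on 1 df; no continuity correction by
#' default.
#'
#' @param tab 2x2 count matrix.
#' @param correct apply Yates continuity correction.
#' @return list(statistic, p).
#' @export
chi_squared_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stopf("chi_squared_2x2: need a 2x2 table")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(e == 0)) return(list(statistic = NA_real_, p = NA_real_))
  d <- abs(tab - e)
  if (correct) d <- pmax(0, d - 0.5)
  stat <- sum(d^2 / e)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Association between the canonical signal and +1 adenine, per pAS class
#'
#' For each positional class, a 2x2 table of {AATAAA in the upstream 50 nt:
#' yes/no} x {+1 base is A: yes/no} with the chi-squared statistic and the
#' four joint-category percentages.
#'
#' @param windows pAS windows with `pas_class`.
#' @param catalog hexamer catalog.
#' @param correct Yates continuity correction (default FALSE).
#' @return data.frame per class: counts (n_sig_a, n_sig_nota, n_nosig_a,
#'   n_nosig_nota), the corresponding percentages, statistic and p.
#' @export
signal_plus_one_association <- function(windows, catalog = default_signal_catalog(),
                                        correct = FALSE) {
  asg <- assign_polya_signal(windows, catalog)
  has_sig <- asg$signal == "AATAAA"
  plus_a <- windows$plus_one == "A"
  cls <- windows$pas_class
  out <- do.call(rbind, lapply(unique(cls), function(k) {
    i <- cls == k
    tab <- matrix(c(sum(has_sig[i] & plus_a[i]), sum(has_sig[i] & !plus_a[i]),
                    sum(!has_sig[i] & plus_a[i]), sum(!has_sig[i] & !plus_a[i])),
                  2, 2, byrow = TRUE)
    ct <- chi_squared_2x2(tab, correct = correct)
    n <- sum(tab)
    data.frame(pas_class = k,
               n_sig_a = tab[1, 1], n_sig_nota = tab[1, 2],
               n_nosig_a = tab[2, 1], n_nosig_nota = tab[2, 2],
               pct_sig_a = 100 * tab[1, 1] / n, pct_sig_nota = 100 * tab[1, 2] / n,
               pct_nosig_a = 100 * tab[2, 1] / n, pct_nosig_nota = 100 * tab[2, 2] / n,
               statistic = ct$statistic, p = ct$p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' PAU stratified by sequence features, per pAS class
#'
#' Each pAS's PAU is first averaged across samples, then compared between
#' feature groups ({has AATAAA vs not} and {+1 A vs not}) within each
#' positional class, with a Wilcoxon rank-sum p-value.
#'
#' @param pau a `pau_table`.
#' @param pas classified pAS table.
#' @param windows pAS windows for the same pASs.
#' @param catalog hexamer catalog.
#' @return data.frame pas_class, feature, mean_with, mean_without, n_with,
#'   n_without, p.
#' @export
pau_by_feature <- function(pau, pas, windows, catalog = default_signal_catalog()) {
  key <- paste(pas$gene_id, pas$pas_id, sep = "|")
  mean_pau <- rowMeans(pau$pau[key, , drop = FALSE], na.rm = TRUE)
  asg <- assign_polya_signal(windows, catalog)
  m <- match(pas$pas_id, windows$pas_id)
  feats <- list(AATAAA = (asg$signal == "AATAAA")[m],
                plus_one_A = (windows$plus_one == "A")[m])
  out <- do.call(rbind, lapply(unique(pas$pas_class), function(k) {
    i <- pas$pas_class == k & !is.nan(mean_pau)
    do.call(rbind, lapply(names(feats), function(f) {
      g <- feats[[f]][i]
      v <- mean_pau[i]
      if (!any(g) || !any(!g)) {
        warnf("pau_by_feature: class %s, feature %s: a group is empty", k, f)
        return(data.frame(pas_class = k, feature = f,
                          mean_with = if (any(g)) mean(v[g]) else NA_real_,
                          mean_without = if (any(!g)) mean(v[!g]) else NA_real_,
                          n_with = sum(g), n_without = sum(!g), p = NA_real_,
                          stringsAsFactors = FALSE))
      }
      p <- stats::wilcox.test(v[g], v[!g], exact = FALSE)$p.value
      data.frame(pas_class = k, feature = f,
                 mean_with = mean(v[g]), mean_without = mean(v[!g]),
                 n_with = sum(g), n_without = sum(!g), p = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
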