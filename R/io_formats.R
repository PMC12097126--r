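# Readers and writers for every external format the pipeline touches.
#
# Conventions (uniform across the package):
#   * BED/bedGraph files are 0-based half-open, as in the BED standard; no
#     auto-correction of 1-based-looking coordinates is ever attempted.
#   * pAS point features have end = start + 1; the cleavage site is the base
#     whose 3' neighbour on the transcript strand is position +1.
#   * Plain data.frames carry the 0-based convention; interval arithmetic is
#     done on GRanges (converted internally).
#   * Every reader rejects malformed input instead of silently repairing it.

.read_lines_checked <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines[nzchar(trimws(lines))]
}

.split_bed_fields <- function(lines, path, min_fields) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < min_fields)
  if (length(bad))
    stopf("%s: malformed line %d: expected >= %d tab-separated fields, got %d",
          path, bad[1], min_fields, n[bad[1]])
  fields
}

.parse_coord <- function(x, path, what) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v))
  if (length(bad))
    stopf("%s: malformed line %d: non-integer %s '%s'", path, bad[1], what, x[bad[1]])
  v
}

.check_interval_frame <- function(df, path) {
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad))
    stopf("%s: malformed line %d: require 0 <= start < end (got %d, %d)",
          path, bad[1], df$start[bad[1]], df$end[bad[1]])
  invisible(df)
}

#' Read a polyA-site BED6 file
#'
#' pAS annotations are point features (`end - start == 1`) whose single base
#' is the cleavage site. Records with score below `min_score` are dropped
#' (the PolyASite-style confidence filter); records with a missing score
#' (`.`) are dropped whenever `min_score > -Inf`. The BED name field is
#' expected to be `gene:pas`; a name without `:` is used as both gene and
#' pAS id.
#'
#' @param path BED6 file.
#' @param min_score minimum score to keep a record (default 4).
#' @return data.frame with columns gene_id, pas_id, chrom, start, end,
#'   strand, score, sorted by (chrom, start). Coordinates are 0-based
#'   half-open.
#' @export
read_pas_bed <- function(path, min_score = 4) {
  lines <- .read_lines_checked(path)
  if (!length(lines))
    return(data.frame(gene_id = character(), pas_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  fields <- .split_bed_fields(lines, path, 6L)
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  df <- data.frame(
    chrom = m[, 1],
    start = .parse_coord(m[, 2], path, "start"),
    end = .parse_coord(m[, 3], path, "end"),
    name = m[, 4],
    score_raw = m[, 5],
    strand = m[, 6],
    stringsAsFactors = FALSE
  )
  .check_interval_frame(df, path)
  bad <- which(df$end - df$start != 1L)
  if (length(bad))
    stopf("%s: malformed line %d: pAS records must be point features (end - start == 1)",
          path, bad[1])
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stopf("%s: malformed line %d: strand must be '+' or '-', got '%s'",
          path, bad[1], df$strand[bad[1]])
  score <- suppressWarnings(as.numeric(df$score_raw))
  bad <- which(is.na(score) & df$score_raw != ".")
  if (length(bad))
    stopf("%s: malformed line %d: score must be numeric or '.', got '%s'",
          path, bad[1], df$score_raw[bad[1]])
  keep <- !is.na(score) & score >= min_score
  if (is.infinite(min_score) && min_score < 0) keep <- keep | is.na(score)
  df <- df[keep, , drop = FALSE]
  score <- score[keep]
  gene_id <- sub(":.*$", "", df$name)
  out <- data.frame(
    gene_id = gene_id,
    pas_id = df$name,
    chrom = df$chrom,
    start = df$start,
    end = df$end,
    strand = df$strand,
    score = score,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a BED6 interval file (optionally with a 7th family column)
#'
#' Used for miRNA binding sites, CLIP peaks, coding masks and transposable
#' elements (`family = TRUE` reads the 7th column as the TE family label).
#'
#' @param path BED file.
#' @param family read a 7th column as `family`.
#' @return GRanges with mcols name, score (NA for `.`) and optionally family.
#' @export
read_intervals_bed <- function(path, family = FALSE) {
  lines <- .read_lines_checked(path)
  min_fields <- if (family) 7L else 6L
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$name <- character()
    S4Vectors::mcols(gr)$score <- numeric()
    if (family) S4Vectors::mcols(gr)$family <- character()
    return(gr)
  }
  fields <- .split_bed_fields(lines, path, min_fields)
  m <- do.call(rbind, lapply(fields, `[`, seq_len(min_fields)))
  df <- data.frame(
    chrom = m[, 1],
    start = .parse_coord(m[, 2], path, "start"),
    end = .parse_coord(m[, 3], path, "end"),
    name = m[, 4],
    score_raw = m[, 5],
    strand = m[, 6],
    stringsAsFactors = FALSE
  )
  .check_interval_frame(df, path)
  bad <- which(!df$strand %in% c("+", "-", "."))
  if (length(bad))
    stopf("%s: malformed line %d: strand must be '+', '-' or '.'", path, bad[1])
  score <- suppressWarnings(as.numeric(df$score_raw))
  bad <- which(is.na(score) & df$score_raw != ".")
  if (length(bad))
    stopf("%s: malformed line %d: score must be numeric or '.'", path, bad[1])
  df$strand[df$strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$name <- df$name
  S4Vectors::mcols(gr)$score <- score
  if (family) S4Vectors::mcols(gr)$family <- m[, 7]
  gr
}

#' Write intervals as BED6 (optionally + family column)
#'
#' @param gr GRanges with mcols name/score (and family if `family = TRUE`).
#' @param path output path.
#' @param family also write the family column.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(gr, path, family = FALSE) {
  df <- .granges_to_df(gr)
  df$strand[df$strand == "*"] <- "."
  score <- ifelse(is.na(df$score), ".", format(df$score, trim = TRUE, scientific = FALSE))
  cols <- list(df$chrom, df$start, df$end, df$name, score, df$strand)
  if (family) cols <- c(cols, list(df$family))
  out <- do.call(paste, c(cols, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Read an isoform-level quantification table
#'
#' TSV with header `gene_id`, `pas_id`, then one column per sample holding
#' TPM values. Duplicate (gene, pAS) keys and negative or non-finite values
#' are rejected.
#'
#' @param path TSV file.
#' @return a `quant_table`: list with `tpm` (matrix, rows = pASs keyed
#'   `gene|pas`, columns = samples), `gene_id`, `pas_id`.
#' @export
read_quant_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  .check_df_cols(df, c("gene_id", "pas_id"), path)
  samples <- setdiff(names(df), c("gene_id", "pas_id"))
  if (!length(samples)) stopf("%s: no sample columns", path)
  quant_table(df$gene_id, df$pas_id,
              as.matrix(df[, samples, drop = FALSE]))
}

#' Construct a quant_table
#'
#' @param gene_id,pas_id parallel id vectors.
#' @param tpm numeric matrix of TPM, one row per (gene, pAS), one column per
#'   sample (column names are sample ids).
#' @return a `quant_table` object.
#' @export
quant_table <- function(gene_id, pas_id, tpm) {
  tpm <- as.matrix(tpm)
  mode(tpm) <- "double"
  if (length(gene_id) != nrow(tpm) || length(pas_id) != nrow(tpm))
    stopf("quant_table: gene_id/pas_id length must match nrow(tpm)")
  key <- paste(gene_id, pas_id, sep = "|")
  if (anyDuplicated(key))
    stopf("quant_table: duplicate (gene_id, pas_id) key: %s", key[duplicated(key)][1])
  if (any(!is.finite(tpm)))
    stopf("quant_table: all TPM values must be finite")
  if (any(tpm < 0))
    stopf("quant_table: negative TPM values are not allowed")
  if (is.null(colnames(tpm))) stopf("quant_table: tpm must have sample column names")
  rownames(tpm) <- key
  structure(list(tpm = tpm, gene_id = as.character(gene_id),
                 pas_id = as.character(pas_id)),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d pASs x %d samples, %d genes\n",
              nrow(x$tpm), ncol(x$tpm), length(unique(x$gene_id))))
  invisible(x)
}

#' Write a quant_table as TSV
#'
#' @param x quant_table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(x, path) {
  df <- data.frame(gene_id = x$gene_id, pas_id = x$pas_id,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(x$tpm, check.names = FALSE))
  write_tsv_table(df, path)
}

#' Read sample metadata
#'
#' TSV with columns sample_id, tissue, stage, replicate and optionally
#' stage_index. If stage_index is absent, stages are ordered by first
#' appearance within the file (a total order shared across tissues).
#'
#' @param path TSV file.
#' @return data.frame with sample_id, tissue, stage, stage_index, replicate.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .check_df_cols(df, c("sample_id", "tissue", "stage", "replicate"), path)
  if (!"stage_index" %in% names(df)) {
    lev <- unique(df$stage)
    df$stage_index <- match(df$stage, lev) - 1L
  }
  key <- paste(df$tissue, df$stage, df$replicate)
  if (anyDuplicated(key))
    stopf("%s: duplicate (tissue, stage, replicate): %s", path, key[duplicated(key)][1])
  if (anyDuplicated(df$sample_id))
    stopf("%s: duplicate sample_id", path)
  df[, c("sample_id", "tissue", "stage", "stage_index", "replicate")]
}

#' Read a per-base conservation track from bedGraph
#'
#' Intervals must be non-overlapping within a chromosome. Bases not covered
#' by any interval have a missing score (never zero-filled).
#'
#' @param path bedGraph file (chrom, start, end, score; 0-based half-open).
#' @return a `cons_track` object queried with [conservation_at()].
#' @export
read_conservation_bedgraph <- function(path) {
  lines <- .read_lines_checked(path)
  if (!length(lines)) {
    df <- data.frame(chrom = character(), start = integer(), end = integer(),
                     score = numeric(), stringsAsFactors = FALSE)
    return(cons_track(df))
  }
  fields <- .split_bed_fields(lines, path, 4L)
  m <- do.call(rbind, lapply(fields, `[`, 1:4))
  df <- data.frame(
    chrom = m[, 1],
    start = .parse_coord(m[, 2], path, "start"),
    end = .parse_coord(m[, 3], path, "end"),
    score = suppressWarnings(as.numeric(m[, 4])),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$score))
  if (length(bad)) stopf("%s: malformed line %d: non-numeric score", path, bad[1])
  .check_interval_frame(df, path)
  cons_track(df)
}

#' Construct a conservation track from an interval data.frame
#'
#' @param df data.frame chrom, start, end, score (0-based half-open).
#' @return a `cons_track` object.
#' @export
cons_track <- function(df) {
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  by_chrom <- split(df, df$chrom)
  for (ch in names(by_chrom)) {
    d <- by_chrom[[ch]]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stopf("cons_track: overlapping intervals on %s", ch)
  }
  structure(list(by_chrom = by_chrom), class = "cons_track")
}

#' @export
print.cons_track <- function(x, ...) {
  n <- sum(vapply(x$by_chrom, nrow, 0L))
  cat(sprintf("cons_track: %d intervals on %d chromosome(s)\n",
              n, length(x$by_chrom)))
  invisible(x)
}

#' Query a conservation track at single bases
#'
#' @param track cons_track.
#' @param chrom chromosome (scalar or vector recycled against `pos`).
#' @param pos 0-based base positions.
#' @return numeric vector of scores, NA where no interval covers the base.
#' @export
conservation_at <- function(track, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n)
  pos <- rep_len(as.integer(pos), n)
  out <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    d <- track$by_chrom[[ch]]
    idx <- which(chrom == ch)
    if (is.null(d) || !nrow(d)) next
    # intervals are sorted and disjoint: locate by binary search on start
    i <- findInterval(pos[idx], d$start)
    ok <- i >= 1L
    okk <- ok
    okk[ok] <- pos[idx][ok] < d$end[i[ok]]
    out[idx[okk]] <- d$score[i[okk]]
  }
  out
}

#' Write a conservation track as bedGraph
#'
#' @param track cons_track.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conservation_bedgraph <- function(track, path) {
  df <- do.call(rbind, track$by_chrom)
  if (is.null(df)) df <- data.frame(chrom = character(), start = integer(),
                                    end = integer(), score = numeric())
  writeLines(paste(df$chrom, df$start, df$end,
                   sprintf("%.6f", df$score), sep = "\t"), path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return Biostrings::DNAStringSet, names truncated at the first whitespace.
#' @export
read_genome_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Write a genome FASTA
#'
#' @param genome DNAStringSet.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Read position weight matrices in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` headers over the
#' DNA alphabet. Each matrix row (position) must sum to 1 within 1e-6.
#'
#' @param path MEME minimal-format motif file.
#' @return named list of numeric matrices (positions x A,C,G,T).
#' @export
read_meme_pwms <- function(path) {
  lines <- readLines(path)
  motif_idx <- grep("^MOTIF\\s+", lines)
  if (!length(motif_idx)) stopf("%s: no MOTIF blocks found", path)
  pwms <- list()
  for (k in seq_along(motif_idx)) {
    i <- motif_idx[k]
    id <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[i])), "\\s+")[[1]][1]
    j <- i + 1L
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) {
      if (j %in% motif_idx) stopf("%s: MOTIF %s has no probability matrix", path, id)
      j <- j + 1L
    }
    if (j > length(lines)) stopf("%s: MOTIF %s has no probability matrix", path, id)
    w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j])))
    if (is.na(w)) stopf("%s: MOTIF %s: cannot parse matrix width", path, id)
    rows <- lines[(j + 1L):(j + w)]
    mat <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                    numeric(4)))
    dimnames(mat) <- list(NULL, c("A", "C", "G", "T"))
    bad <- which(abs(rowSums(mat) - 1) > 1e-6)
    if (length(bad))
      stopf("%s: MOTIF %s: probability row %d does not sum to 1", path, id, bad[1])
    pwms[[id]] <- mat
  }
  pwms
}

#' Write PWMs in MEME minimal format
#'
#' @param pwms named list of positions x ACGT probability matrices.
#' @param path output path.
#' @param background background base frequencies (A, C, G, T).
#' @return `path`, invisibly.
#' @export
write_meme_pwms <- function(pwms, path, background = rep(0.25, 4)) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "Background letter frequencies",
           sprintf("A %.5f C %.5f G %.5f T %.5f", background[1], background[2],
                   background[3], background[4]), "")
  for (id in names(pwms)) {
    m <- pwms[[id]]
    out <- c(out, sprintf("MOTIF %s", id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     nrow(m)),
             apply(m, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                             r[1], r[2], r[3], r[4])),
             "")
  }
  writeLines(out, path)
  invisible(path)
}
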