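# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom methods is
.check_df_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s: missing required column(s): %s", what, paste(miss, collapse = ", "))
  invisible(df)
}

# 0-based half-open data.frame intervals -> GRanges (1-based closed).
# All interval arithmetic in the package goes through GenomicRanges; plain
# data.frames keep the on-disk BED convention.
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols `mcols<-`
.df_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand %||% "*"
  )
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}

.granges_to_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(S4Vectors::mcols(gr)))
}

# Fixed-format TSV writer: column order as given, reals to 6 decimals.
.format_tsv_col <- function(x) {
  if (is.double(x)) ifelse(is.na(x), "NA", sprintf("%.6f", x)) else as.character(x)
}

#' Write a table as TSV with fixed column order and 6-decimal reals
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  out <- as.data.frame(lapply(df, .format_tsv_col), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic per-purpose RNG stream derived from a user seed: keeps the
# generator's sub-steps independent of each other while staying < 2^31.
.derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
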