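# Shared fixture builders. Everything is generated in code; no stored data.

# Independent reverse-complement used by oracles (not the package's helper).
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

# A small classified pAS table built directly (0-based half-open coords).
toy_pas <- function() {
  pas <- data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gC"),
    pas_id = c("gA:p1", "gA:p2", "gA:p3", "gB:p1", "gB:p2", "gC:p1"),
    chrom = c(rep("chr1", 3), rep("chr1", 2), "chr2"),
    start = c(200L, 300L, 500L, 1200L, 1050L, 400L),
    end = c(201L, 301L, 501L, 1201L, 1051L, 401L),
    strand = c("+", "+", "+", "-", "-", "+"),
    score = 5,
    stringsAsFactors = FALSE
  )
  stops <- c(gA = 100L, gB = 1400L, gC = 300L)
  list(pas = classify_pas(pas, stops), stops = stops)
}

# Random quant table: n_genes with 1..max_pas pASs, n_samples columns.
random_quant <- function(n_genes, n_samples, max_pas = 4, seed = 1) {
  set.seed(seed)
  n_pas <- sample.int(max_pas, n_genes, replace = TRUE)
  gene_id <- rep(sprintf("g%03d", seq_len(n_genes)), n_pas)
  pas_id <- unlist(lapply(seq_len(n_genes), function(i)
    sprintf("g%03d:p%d", i, seq_len(n_pas[i]))))
  tpm <- matrix(round(stats::rexp(length(gene_id) * n_samples, 1 / 5), 4),
                ncol = n_samples,
                dimnames = list(NULL, sprintf("s%02d", seq_len(n_samples))))
  quant_table(gene_id, pas_id, tpm)
}

write_lines_tmp <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Random toy genome as a DNAStringSet.
toy_genome <- function(lens = c(chr1 = 2000L, chr2 = 1500L), seed = 1) {
  set.seed(seed)
  gs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
  g <- Biostrings::DNAStringSet(gs)
  names(g) <- names(lens)
  g
}

# GRanges helper from 0-based half-open vectors.
gr0 <- function(chrom, start, end, strand = "*", ...) {
  gr <- if (length(chrom))
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                           strand = strand)
  else GenomicRanges::GRanges()
  mc <- list(...)
  for (nm in names(mc)) S4Vectors::mcols(gr)[[nm]] <- mc[[nm]]
  gr
}
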