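# Independent brute-force oracles and random-fixture helpers.
# These deliberately avoid IRanges and the package's own interval code.

# O(windows x genes) sliding-window counter over plain loops.
brute_window_counts <- function(gene_start, gene_end, contig_len,
                                window = 10000, step = 1000) {
  starts <- seq(0, contig_len - 1, by = step)
  counts <- integer(length(starts))
  ends <- integer(length(starts))
  for (i in seq_along(starts)) {
    w0 <- starts[i]
    w1 <- min(w0 + window, contig_len)
    ends[i] <- w1
    counts[i] <- sum(gene_start < w1 & gene_end > w0)
  }
  data.frame(start = starts, end = ends, n = counts)
}

# Paint every base into TP/FP/FN by set membership and count.
paint_eval <- function(pred, gold, contig_len) {
  contigs <- union(unique(pred$contig_id), unique(gold$contig_id))
  tp <- fp <- fn <- 0L
  for (ctg in contigs) {
    in_pred <- logical(contig_len)
    in_gold <- logical(contig_len)
    p <- pred[pred$contig_id == ctg, ]
    g <- gold[gold$contig_id == ctg, ]
    for (i in seq_len(nrow(p))) in_pred[(p$start[i] + 1):p$end[i]] <- TRUE
    for (i in seq_len(nrow(g))) in_gold[(g$start[i] + 1):g$end[i]] <- TRUE
    tp <- tp + sum(in_pred & in_gold)
    fp <- fp + sum(in_pred & !in_gold)
    fn <- fn + sum(!in_pred & in_gold)
  }
  list(tp = tp, fp = fp, fn = fn)
}

# Paint-and-extract union of intervals on one contig.
paint_union <- function(start, end, contig_len) {
  covered <- logical(contig_len)
  for (i in seq_along(start)) covered[(start[i] + 1):end[i]] <- TRUE
  r <- rle(covered)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths
  data.frame(start = starts[r$values], end = stops[r$values])
}

# Hand-coded standard codon lookup (the amino-acid map of the bacterial
# code equals the standard code; they differ only in start-codon sets).
oracle_translate <- function(dna) {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  map <- stats::setNames(aas, codons)
  n <- nchar(dna) %/% 3
  out <- character(n)
  for (i in seq_len(n)) {
    cod <- substr(dna, 3 * i - 2, 3 * i)
    out[i] <- if (cod %in% names(map)) map[[cod]] else "X"
  }
  if (n > 0 && out[n] == "*") out <- out[-n]
  out[out == "*"] <- "X"
  paste(out, collapse = "")
}

# Random single-contig gene table (0-based half-open hull intervals).
random_gene_table <- function(n_genes, contig_len, contig_id = "c1") {
  start <- sort(sample.int(contig_len - 100L, n_genes, replace = TRUE)) - 1L
  len <- sample(60:2400, n_genes, replace = TRUE)
  end <- pmin(start + len, contig_len)
  tibble::tibble(
    feature_id = paste0("g", seq_len(n_genes)),
    contig_id = contig_id,
    start = start, end = end,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    ftype = "CDS", product = "", phase = 0L
  )
}

# Random interval set on one contig, possibly overlapping.
random_intervals <- function(n, contig_len, contig_id = "c1") {
  start <- sample.int(contig_len - 10L, n, replace = TRUE) - 1L
  end <- pmin(start + sample.int(3000L, n, replace = TRUE), contig_len)
  tibble::tibble(contig_id = contig_id, start = start, end = end)
}
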