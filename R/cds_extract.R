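#' Extract the coding sequence of features from the genome
#'
#' Slices each CDS interval out of its contig; minus-strand features are
#' reverse-complemented so the returned string reads 5'->3' on the coding
#' strand. GFF phase is NOT applied here (it is a translation-time offset, see
#' [translate_cds()]). Multi-segment CDS sharing a `feature_id` are spliced in
#' annotation order.
#'
#' @param genome Contig table from [read_genome()].
#' @param features Feature tibble; rows with `ftype != "CDS"` are dropped.
#' @return Tibble with `gene_id`, `contig_id`, `start`, `end` (hull), `strand`,
#'   `phase` (of the first segment) and `dna`.
#' @export
extract_cds <- function(genome, features) {
  cds <- dplyr::filter(features, .data$ftype == "CDS")
  if (nrow(cds) == 0) {
    return(tibble::tibble(gene_id = character(), contig_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), phase = integer(),
                          dna = character()))
  }
  lens <- stats::setNames(genome$length, genome$contig_id)
  if (any(!cds$contig_id %in% genome$contig_id) ||
      any(cds$start < 0 | cds$end > lens[cds$contig_id])) {
    stop("CDS interval outside contig bounds", call. = FALSE)
  }
  seqs <- stats::setNames(genome$sequence, genome$contig_id)
  cds$segment <- substr(seqs[cds$contig_id], cds$start + 1L, cds$end)
  cds |>
    dplyr::arrange(.data$contig_id, .data$start) |>
    dplyr::group_by(gene_id = .data$feature_id, .data$contig_id) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      strand = .data$strand[1],
      phase = if (.data$strand[1] == "-") {
        .data$phase[dplyr::n()]
      } else {
        .data$phase[1]
      },
      dna = {
        spliced <- paste(.data$segment, collapse = "")
        if (.data$strand[1] == "-") {
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(spliced)))
        } else {
          spliced
        }
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$contig_id, .data$start)
}

#' Translate coding sequences with the bacterial genetic code
#'
#' Translation uses NCBI genetic code table 11 (bacterial/archaeal/plant
#' plastid). The GFF `phase` offset is applied (that many leading bases are
#' dropped). A trailing partial codon (< 3 nt) is ignored with a warning; a
#' trailing stop codon is trimmed; internal stops (pseudogenes happen in real
#' annotations) are replaced by `X` with a warning rather than aborting the
#' run — the downstream similarity search decides their fate. Codons containing
#' ambiguity codes that cannot be resolved translate to `X`.
#'
#' @param dna Character vector of coding-strand DNA sequences.
#' @param phase Integer vector (recycled) of leading bases to drop; default 0.
#' @return Character vector of amino-acid sequences.
#' @export
translate_cds <- function(dna, phase = 0L) {
  if (any(nchar(dna) < 3)) {
    stop("coding sequence shorter than 3 nt", call. = FALSE)
  }
  phase <- rep_len(as.integer(phase), length(dna))
  dna <- substr(dna, phase + 1L, nchar(dna))
  keep <- (nchar(dna) %/% 3L) * 3L
  if (any(keep < nchar(dna))) {
    warning("trailing partial codon ignored in ", sum(keep < nchar(dna)),
            " sequence(s)", call. = FALSE)
  }
  dna <- substr(dna, 1L, keep)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(dna),
    genetic.code = Biostrings::getGeneticCode("11"),
    if.fuzzy.codon = "solve"
  ))
  aa <- sub("\\*$", "", aa)
  internal <- grepl("*", aa, fixed = TRUE)
  if (any(internal)) {
    warning("internal stop codon(s) in ", sum(internal),
            " sequence(s) replaced by 'X'", call. = FALSE)
    aa <- gsub("*", "X", aa, fixed = TRUE)
  }
  unname(aa)
}

#' Translate every annotated CDS to its protein
#'
#' Convenience wrapper over [extract_cds()] and [translate_cds()]: the
#' genome-wide proteome the similarity search queries.
#'
#' @inheritParams extract_cds
#' @return Tibble with `gene_id`, `contig_id`, `start`, `end`, `strand`, `aa`.
#' @export
translate_features <- function(genome, features) {
  cds <- extract_cds(genome, features)
  if (nrow(cds) == 0) {
    return(tibble::tibble(gene_id = character(), contig_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), aa = character()))
  }
  cds$aa <- translate_cds(cds$dna, cds$phase)
  dplyr::select(cds, "gene_id", "contig_id", "start", "end", "strand", "aa")
}

#' Write a translated proteome as protein FASTA
#'
#' The export consumed by an external protein aligner.
#'
#' @param proteome Tibble from [translate_features()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(stats::setNames(proteome$aa, proteome$gene_id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
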