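#' Read a genome FASTA into a contig table
#'
#' Reads a (multi-)FASTA of contigs. Sequences are upper-cased on read; only
#' IUPAC nucleotide codes are accepted. Duplicate contig ids are rejected.
#'
#' @param path Path to a FASTA file (uncompressed or gzip).
#' @return A tibble with columns `contig_id`, `sequence` (character, upper
#'   case) and `length` (bp).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    stop("genome FASTA not found: ", path, call. = FALSE)
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) {
    stop("empty FASTA: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop(
      "duplicate contig id(s) in ", path, ": ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  seq_chr <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTUMRWSYKVHDBN.-]", seq_chr)
  if (any(bad)) {
    stop(
      "non-IUPAC residues in record(s): ", paste(ids[bad], collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    contig_id = unname(ids),
    sequence = unname(seq_chr),
    length = unname(nchar(seq_chr))
  )
}

#' Read gene annotation from GFF3
#'
#' Parses a GFF3 file and returns features in the package's internal
#' coordinate convention: 0-based, half-open `[start, end)`. GFF3 1-based
#' inclusive coordinates are converted at this boundary; BED-style intervals
#' need no further conversion. Feature types other than CDS, tRNA and gene are
#' retained with `ftype = "other"` and ignored by the density scan. CDS
#' features lacking both `ID` and `Parent` attributes are skipped with a
#' warning. Multi-segment CDS sharing an id keep one row per segment; use
#' [feature_hulls()] for the per-gene interval used in counting.
#'
#' @param path Path to a GFF3 file (a trailing `##FASTA` section is tolerated
#'   and ignored).
#' @param genome Optional contig table from [read_genome()]; when supplied,
#'   features on unknown contigs or extending past a contig end are rejected.
#' @return A tibble with columns `feature_id`, `contig_id`, `start`, `end`
#'   (0-based half-open), `strand` (`+`, `-` or `*`), `ftype`
#'   (`CDS`/`tRNA`/`gene`/`other`), `product`, `phase`.
#' @export
read_annotation <- function(path, genome = NULL) {
  if (!file.exists(path)) {
    stop("GFF3 file not found: ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  get_col <- function(nm, default = NA_character_) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else rep(default, length(gr))
  }
  ids <- get_col("ID")
  parents <- if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else {
    rep(NA_character_, length(gr))
  }
  type <- as.character(mc$type)
  ftype <- dplyr::case_when(
    type == "CDS" ~ "CDS",
    type == "tRNA" ~ "tRNA",
    type == "gene" ~ "gene",
    TRUE ~ "other"
  )
  feature_id <- dplyr::coalesce(ids, parents)
  drop <- ftype == "CDS" & is.na(feature_id)
  if (any(drop)) {
    warning(sum(drop), " CDS feature(s) without ID or Parent skipped", call. = FALSE)
  }
  feature_id[is.na(feature_id)] <- paste0("feature_", seq_len(length(gr)))[is.na(feature_id)]

  feats <- tibble::tibble(
    feature_id = feature_id,
    contig_id = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    ftype = ftype,
    product = get_col("product", ""),
    phase = if ("phase" %in% names(mc)) as.integer(mc$phase) else NA_integer_
  )[!drop, ]
  feats$product[is.na(feats$product)] <- ""
  feats$phase[is.na(feats$phase) & feats$ftype == "CDS"] <- 0L

  if (!is.null(genome)) {
    unknown <- setdiff(feats$contig_id, genome$contig_id)
    if (length(unknown) > 0) {
      stop("features on contig(s) absent from genome: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    lens <- stats::setNames(genome$length, genome$contig_id)
    over <- feats$end > lens[feats$contig_id]
    if (any(over)) {
      stop("feature(s) extend past contig end: ",
           paste(utils::head(feats$feature_id[over], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  feats
}

#' Per-gene interval hulls
#'
#' Collapses multi-segment features sharing a `feature_id` to one row whose
#' interval is the hull of the segments (min start, max end). Single-segment
#' features pass through unchanged. This is the per-gene interval the density
#' scan counts.
#'
#' @param features Feature tibble from [read_annotation()].
#' @return One row per (`feature_id`, `contig_id`, `ftype`).
#' @export
feature_hulls <- function(features) {
  features |>
    dplyr::group_by(.data$feature_id, .data$contig_id, .data$ftype) |>
    dplyr::summarise(
      start = min(.data$start),
      end = max(.data$end),
      strand = .data$strand[1],
      product = .data$product[1],
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$contig_id, .data$start)
}

#' Write predictions as BED4
#'
#' Intervals are written 0-based half-open (the internal convention, so no
#' conversion happens here), sorted by contig then start, one line per
#' prophage, no header.
#'
#' @param predictions Tibble with `contig_id`, `start`, `end` and optionally
#'   `name` (defaults to `prophage_1..n` in sorted order).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(predictions, path) {
  predictions <- dplyr::arrange(predictions, .data$contig_id, .data$start)
  if (nrow(predictions) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nm <- if ("name" %in% names(predictions) && !anyNA(predictions$name)) {
    predictions$name
  } else {
    paste0("prophage_", seq_len(nrow(predictions)))
  }
  lines <- sprintf("%s\t%d\t%d\t%s",
                   predictions$contig_id,
                   as.integer(predictions$start),
                   as.integer(predictions$end),
                   nm)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path Path to a BED file (>= 3 columns, no header).
#' @return Tibble with `contig_id`, `start`, `end`, `name` (NA when absent).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0) {
    return(tibble::tibble(contig_id = character(), start = integer(),
                          end = integer(), name = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_min <- min(lengths(parts))
  if (ncol_min < 3) {
    stop("BED line with fewer than 3 columns in ", path, call. = FALSE)
  }
  tibble::tibble(
    contig_id = vapply(parts, `[[`, character(1), 1),
    start = as.integer(vapply(parts, `[[`, character(1), 2)),
    end = as.integer(vapply(parts, `[[`, character(1), 3)),
    name = vapply(parts, function(p) if (length(p) >= 4) p[[4]] else NA_character_,
                  character(1))
  )
}

#' Write the nucleotide sequence of each prediction as FASTA
#'
#' @param genome Contig table from [read_genome()].
#' @param predictions Prediction tibble (`contig_id`, `start`, `end`,
#'   optionally `name`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(genome, predictions, path) {
  predictions <- dplyr::arrange(predictions, .data$contig_id, .data$start)
  if (nrow(predictions) == 0) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), path)
    return(invisible(path))
  }
  lens <- stats::setNames(genome$length, genome$contig_id)
  bad <- !(predictions$contig_id %in% genome$contig_id) |
    predictions$start < 0 | predictions$end > lens[predictions$contig_id]
  if (any(bad)) {
    stop("prediction interval(s) outside contig bounds", call. = FALSE)
  }
  seqs <- stats::setNames(genome$sequence, genome$contig_id)
  nm <- if ("name" %in% names(predictions) && !anyNA(predictions$name)) {
    predictions$name
  } else {
    paste0("prophage_", seq_len(nrow(predictions)))
  }
  out <- Biostrings::DNAStringSet(substr(seqs[predictions$contig_id],
                                         predictions$start + 1L,
                                         predictions$end))
  names(out) <- sprintf("%s %s:%d-%d", nm, predictions$contig_id,
                        predictions$start, predictions$end)
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}
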