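#' Count phage-like genes in a sliding window
#'
#' Slides a window of `window` bp in steps of `step` bp across each contig and
#' counts the phage-like genes overlapping each window by at least 1 bp.
#' Windows are anchored at coordinate 0 of each contig; a window starting at
#' `s` spans `[s, min(s + window, contig_len))`, and the last start is the
#' largest multiple of `step` below the contig length, so terminal windows are
#' truncated. Contigs shorter than the window yield a single truncated window.
#' Contigs are treated as linear: windows never wrap the origin.
#'
#' @param features Feature tibble (per-gene hulls are taken internally, so
#'   multi-segment CDS count once).
#' @param phage_genes Output of [flag_phage_genes()] (or a character vector of
#'   gene ids).
#' @param contig_lengths Named integer vector of contig lengths, or a contig
#'   table from [read_genome()].
#' @param window Window length in bp (default 10000).
#' @param step Step in bp (default 1000); must satisfy `0 < step <= window`.
#' @return Tibble with `contig_id`, `start`, `end`, `n_phage_genes`,
#'   `phage_gene_ids` (list-column).
#' @export
scan_windows <- function(features, phage_genes, contig_lengths,
                         window = 10000L, step = 1000L) {
  stopifnot(step > 0, step <= window)
  if (is.data.frame(contig_lengths)) {
    contig_lengths <- stats::setNames(contig_lengths$length,
                                      contig_lengths$contig_id)
  }
  ids <- as_gene_ids(phage_genes)
  hulls <- feature_hulls(features)
  genes <- dplyr::filter(hulls, .data$ftype %in% c("CDS", "gene"),
                         .data$feature_id %in% ids)
  purrr::map_dfr(names(contig_lengths), function(ctg) {
    len <- as.integer(contig_lengths[[ctg]])
    starts <- seq.int(0L, by = as.integer(step),
                      length.out = max(1L, ceiling(len / step)))
    starts <- starts[starts < len]
    ends <- pmin(starts + as.integer(window), len)
    g <- dplyr::filter(genes, .data$contig_id == ctg)
    if (nrow(g) == 0) {
      return(tibble::tibble(contig_id = ctg, start = starts, end = ends,
                            n_phage_genes = 0L,
                            phage_gene_ids = rep(list(character(0)),
                                                 length(starts))))
    }
    win_ir <- IRanges::IRanges(start = starts + 1L, end = ends)
    gene_ir <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    ov <- IRanges::findOverlaps(win_ir, gene_ir, minoverlap = 1L)
    id_lists <- rep(list(character(0)), length(starts))
    if (length(ov) > 0) {
      sp <- split(g$feature_id[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov))
      id_lists[as.integer(names(sp))] <- lapply(sp, function(x) sort(unique(x)))
    }
    tibble::tibble(contig_id = ctg, start = starts, end = ends,
                   n_phage_genes = lengths(id_lists),
                   phage_gene_ids = id_lists)
  })
}

#' Select candidate windows
#'
#' Keeps windows holding at least `min_genes` phage-like genes whose own
#' length exceeds `min_span` (strict). The length condition only binds for
#' truncated terminal windows under the default `span_rule = "window"`; the
#' alternative reading, `span_rule = "genespan"`, instead requires the span
#' from the first to the last phage-like gene within the window to exceed
#' `min_span`.
#'
#' @param windows Output of [scan_windows()].
#' @param min_genes Minimum phage-like gene count (default 8).
#' @param min_span Strict lower bound in bp on the window length (default
#'   5000, half the default window).
#' @param features Feature tibble; required for `span_rule = "genespan"`.
#' @param span_rule `"window"` (default) or `"genespan"`.
#' @return The selected rows of `windows`.
#' @export
select_windows <- function(windows, min_genes = 8L, min_span = 5000L,
                           features = NULL,
                           span_rule = c("window", "genespan")) {
  span_rule <- match.arg(span_rule)
  keep_genes <- windows$n_phage_genes >= min_genes
  if (span_rule == "window") {
    keep_span <- (windows$end - windows$start) > min_span
  } else {
    if (is.null(features)) {
      stop("span_rule = \"genespan\" requires `features`", call. = FALSE)
    }
    hulls <- feature_hulls(features)
    starts <- stats::setNames(hulls$start, hulls$feature_id)
    ends <- stats::setNames(hulls$end, hulls$feature_id)
    keep_span <- vapply(windows$phage_gene_ids, function(ids) {
      if (length(ids) == 0) return(FALSE)
      (max(ends[ids]) - min(starts[ids])) > min_span
    }, logical(1))
  }
  windows[keep_genes & keep_span, ]
}

#' Merge overlapping windows into preliminary predictions
#'
#' Takes the maximal unions of transitively-overlapping (or book-ended)
#' selected windows per contig. Supporting gene sets are the unions over
#' member windows. Output is sorted by contig and start and pairwise disjoint;
#' merging is idempotent.
#'
#' @param selected Output of [select_windows()].
#' @return Prediction tibble with `contig_id`, `start`, `end`,
#'   `stage = "preliminary"`, `gene_ids` (list-column), `anchored_trnas`
#'   (empty list-column).
#' @export
merge_windows <- function(selected) {
  empty <- tibble::tibble(contig_id = character(), start = integer(),
                          end = integer(), stage = character(),
                          gene_ids = list(), anchored_trnas = list())
  if (nrow(selected) == 0) return(empty)
  out <- selected |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::group_map(function(df, key) {
      ir <- IRanges::IRanges(start = df$start + 1L, end = df$end)
      red <- IRanges::reduce(ir)
      ov <- IRanges::findOverlaps(ir, red)
      genes <- lapply(split(S4Vectors::queryHits(ov),
                            S4Vectors::subjectHits(ov)),
                      function(i) sort(unique(unlist(df$phage_gene_ids[i]))))
      tibble::tibble(
        contig_id = key$contig_id,
        start = BiocGenerics::start(red) - 1L,
        end = BiocGenerics::end(red),
        stage = "preliminary",
        gene_ids = unname(genes[as.character(seq_along(red))]),
        anchored_trnas = rep(list(character(0)), length(red))
      )
    }) |>
    dplyr::bind_rows()
  dplyr::arrange(out, .data$contig_id, .data$start)
}

#' Export per-window counts as a debug table
#'
#' Writes the intermediate per-window counts (contig, start, end, count) as a
#' headered tab-separated file, mirroring the pipeline's folder of
#' intermediate files.
#'
#' @param windows Output of [scan_windows()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(windows, path) {
  df <- dplyr::select(windows, "contig_id", "start", "end", "n_phage_genes")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
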