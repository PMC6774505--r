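#' Trim preliminary predictions to their terminal phage-like genes
#'
#' Each preliminary region is contracted to
#' `[start of leftmost, end of rightmost)` phage-like gene overlapping it, and
#' the supporting gene set becomes exactly those overlapping genes. A region
#' overlapped by no phage-like gene is discarded with a warning (cannot happen
#' for predictions produced by [select_windows()] with `min_genes >= 1`).
#' Trimming never enlarges a region.
#'
#' @param predictions Preliminary predictions from [merge_windows()].
#' @param features Feature tibble.
#' @param phage_genes Output of [flag_phage_genes()] or a character vector.
#' @return Predictions with `stage = "trimmed"`.
#' @export
trim_to_phage_genes <- function(predictions, features, phage_genes) {
  ids <- as_gene_ids(phage_genes)
  hulls <- feature_hulls(features)
  genes <- dplyr::filter(hulls, .data$ftype %in% c("CDS", "gene"),
                         .data$feature_id %in% ids)
  res <- purrr::pmap_dfr(
    predictions[c("contig_id", "start", "end", "anchored_trnas")],
    function(contig_id, start, end, anchored_trnas) {
      g <- genes[genes$contig_id == contig_id &
                   genes$start < end & genes$end > start, ]
      if (nrow(g) == 0) {
        warning("prediction ", contig_id, ":", start, "-", end,
                " overlaps no phage-like gene; discarded", call. = FALSE)
        return(NULL)
      }
      tibble::tibble(
        contig_id = contig_id,
        start = max(start, min(g$start)),
        end = min(end, max(g$end)),
        stage = "trimmed",
        gene_ids = list(sort(g$feature_id)),
        anchored_trnas = list(anchored_trnas)
      )
    }
  )
  if (nrow(res) == 0) {
    return(tibble::tibble(contig_id = character(), start = integer(),
                          end = integer(), stage = character(),
                          gene_ids = list(), anchored_trnas = list()))
  }
  res
}

#' Adjust prediction borders to nearby tRNA genes
#'
#' tRNA genes are hotspots of prophage integration, so borders often abut
#' them. For each border, tRNA features overlapping the symmetric flank
#' `[border - flank, border + flank)` are collected; if any exist the border
#' moves to their most outward coordinate — the minimum tRNA start on the left
#' border, the maximum tRNA end on the right — extending or contracting the
#' prediction. A border with no tRNA in its flank is unchanged. An adjustment
#' that would invert the interval keeps the trimmed borders and warns. The
#' features anchoring each border are recorded in `anchored_trnas`.
#'
#' @param predictions Trimmed predictions from [trim_to_phage_genes()].
#' @param features Feature tibble (only `ftype == "tRNA"` rows are used;
#'   strand is ignored).
#' @param flank Search distance in bp on each side of a border (default 3000).
#' @return Predictions with `stage = "final"`.
#' @export
adjust_to_trna <- function(predictions, features, flank = 3000L) {
  trnas <- dplyr::filter(feature_hulls(features), .data$ftype == "tRNA")
  purrr::pmap_dfr(
    predictions[c("contig_id", "start", "end", "gene_ids")],
    function(contig_id, start, end, gene_ids) {
      tc <- trnas[trnas$contig_id == contig_id, ]
      in_flank <- function(b) {
        tc[tc$start < b + flank & tc$end > b - flank, ]
      }
      left <- in_flank(start)
      right <- in_flank(end)
      new_start <- if (nrow(left) > 0) min(left$start) else start
      new_end <- if (nrow(right) > 0) max(right$end) else end
      anchors <- character(0)
      if (nrow(left) > 0) anchors <- c(anchors, left$feature_id[which.min(left$start)])
      if (nrow(right) > 0) anchors <- c(anchors, right$feature_id[which.max(right$end)])
      if (new_start >= new_end) {
        warning("tRNA adjustment would invert ", contig_id, ":", start, "-",
                end, "; keeping trimmed borders", call. = FALSE)
        new_start <- start
        new_end <- end
        anchors <- character(0)
      }
      tibble::tibble(contig_id = contig_id, start = new_start, end = new_end,
                     stage = "final", gene_ids = list(gene_ids),
                     anchored_trnas = list(unique(anchors)))
    }
  )
}

#' Finalize predictions: sort, merge, name
#'
#' Re-sorts final predictions, merges any pair made overlapping (or
#' book-ended) by tRNA extension — uniting their supporting gene and tRNA
#' sets — and assigns ids `prophage_1..n` by position. The output is pairwise
#' disjoint within each contig.
#'
#' @param predictions Final-stage predictions from [adjust_to_trna()].
#' @return Prediction tibble with a `name` column.
#' @export
finalize_predictions <- function(predictions) {
  empty <- tibble::tibble(contig_id = character(), start = integer(),
                          end = integer(), stage = character(),
                          gene_ids = list(), anchored_trnas = list(),
                          name = character())
  if (nrow(predictions) == 0) return(empty)
  out <- predictions |>
    dplyr::group_by(.data$contig_id) |>
    dplyr::group_map(function(df, key) {
      ir <- IRanges::IRanges(start = df$start + 1L, end = df$end)
      red <- IRanges::reduce(ir)
      ov <- IRanges::findOverlaps(ir, red)
      grp <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
      tibble::tibble(
        contig_id = key$contig_id,
        start = BiocGenerics::start(red) - 1L,
        end = BiocGenerics::end(red),
        stage = "final",
        gene_ids = lapply(grp, function(i) sort(unique(unlist(df$gene_ids[i])))),
        anchored_trnas = lapply(grp, function(i)
          sort(unique(unlist(df$anchored_trnas[i]))))
      )
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$contig_id, .data$start)
  out$name <- paste0("prophage_", seq_len(nrow(out)))
  out
}
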