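#' Length-based evaluation against a gold standard
#'
#' Compares predicted and gold-standard prophage intervals by base-pair
#' overlap, not per-prophage pairing: each set is first reduced to its
#' disjoint union per contig (preventing double counting), then
#' `TP = |pred intersect gold|`, `FP = |pred \ gold|` and `FN = |gold \ pred|`
#' in bases, summed over contigs. Sensitivity is `TP/(TP+FN)` and positive
#' predictive value `TP/(TP+FP)`; a ratio whose denominator is 0 (empty gold,
#' or empty predictions) is reported as `NA`, never 0. Intervals on a contig
#' absent from the other set count fully as FP or FN.
#'
#' @param predictions Tibble of predicted intervals (`contig_id`, `start`,
#'   `end`; 0-based half-open).
#' @param gold Tibble of gold-standard intervals, same convention.
#' @return A `prophage_eval` object with fields `tp_len`, `fp_len`, `fn_len`,
#'   `sensitivity`, `ppv`; see [tidy.prophage_eval()] and
#'   [glance.prophage_eval()].
#' @export
evaluate_predictions <- function(predictions, gold) {
  reduce_set <- function(df) {
    if (nrow(df) == 0) {
      return(stats::setNames(list(), character(0)))
    }
    lapply(split(df, df$contig_id), function(d) {
      IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    })
  }
  p <- reduce_set(predictions)
  g <- reduce_set(gold)
  contigs <- union(names(p), names(g))
  tp <- fp <- fn <- 0
  for (ctg in contigs) {
    pi <- if (ctg %in% names(p)) p[[ctg]] else IRanges::IRanges()
    gi <- if (ctg %in% names(g)) g[[ctg]] else IRanges::IRanges()
    tp <- tp + sum(IRanges::width(IRanges::intersect(pi, gi)))
    fp <- fp + sum(IRanges::width(IRanges::setdiff(pi, gi)))
    fn <- fn + sum(IRanges::width(IRanges::setdiff(gi, pi)))
  }
  structure(
    list(
      tp_len = tp, fp_len = fp, fn_len = fn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_
    ),
    class = "prophage_eval"
  )
}

#' @export
print.prophage_eval <- function(x, ...) {
  cat("Prophage prediction evaluation (base-pair overlap)\n")
  cat(sprintf("  TP length: %.0f bp\n  FP length: %.0f bp\n  FN length: %.0f bp\n",
              x$tp_len, x$fp_len, x$fn_len))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("  Sensitivity: %s\n  PPV: %s\n",
              fmt(x$sensitivity), fmt(x$ppv)))
  invisible(x)
}

#' Tidy an evaluation result
#'
#' @param x A `prophage_eval` object.
#' @param ... Unused.
#' @return One-row tibble with `tp_len`, `fp_len`, `fn_len`, `sensitivity`,
#'   `ppv`.
#' @export
tidy.prophage_eval <- function(x, ...) {
  tibble::tibble(tp_len = x$tp_len, fp_len = x$fp_len, fn_len = x$fn_len,
                 sensitivity = x$sensitivity, ppv = x$ppv)
}

#' One-line summary of an evaluation result
#'
#' @param x A `prophage_eval` object.
#' @param ... Unused.
#' @return One-row tibble with percent-formatted `sensitivity_pct` and
#'   `ppv_pct` (one decimal place, the conventional presentation) alongside
#'   the raw lengths.
#' @export
glance.prophage_eval <- function(x, ...) {
  tibble::tibble(
    sensitivity_pct = round(100 * x$sensitivity, 1),
    ppv_pct = round(100 * x$ppv, 1),
    tp_len = x$tp_len, fp_len = x$fp_len, fn_len = x$fn_len
  )
}

#' Generics for tidy() and glance()
#'
#' Broom-style generics, defined here so the package has no broom dependency.
#' @param x Object to summarise.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Compare several tools against one gold standard
#'
#' Evaluates each prediction set against the same gold standard. In
#' `mode = "pooled"` all contigs contribute to one TP/FP/FN pool per tool (the
#' shared gold denominator makes sensitivities directly comparable). In
#' `mode = "per-genome"` each contig is evaluated separately and the
#' unweighted mean of the per-contig sensitivity and PPV is reported
#' (contigs where a ratio is undefined are dropped from its mean).
#'
#' @param prediction_sets Named list of prediction tibbles (one per tool).
#' @param gold Gold-standard interval tibble.
#' @param mode `"pooled"` (default) or `"per-genome"`.
#' @return Tibble with one row per tool, in the order given.
#' @export
compare_tools <- function(prediction_sets, gold,
                          mode = c("pooled", "per-genome")) {
  mode <- match.arg(mode)
  stopifnot(length(prediction_sets) >= 1, !is.null(names(prediction_sets)))
  purrr::imap_dfr(prediction_sets, function(pred, tool) {
    if (mode == "pooled") {
      dplyr::bind_cols(tibble::tibble(tool = tool),
                       tidy(evaluate_predictions(pred, gold)))
    } else {
      contigs <- union(unique(pred$contig_id), unique(gold$contig_id))
      per <- purrr::map_dfr(contigs, function(ctg) {
        tidy(evaluate_predictions(pred[pred$contig_id == ctg, ],
                                  gold[gold$contig_id == ctg, ]))
      })
      tibble::tibble(
        tool = tool,
        tp_len = sum(per$tp_len), fp_len = sum(per$fp_len),
        fn_len = sum(per$fn_len),
        sensitivity = mean(per$sensitivity, na.rm = TRUE),
        ppv = mean(per$ppv, na.rm = TRUE)
      )
    }
  })
}
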