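#' Predict prophages from annotation and similarity hits
#'
#' The full in-memory pipeline: flag phage-like genes (e-value strictly below
#' `evalue`), count them in a 10 kb / 1 kb sliding window on each contig,
#' select windows with at least `min_genes` of them and length above
#' `min_span`, merge overlapping windows into preliminary predictions, trim
#' borders to the outermost phage-like genes, adjust borders to tRNA genes
#' within `trna_flank`, and finalize. Contigs are scanned independently, so
#' prophages wholly contained within a contig of a fragmented assembly are
#' found; prophages split across contigs are not.
#'
#' @param genome Contig table from [read_genome()].
#' @param features Feature tibble from [read_annotation()].
#' @param hits Hit tibble from [read_hits()].
#' @param evalue Strict e-value cutoff for flagging (default `1e-5`).
#' @param window,step Sliding-window length and step, bp.
#' @param min_genes Minimum phage-like genes per window.
#' @param min_span Strict lower bound on window length, bp.
#' @param trna_flank tRNA search distance around each border, bp.
#' @param span_rule `"window"` or `"genespan"`; see [select_windows()].
#' @return Finalized prediction tibble (`contig_id`, `start`, `end`, `stage`,
#'   `gene_ids`, `anchored_trnas`, `name`).
#' @export
predict_prophages <- function(genome, features, hits, evalue = 1e-5,
                              window = 10000L, step = 1000L,
                              min_genes = 8L, min_span = 5000L,
                              trna_flank = 3000L,
                              span_rule = c("window", "genespan")) {
  span_rule <- match.arg(span_rule)
  phage <- flag_phage_genes(hits, evalue_cutoff = evalue, features = features)
  windows <- scan_windows(features, phage, genome, window = window,
                          step = step)
  selected <- select_windows(windows, min_genes = min_genes,
                             min_span = min_span, features = features,
                             span_rule = span_rule)
  merged <- merge_windows(selected)
  if (nrow(merged) == 0) return(finalize_predictions(merged))
  merged |>
    trim_to_phage_genes(features, phage) |>
    adjust_to_trna(features, flank = trna_flank) |>
    finalize_predictions()
}

#' Run a prediction from files to an output folder
#'
#' File-level front end mirroring the shell command: reads the genome and
#' annotation, obtains hits either from a precomputed 12-column hit file
#' (`hits`) or by translating the proteome and running the external aligner
#' against a database directory (`db_dir`), predicts prophages, and writes
#' the outputs: `prophages.bed`, `prophages.fasta`, `genome_map.png`, a run
#' manifest, and an `intermediate/` folder with the per-window count table,
#' the flagged gene list and the hit file used. The manifest (parameters,
#' input checksums, package version) contains no timestamps, so identical
#' inputs and parameters yield byte-identical BED and manifest.
#'
#' @param fasta,gff Input genome FASTA and GFF3 annotation paths.
#' @param hits Optional precomputed hit-file path (offline route; no external
#'   aligner is invoked when given).
#' @param db_dir Optional database directory from [write_phage_db()]; used
#'   with the external aligner when `hits` is not given.
#' @param outdir Output directory (created).
#' @param cores Threads passed to the external aligner.
#' @inheritParams predict_prophages
#' @return The finalized prediction tibble, invisibly.
#' @export
run_predict <- function(fasta, gff, outdir, hits = NULL, db_dir = NULL,
                        evalue = 1e-5, window = 10000L, step = 1000L,
                        min_genes = 8L, min_span = 5000L, trna_flank = 3000L,
                        span_rule = "window", cores = 1L) {
  if (is.null(hits) && is.null(db_dir)) {
    stop("supply either a precomputed hit file (`hits`) or a database ",
         "directory (`db_dir`)", call. = FALSE)
  }
  dir.create(file.path(outdir, "intermediate"), recursive = TRUE,
             showWarnings = FALSE)
  genome <- read_genome(fasta)
  features <- read_annotation(gff, genome)

  hit_path <- hits
  if (is.null(hit_path)) {
    proteome <- translate_features(genome, features)
    prot_path <- file.path(outdir, "intermediate", "proteome.faa")
    write_proteome(proteome, prot_path)
    hit_path <- file.path(outdir, "intermediate", "search_hits.tsv")
    run_external_search(prot_path, db_dir, hit_path, threads = cores)
  }
  hit_tbl <- read_hits(hit_path)

  phage <- flag_phage_genes(hit_tbl, evalue_cutoff = evalue,
                            features = features)
  windows <- scan_windows(features, phage, genome, window = window,
                          step = step)
  selected <- select_windows(windows, min_genes = min_genes,
                             min_span = min_span, features = features,
                             span_rule = span_rule)
  merged <- merge_windows(selected)
  predictions <- if (nrow(merged) == 0) {
    finalize_predictions(merged)
  } else {
    merged |>
      trim_to_phage_genes(features, phage) |>
      adjust_to_trna(features, flank = trna_flank) |>
      finalize_predictions()
  }

  write_bed(predictions, file.path(outdir, "prophages.bed"))
  write_region_fasta(genome, predictions, file.path(outdir, "prophages.fasta"))
  write_window_table(windows, file.path(outdir, "intermediate",
                                        "window_counts.tsv"))
  writeLines(phage$gene_id, file.path(outdir, "intermediate",
                                      "phage_genes.txt"))
  if (!is.null(hits)) {
    file.copy(hits, file.path(outdir, "intermediate", "search_hits.tsv"),
              overwrite = TRUE)
  }

  map_ok <- tryCatch({
    grDevices::png(file.path(outdir, "genome_map.png"), width = 1200,
                   height = 200 + 120 * nrow(genome), res = 120)
    print(plot_genome_map(genome, predictions))
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    warning("genome map not rendered: ", conditionMessage(e), call. = FALSE)
    FALSE
  })

  manifest <- list(
    tool = "prophagescan",
    version = as.character(utils::packageVersion("prophagescan")),
    parameters = list(
      evalue = evalue, window = window, step = step, min_genes = min_genes,
      min_span = min_span, trna_flank = trna_flank, span_rule = span_rule
    ),
    inputs = list(
      fasta = unname(tools::md5sum(fasta)),
      gff = unname(tools::md5sum(gff)),
      hits = unname(tools::md5sum(hit_path))
    ),
    db_report = if (!is.null(db_dir) &&
                      file.exists(file.path(db_dir, "db_report.txt"))) {
      paste(readLines(file.path(db_dir, "db_report.txt")), collapse = "\n")
    } else {
      NULL
    },
    n_prophages = nrow(predictions),
    genome_map = map_ok
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(predictions)
}

#' Build and write a reference database from a proteome directory
#'
#' @param proteome_dir Directory of protein FASTA files (`.fa`, `.faa`,
#'   `.fasta`).
#' @param metadata Path to the tab-separated metadata table
#'   (`phage_id`, `family`, ...).
#' @param outdir Output database directory.
#' @param exclusion_terms Product substrings to exclude.
#' @param build_date Date recorded in the report.
#' @return The `phage_db` object, invisibly.
#' @export
run_build_db <- function(proteome_dir, metadata, outdir,
                         exclusion_terms = "ABC transporter",
                         build_date = Sys.Date()) {
  files <- list.files(proteome_dir, pattern = "\\.(fa|faa|fasta)$",
                      full.names = TRUE)
  if (length(files) == 0) {
    stop("no FASTA files in ", proteome_dir, call. = FALSE)
  }
  db <- build_phage_db(files, metadata, exclusion_terms = exclusion_terms,
                       build_date = build_date)
  write_phage_db(db, outdir)
  invisible(db)
}

#' Evaluate one or more prediction BED files against a gold standard
#'
#' @param pred Named character vector of prediction BED paths (names are tool
#'   labels; unnamed paths are labelled by file name).
#' @param gold Gold-standard BED path.
#' @param mode `"pooled"` or `"per-genome"`; see [compare_tools()].
#' @return Tibble, one row per prediction set.
#' @export
run_evaluate <- function(pred, gold, mode = "pooled") {
  labels <- names(pred)
  if (is.null(labels)) labels <- rep("", length(pred))
  labels[!nzchar(labels)] <-
    tools::file_path_sans_ext(basename(pred[!nzchar(labels)]))
  sets <- stats::setNames(lapply(pred, read_bed), labels)
  compare_tools(sets, read_bed(gold), mode = mode)
}

#' Generate a fixture set from a scenario configuration file
#'
#' @param config Path to a JSON scenario description: top-level
#'   `contig_len`, `gene_density`, `background_hit_rate`, optional
#'   `contig_id`, `weak_hit_rate`, and an `islands` array of objects with the
#'   [sim_island()] fields.
#' @param seed Integer seed (overrides any seed in the file).
#' @param outdir Output directory for the fixture files.
#' @return The fixture list from [simulate_fixtures()], invisibly.
#' @export
run_simulate <- function(config, seed, outdir) {
  cfg <- jsonlite::read_json(config, simplifyVector = FALSE)
  islands <- lapply(cfg$islands, function(i) do.call(sim_island, i))
  args <- cfg[setdiff(names(cfg), c("islands", "seed"))]
  scenario <- do.call(sim_scenario,
                      c(args, list(seed = seed, islands = islands)))
  invisible(simulate_fixtures(scenario, dir = outdir))
}

#' Plot predicted prophage positions along the genome
#'
#' One horizontal track per contig with prediction boxes; a quick visual
#' check of where the prophages sit.
#'
#' @param genome Contig table.
#' @param predictions Finalized prediction tibble.
#' @return A ggplot object.
#' @export
plot_genome_map <- function(genome, predictions) {
  genome <- dplyr::mutate(genome,
                          y = dplyr::row_number())
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = genome,
      ggplot2::aes(x = 0, xend = .data$length / 1000, y = .data$y,
                   yend = .data$y),
      linewidth = 1, colour = "grey40"
    ) +
    ggplot2::scale_y_continuous(breaks = genome$y, labels = genome$contig_id,
                                limits = c(0.5, nrow(genome) + 0.5)) +
    ggplot2::labs(x = "position (kb)", y = NULL,
                  title = "Predicted prophages") +
    ggplot2::theme_minimal()
  if (nrow(predictions) > 0) {
    pr <- dplyr::left_join(predictions,
                           dplyr::select(genome, "contig_id", "y"),
                           by = "contig_id")
    p <- p + ggplot2::geom_rect(
      data = pr,
      ggplot2::aes(xmin = .data$start / 1000, xmax = .data$end / 1000,
                   ymin = .data$y - 0.25, ymax = .data$y + 0.25),
      fill = "seagreen", alpha = 0.8
    ) +
      ggplot2::geom_text(
        data = pr,
        ggplot2::aes(x = (.data$start + .data$end) / 2000,
                     y = .data$y + 0.35, label = .data$name),
        size = 2.8, vjust = 0
      )
  }
  p
}

#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL
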