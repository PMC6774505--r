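#' Read a 12-column tabular alignment hit file
#'
#' The interchange format is the de-facto standard tabular protein-aligner
#' output ("outfmt 6"): query, subject, percent identity, alignment length,
#' mismatches, gap opens, qstart, qend, sstart, send, evalue, bitscore,
#' tab-separated, no header. Malformed rows are rejected with their line
#' numbers.
#'
#' @param path Path to the hit file; an empty file yields an empty tibble.
#' @return Tibble with `gene_id`, `subject_id`, `pident`, `length`,
#'   `mismatches`, `gapopens`, `qstart`, `qend`, `sstart`, `send`, `evalue`,
#'   `bitscore`.
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) {
    stop("hit file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines_keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  empty <- tibble::tibble(
    gene_id = character(), subject_id = character(), pident = double(),
    length = integer(), mismatches = integer(), gapopens = integer(),
    qstart = integer(), qend = integer(), sstart = integer(), send = integer(),
    evalue = double(), bitscore = double()
  )
  if (length(lines_keep) == 0) {
    return(empty)
  }
  parts <- strsplit(lines[lines_keep], "\t", fixed = TRUE)
  bad_ncol <- lengths(parts) != 12L
  if (any(bad_ncol)) {
    stop("hit file row(s) without 12 columns at line(s): ",
         paste(utils::head(lines_keep[bad_ncol], 5), collapse = ", "),
         call. = FALSE)
  }
  m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10)
  bad_num <- rowSums(is.na(num)) > 0
  if (any(bad_num)) {
    stop("non-numeric field(s) in hit file at line(s): ",
         paste(utils::head(lines_keep[bad_num], 5), collapse = ", "),
         call. = FALSE)
  }
  if (any(num[, 9] < 0)) {
    stop("negative e-value in hit file", call. = FALSE)
  }
  tibble::tibble(
    gene_id = m[, 1], subject_id = m[, 2],
    pident = num[, 1], length = as.integer(num[, 2]),
    mismatches = as.integer(num[, 3]), gapopens = as.integer(num[, 4]),
    qstart = as.integer(num[, 5]), qend = as.integer(num[, 6]),
    sstart = as.integer(num[, 7]), send = as.integer(num[, 8]),
    evalue = num[, 9], bitscore = num[, 10]
  )
}

#' Run an external protein similarity search (blastp)
#'
#' Thin wrapper over NCBI `blastp` against a database directory produced by
#' [write_phage_db()]. This is the only component that touches an external
#' binary; the rest of the pipeline runs offline from a precomputed hit file
#' (see `hits` in [run_predict()]). The command line, exit status and tool
#' version are logged to stderr.
#'
#' @param proteome_fasta Path to the query protein FASTA.
#' @param db_dir Database directory containing `phage_proteins.faa` (a BLAST
#'   index is built on first use).
#' @param out Output hit-file path.
#' @param threads Number of aligner threads.
#' @param evalue Reporting threshold passed to the aligner (keep it looser
#'   than the flagging cutoff so filtering happens in one place).
#' @return `out`, invisibly.
#' @export
run_external_search <- function(proteome_fasta, db_dir, out,
                                threads = 1L, evalue = 1e-3) {
  blastp <- Sys.which("blastp")
  if (!nzchar(blastp)) {
    stop("blastp not found on PATH; run the aligner elsewhere and supply ",
         "its 12-column tabular output via the precomputed hit-file route ",
         "(`hits` argument / `--hits`)", call. = FALSE)
  }
  db_fasta <- file.path(db_dir, "phage_proteins.faa")
  if (!file.exists(db_fasta)) {
    stop("database FASTA not found: ", db_fasta, call. = FALSE)
  }
  if (!file.exists(paste0(db_fasta, ".pin")) &&
      !file.exists(paste0(db_fasta, ".pdb"))) {
    mk <- system2(Sys.which("makeblastdb"),
                  c("-in", shQuote(db_fasta), "-dbtype", "prot"),
                  stdout = TRUE, stderr = TRUE)
    if (!is.null(attr(mk, "status")) && attr(mk, "status") != 0) {
      stop("makeblastdb failed:\n", paste(mk, collapse = "\n"), call. = FALSE)
    }
  }
  ver <- system2(blastp, "-version", stdout = TRUE)[1]
  args <- c("-query", shQuote(proteome_fasta), "-db", shQuote(db_fasta),
            "-outfmt", "6", "-evalue", format(evalue, scientific = TRUE),
            "-num_threads", as.integer(threads), "-out", shQuote(out))
  message("running: blastp ", paste(args, collapse = " "), " [", ver, "]")
  res <- system2(blastp, args, stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("blastp exited with status ", status, ":\n",
         paste(res, collapse = "\n"), call. = FALSE)
  }
  if (!file.exists(out)) file.create(out)
  invisible(out)
}

#' Flag phage-like genes from similarity hits
#'
#' A gene is phage-like iff it has at least one hit with e-value strictly
#' below the cutoff (default `1e-5`); a hit at exactly the cutoff does not
#' qualify. Each gene appears at most once regardless of how many hits pass.
#'
#' @param hits Hit tibble from [read_hits()].
#' @param evalue_cutoff Strict upper bound on the e-value.
#' @param features Optional feature tibble; when supplied, flagged ids are
#'   checked to exist in the annotation.
#' @return Tibble with one column `gene_id`, sorted, unique.
#' @export
flag_phage_genes <- function(hits, evalue_cutoff = 1e-5, features = NULL) {
  ids <- sort(unique(hits$gene_id[hits$evalue < evalue_cutoff]))
  if (!is.null(features)) {
    missing <- setdiff(ids, features$feature_id)
    if (length(missing) > 0) {
      stop("flagged gene id(s) absent from annotation: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  tibble::tibble(gene_id = ids)
}

# Accept either a flag_phage_genes() tibble or a bare character vector.
as_gene_ids <- function(phage_genes) {
  if (is.data.frame(phage_genes)) phage_genes$gene_id else as.character(phage_genes)
}
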