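#' Build a phage protein reference database from local proteomes
#'
#' Assembles the reference database the similarity search runs against, from
#' a set of local phage proteome FASTA files plus a metadata table mapping
#' each phage to its family. Records whose product annotation contains any
#' exclusion term (case-insensitive substring match on the description, not
#' the sequence) are dropped and logged; ABC transporters are excluded by
#' default because they are highly conserved outside prophage regions and
#' would seed false-positive predictions. Network retrieval is out of scope:
#' the builder consumes a local mirror, and the build date plus per-family
#' counts are recorded for reproducibility.
#'
#' The family whitelist is data-driven: only phages present in
#' `metadata` enter the database, so taxonomy updates are a metadata edit,
#' not a code change.
#'
#' @param proteome_files Character vector of protein FASTA paths. Record
#'   headers are `protein_id phage_id product...`; when the header carries no
#'   phage id the file name (without extension) is used.
#' @param metadata Tibble/data frame with columns `phage_id` and `family`
#'   (path to a tab-separated file also accepted).
#' @param exclusion_terms Character vector of product substrings to exclude
#'   (default `"ABC transporter"`).
#' @param build_date Date stamp recorded in the database (defaults to today;
#'   pass a fixed value for reproducible builds).
#' @return A `phage_db` object: list with `proteins` (tibble: `protein_id`,
#'   `phage_id`, `family`, `product`, `aa_sequence`), `build_date`,
#'   `per_family_counts` (named integer), `excluded_log` (tibble:
#'   `protein_id`, `reason`).
#' @export
build_phage_db <- function(proteome_files, metadata,
                           exclusion_terms = "ABC transporter",
                           build_date = Sys.Date()) {
  if (is.character(metadata) && length(metadata) == 1 && file.exists(metadata)) {
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("phage_id", "family") %in% names(metadata)))
  fam <- stats::setNames(as.character(metadata$family),
                         as.character(metadata$phage_id))

  recs <- purrr::map_dfr(proteome_files, function(f) {
    aa <- Biostrings::readAAStringSet(f)
    if (length(aa) == 0) return(NULL)
    hdr <- names(aa)
    toks <- strsplit(hdr, "\\s+")
    tibble::tibble(
      protein_id = vapply(toks, `[[`, character(1), 1),
      phage_id = vapply(toks, function(t) {
        if (length(t) >= 2) t[[2]] else tools::file_path_sans_ext(basename(f))
      }, character(1)),
      product = vapply(toks, function(t) {
        if (length(t) >= 3) paste(t[-(1:2)], collapse = " ") else ""
      }, character(1)),
      aa_sequence = as.character(aa)
    )
  })
  if (nrow(recs) == 0) {
    stop("no protein records in supplied proteome files", call. = FALSE)
  }

  known <- recs$phage_id %in% names(fam)
  excl_family <- recs[!known, c("protein_id", "product")]
  recs <- recs[known, ]
  recs$family <- unname(fam[recs$phage_id])

  hit_term <- rep(NA_character_, nrow(recs))
  for (term in exclusion_terms) {
    m <- is.na(hit_term) &
      grepl(term, recs$product, ignore.case = TRUE, fixed = FALSE)
    hit_term[m] <- term
  }
  excluded <- dplyr::bind_rows(
    tibble::tibble(
      protein_id = recs$protein_id[!is.na(hit_term)],
      reason = paste0("product matches exclusion term '",
                      hit_term[!is.na(hit_term)], "'")
    ),
    tibble::tibble(
      protein_id = excl_family$protein_id,
      reason = "phage not in metadata family whitelist"
    )
  )
  proteins <- recs[is.na(hit_term),
                   c("protein_id", "phage_id", "family", "product",
                     "aa_sequence")]
  if (nrow(proteins) == 0) {
    stop("database empty after exclusion filtering; a prediction run ",
         "against it would flag nothing", call. = FALSE)
  }
  structure(
    list(
      proteins = tibble::as_tibble(proteins),
      build_date = as.Date(build_date),
      per_family_counts = vapply(split(proteins$protein_id, proteins$family),
                                 length, integer(1)),
      excluded_log = excluded
    ),
    class = "phage_db"
  )
}

#' @export
print.phage_db <- function(x, ...) {
  cat(db_report(x))
  invisible(x)
}

#' Plain-text database report
#'
#' The reproducibility record written into every run's output folder: build
#' date, total protein count, and per-family counts. Families with no
#' retained proteins are absent.
#'
#' @param db A `phage_db` object.
#' @return A single character string (newline-separated report).
#' @export
db_report <- function(db) {
  stopifnot(inherits(db, "phage_db"))
  fam <- db$per_family_counts[db$per_family_counts > 0]
  fam <- fam[order(names(fam))]
  paste0(
    "Phage protein reference database\n",
    "build_date: ", format(db$build_date), "\n",
    "total_proteins: ", nrow(db$proteins), "\n",
    "excluded_records: ", nrow(db$excluded_log), "\n",
    "proteins_per_family:\n",
    paste0("  ", names(fam), ": ", fam, "\n", collapse = "")
  )
}

#' Write a database to a directory
#'
#' Materialises the database as `phage_proteins.faa` (headers
#' `protein_id phage_id product`) plus the plain-text report and the
#' exclusion log — the layout [run_external_search()] consumes.
#'
#' @param db A `phage_db` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phage_db <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aa <- Biostrings::AAStringSet(db$proteins$aa_sequence)
  names(aa) <- sprintf("%s %s %s", db$proteins$protein_id,
                       db$proteins$phage_id, db$proteins$product)
  Biostrings::writeXStringSet(aa, file.path(dir, "phage_proteins.faa"))
  writeLines(db_report(db), file.path(dir, "db_report.txt"))
  utils::write.table(db$excluded_log, file.path(dir, "excluded_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
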