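#' Describe a prophage island for simulation
#'
#' An island is a run of `n_genes` genes of `gene_len` bp separated by
#' `spacing` bp, starting at `position`. A fraction `phage_fraction` of its
#' genes receive strong phage hits (e-value sampled log-uniform in
#' `[1e-50, 1e-6]`, below the flagging cutoff). Optional flanking tRNA genes
#' are placed `left_trna` / `right_trna` bp outside the island hull.
#'
#' @param position 0-based start of the first gene.
#' @param n_genes Number of genes in the island.
#' @param gene_len Gene length in bp (rounded down to a codon multiple).
#' @param spacing Intergenic gap within the island, bp.
#' @param phage_fraction Fraction of island genes given phage hits.
#' @param left_trna,right_trna Optional gap in bp between the island hull and
#'   a flanking tRNA (tRNA outward of the island); `NULL` for none.
#' @param trna_len tRNA gene length, bp.
#' @return A `sim_island` list.
#' @export
sim_island <- function(position, n_genes = 12L, gene_len = 600L,
                       spacing = 150L, phage_fraction = 1,
                       left_trna = NULL, right_trna = NULL, trna_len = 80L) {
  stopifnot(n_genes >= 1, gene_len >= 3, spacing >= 0,
            phage_fraction >= 0, phage_fraction <= 1)
  gene_len <- (gene_len %/% 3L) * 3L
  structure(
    list(position = as.integer(position), n_genes = as.integer(n_genes),
         gene_len = as.integer(gene_len), spacing = as.integer(spacing),
         phage_fraction = phage_fraction, left_trna = left_trna,
         right_trna = right_trna, trna_len = as.integer(trna_len)),
    class = "sim_island"
  )
}

island_hull <- function(isl) {
  len <- isl$n_genes * isl$gene_len + (isl$n_genes - 1L) * isl$spacing
  c(isl$position, isl$position + len)
}

#' Define a simulation scenario
#'
#' A scenario fixes everything the generator needs: contig length, background
#' gene density and phage-hit rate, the implanted islands, and the seed. The
#' same scenario always produces byte-identical fixtures.
#'
#' @param seed Integer RNG seed.
#' @param contig_len Contig length, bp.
#' @param contig_id Contig name.
#' @param gene_density Background gene density, genes per kb.
#' @param background_hit_rate Fraction of background genes given strong
#'   (below-cutoff) phage hits.
#' @param weak_hit_rate Fraction of remaining genes given weak hits with
#'   e-value log-uniform in `[1e-4, 10]`, straddling nothing: these must never
#'   be flagged.
#' @param islands List of [sim_island()] objects; must be non-overlapping
#'   (including their tRNAs) and inside the contig.
#' @param decoys Optional decoy specification from [decoy_inject()].
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(seed = 1L, contig_len = 50000L,
                         contig_id = "contig_1", gene_density = 1,
                         background_hit_rate = 0, weak_hit_rate = 0.3,
                         islands = list(), decoys = NULL) {
  stopifnot(contig_len > 0, gene_density >= 0,
            background_hit_rate >= 0, background_hit_rate <= 1)
  if (length(islands) > 0 && inherits(islands, "sim_island")) {
    islands <- list(islands)
  }
  spans <- lapply(islands, function(isl) {
    h <- island_hull(isl)
    lo <- if (!is.null(isl$left_trna)) h[1] - isl$left_trna - isl$trna_len else h[1]
    hi <- if (!is.null(isl$right_trna)) h[2] + isl$right_trna + isl$trna_len else h[2]
    c(lo, hi)
  })
  if (length(spans) > 0) {
    ord <- order(vapply(spans, `[[`, numeric(1), 1))
    spans <- spans[ord]
    islands <- islands[ord]
    for (s in spans) {
      if (s[1] < 0 || s[2] > contig_len) {
        stop("island (with its tRNAs) extends outside the contig", call. = FALSE)
      }
    }
    if (length(spans) > 1) {
      lo <- vapply(spans, `[[`, numeric(1), 1)
      hi <- vapply(spans, `[[`, numeric(1), 2)
      if (any(lo[-1] < hi[-length(hi)])) {
        stop("islands overlap", call. = FALSE)
      }
    }
  }
  structure(
    list(seed = as.integer(seed), contig_len = as.integer(contig_len),
         contig_id = contig_id, gene_density = gene_density,
         background_hit_rate = background_hit_rate,
         weak_hit_rate = weak_hit_rate, islands = islands, decoys = decoys),
    class = "sim_scenario"
  )
}

#' Add sub-threshold decoy genes to a scenario
#'
#' Decoys are isolated background genes with very strong phage hits (default
#' e-value `1e-30`) placed `spacing` bp apart. At the default wide spacing no
#' 10 kb window ever holds eight of them, so a correct detector ignores them;
#' clustering them (small `spacing`) constructs a designed false positive to
#' probe the selection threshold. Decoys never enter the truth set.
#'
#' @param scenario A `sim_scenario`.
#' @param n_decoys Number of decoy genes.
#' @param spacing Gap between consecutive decoys, bp.
#' @param gene_len Decoy gene length, bp.
#' @param evalue Hit e-value assigned to every decoy.
#' @param start 0-based start of the first decoy (`NULL`: the start of the
#'   largest island-free gap).
#' @return The scenario with the decoy specification attached.
#' @export
decoy_inject <- function(scenario, n_decoys, spacing = 12000L,
                         gene_len = 600L, evalue = 1e-30, start = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"), n_decoys >= 0)
  scenario$decoys <- list(n = as.integer(n_decoys),
                          spacing = as.integer(spacing),
                          gene_len = (as.integer(gene_len) %/% 3L) * 3L,
                          evalue = evalue, start = start)
  scenario
}

# Run code with a fixed seed without disturbing the caller's RNG stream.
with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Random coding sequence: ATG + non-stop codons + TAA, total len bp.
random_cds_seq <- function(len) {
  codons <- stats::na.omit(names(Biostrings::getGeneticCode("11"))[
    Biostrings::getGeneticCode("11") != "*"])
  n_mid <- len %/% 3L - 2L
  paste0("ATG",
         paste(sample(codons, max(0L, n_mid), replace = TRUE), collapse = ""),
         "TAA")
}

#' Generate a synthetic fixture set
#'
#' Produces a genome, annotation, similarity-hit table and truth intervals
#' with the statistical structure the detector assumes: background genes at
#' the scenario's density, implanted high-phage-gene-density islands,
#' optional flanking tRNAs at integration-site positions, and a hit table
#' consistent with the implanted truth. The truth interval of an island is
#' the hull of its phage-flagged genes, extended to the outward coordinate of
#' a flanking tRNA when that tRNA lies within `trna_flank` of the hull border
#' (mirroring the detector's border rule); islands with no flagged gene
#' contribute no truth. Fully deterministic given `scenario$seed`.
#'
#' @param scenario A [sim_scenario()].
#' @param dir Optional output directory; when given, writes `genome.fasta`,
#'   `annotation.gff3`, `hits.tsv` and `truth.bed`.
#' @param trna_flank Border flank used when extending truth to tRNAs, bp.
#' @return List with `genome`, `features`, `hits`, `truth` tibbles and, when
#'   `dir` is given, `paths`.
#' @export
simulate_fixtures <- function(scenario, dir = NULL, trna_flank = 3000L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  with_sim_seed(scenario$seed, {
    ctg <- scenario$contig_id
    L <- scenario$contig_len

    feats <- list()
    phage_flag <- character(0)   # gene ids with strong hits
    decoy_ids <- character(0)
    truth <- list()

    # islands (already sorted/validated by sim_scenario)
    reserved <- matrix(numeric(0), ncol = 2)
    for (k in seq_along(scenario$islands)) {
      isl <- scenario$islands[[k]]
      starts <- isl$position +
        (seq_len(isl$n_genes) - 1L) * (isl$gene_len + isl$spacing)
      ids <- sprintf("island%d_g%d", k, seq_len(isl$n_genes))
      n_phage <- round(isl$phage_fraction * isl$n_genes)
      flagged <- if (n_phage > 0) sort(sample(seq_len(isl$n_genes), n_phage)) else integer(0)
      phage_flag <- c(phage_flag, ids[flagged])
      feats[[length(feats) + 1]] <- tibble::tibble(
        feature_id = ids, contig_id = ctg,
        start = as.integer(starts), end = as.integer(starts + isl$gene_len),
        strand = sample(c("+", "-"), isl$n_genes, replace = TRUE),
        ftype = "CDS", product = "island protein", phase = 0L
      )
      h <- island_hull(isl)
      lo <- h[1]; hi <- h[2]
      if (!is.null(isl$left_trna)) {
        ts <- h[1] - isl$left_trna - isl$trna_len
        feats[[length(feats) + 1]] <- tibble::tibble(
          feature_id = sprintf("island%d_trnaL", k), contig_id = ctg,
          start = as.integer(ts), end = as.integer(ts + isl$trna_len),
          strand = "+", ftype = "tRNA", product = "tRNA", phase = NA_integer_
        )
        lo <- ts
      }
      if (!is.null(isl$right_trna)) {
        ts <- h[2] + isl$right_trna
        feats[[length(feats) + 1]] <- tibble::tibble(
          feature_id = sprintf("island%d_trnaR", k), contig_id = ctg,
          start = as.integer(ts), end = as.integer(ts + isl$trna_len),
          strand = "-", ftype = "tRNA", product = "tRNA", phase = NA_integer_
        )
        hi <- ts + isl$trna_len
      }
      if (length(flagged) > 0) {
        t_lo <- starts[flagged[1]]
        t_hi <- starts[flagged[length(flagged)]] + isl$gene_len
        if (!is.null(isl$left_trna)) {
          trna_s <- h[1] - isl$left_trna - isl$trna_len
          trna_e <- h[1] - isl$left_trna
          if (trna_s < t_lo + trna_flank && trna_e > t_lo - trna_flank) {
            t_lo <- min(t_lo, trna_s)
          }
        }
        if (!is.null(isl$right_trna)) {
          trna_s <- h[2] + isl$right_trna
          trna_e <- trna_s + isl$trna_len
          if (trna_s < t_hi + trna_flank && trna_e > t_hi - trna_flank) {
            t_hi <- max(t_hi, trna_e)
          }
        }
        truth[[length(truth) + 1]] <- tibble::tibble(
          contig_id = ctg, start = as.integer(t_lo), end = as.integer(t_hi))
      }
      reserved <- rbind(reserved, c(lo, hi))
    }

    # decoys: isolated strong-hit genes in island-free space
    if (!is.null(scenario$decoys) && scenario$decoys$n > 0) {
      d <- scenario$decoys
      d_start <- d$start
      if (is.null(d_start)) {
        gaps <- free_gaps(reserved, L)
        d_start <- gaps[which.max(gaps[, 2] - gaps[, 1]), 1] + 100
      }
      starts <- d_start + (seq_len(d$n) - 1L) * d$spacing
      if (any(starts + d$gene_len > L)) {
        stop("decoys extend outside the contig", call. = FALSE)
      }
      ids <- sprintf("decoy_g%d", seq_len(d$n))
      decoy_ids <- ids
      feats[[length(feats) + 1]] <- tibble::tibble(
        feature_id = ids, contig_id = ctg,
        start = as.integer(starts), end = as.integer(starts + d$gene_len),
        strand = sample(c("+", "-"), d$n, replace = TRUE),
        ftype = "CDS", product = "decoy protein", phase = 0L
      )
      reserved <- rbind(reserved, cbind(starts, starts + d$gene_len))
    }

    # background genes fill the remaining gaps at the stated density
    bg_len <- 900L
    if (scenario$gene_density > 0) {
      pitch <- max(bg_len + 50L, round(1000 / scenario$gene_density))
      gaps <- free_gaps(reserved, L)
      bg_starts <- integer(0)
      for (gi in seq_len(nrow(gaps))) {
        lo <- gaps[gi, 1] + 50
        while (lo + bg_len <= gaps[gi, 2] - 50) {
          bg_starts <- c(bg_starts, as.integer(lo))
          lo <- lo + pitch + sample.int(50L, 1L)
        }
      }
      if (length(bg_starts) > 0) {
        ids <- sprintf("bg_g%d", seq_along(bg_starts))
        n_strong <- stats::rbinom(1, length(ids), scenario$background_hit_rate)
        strong <- if (n_strong > 0) sample(seq_along(ids), n_strong) else integer(0)
        phage_flag <- c(phage_flag, ids[strong])
        feats[[length(feats) + 1]] <- tibble::tibble(
          feature_id = ids, contig_id = ctg,
          start = bg_starts, end = bg_starts + bg_len,
          strand = sample(c("+", "-"), length(ids), replace = TRUE),
          ftype = "CDS", product = "background protein", phase = 0L
        )
      }
    }

    features <- dplyr::arrange(dplyr::bind_rows(feats), .data$start)

    # genome sequence: random background, coding regions overwritten
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    cds <- features[features$ftype == "CDS", ]
    for (i in seq_len(nrow(cds))) {
      s <- random_cds_seq(cds$end[i] - cds$start[i])
      if (cds$strand[i] == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      base[(cds$start[i] + 1):cds$end[i]] <- strsplit(s, "")[[1]]
    }
    genome <- tibble::tibble(contig_id = ctg,
                             sequence = paste(base, collapse = ""),
                             length = L)

    # hit table consistent with the flags
    gene_rows <- features[features$ftype == "CDS", ]
    strong_ids <- sort(unique(phage_flag))
    rest <- setdiff(gene_rows$feature_id, c(strong_ids, decoy_ids))
    weak_ids <- rest[stats::runif(length(rest)) < scenario$weak_hit_rate]
    mk_hits <- function(ids, ev) {
      if (length(ids) == 0) return(NULL)
      qlen <- as.integer((gene_rows$end[match(ids, gene_rows$feature_id)] -
                            gene_rows$start[match(ids, gene_rows$feature_id)]) / 3)
      tibble::tibble(
        gene_id = ids,
        subject_id = sprintf("phageprot_%04d", sample.int(9999L, length(ids),
                                                          replace = TRUE)),
        pident = round(stats::runif(length(ids), 35, 95), 1),
        length = qlen, mismatches = 0L, gapopens = 0L,
        qstart = 1L, qend = qlen, sstart = 1L, send = qlen,
        evalue = ev, bitscore = round(stats::runif(length(ids), 60, 500), 1)
      )
    }
    ev_strong <- 10^stats::runif(length(strong_ids), -50, -6)
    ev_weak <- 10^stats::runif(length(weak_ids), -4, 1)
    hits <- dplyr::bind_rows(
      mk_hits(strong_ids, ev_strong),
      mk_hits(weak_ids, ev_weak),
      if (length(decoy_ids) > 0) mk_hits(decoy_ids,
                                         rep(scenario$decoys$evalue,
                                             length(decoy_ids)))
    )
    if (is.null(hits)) hits <- mk_hits(character(0), numeric(0))
    hits <- dplyr::arrange(hits, .data$gene_id)

    truth <- if (length(truth) > 0) {
      dplyr::arrange(dplyr::bind_rows(truth), .data$start)
    } else {
      tibble::tibble(contig_id = character(), start = integer(),
                     end = integer())
    }

    out <- list(genome = genome, features = features, hits = hits,
                truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        fasta = file.path(dir, "genome.fasta"),
        gff = file.path(dir, "annotation.gff3"),
        hits = file.path(dir, "hits.tsv"),
        truth = file.path(dir, "truth.bed")
      )
      dna <- Biostrings::DNAStringSet(stats::setNames(genome$sequence,
                                                      genome$contig_id))
      Biostrings::writeXStringSet(dna, paths$fasta)
      write_gff3(features, genome, paths$gff)
      write_hits(hits, paths$hits)
      write_bed(dplyr::mutate(truth,
                              name = paste0("truth_", dplyr::row_number())),
                paths$truth)
      out$paths <- paths
    }
    out
  })
}

# Complement of reserved [lo,hi) rows within [0, L).
free_gaps <- function(reserved, L) {
  if (nrow(reserved) == 0) return(matrix(c(0, L), ncol = 2))
  reserved <- reserved[order(reserved[, 1]), , drop = FALSE]
  lo <- c(0, reserved[, 2])
  hi <- c(reserved[, 1], L)
  keep <- hi - lo > 0
  cbind(lo[keep], hi[keep])
}

#' Write features as GFF3
#'
#' Emits the 9-column GFF3 the pipeline consumes, converting the internal
#' 0-based half-open coordinates back to 1-based inclusive at the boundary.
#'
#' @param features Feature tibble.
#' @param genome Contig table (for `##sequence-region` headers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, genome, path) {
  hdr <- c("##gff-version 3",
           sprintf("##sequence-region %s 1 %d", genome$contig_id,
                   genome$length))
  body <- sprintf(
    "%s\tprophagescan_sim\t%s\t%d\t%d\t.\t%s\t%s\tID=%s;product=%s",
    features$contig_id, features$ftype, features$start + 1L, features$end,
    features$strand,
    ifelse(is.na(features$phase), ".", as.character(features$phase)),
    features$feature_id, features$product
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a hit table in 12-column tabular format
#'
#' @param hits Hit tibble as returned by [read_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f",
                   hits$gene_id, hits$subject_id, hits$pident, hits$length,
                   hits$mismatches, hits$gapopens, hits$qstart, hits$qend,
                   hits$sstart, hits$send, hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}
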