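# Cohort orchestration: scan every genome, tabulate the survey, build
# the two phylogenies (concatenated cluster proteins; five-gene MLSA),
# and serialize architectures as JSON / cohort tables as TSV. Outputs
# are deterministic given inputs, thresholds and seed.

#' Scan a cohort of genomes for the reference cluster
#'
#' Runs [scan_genome()] over every genome; unreadable or failing genomes
#' are recorded as FAILED and the run continues.
#'
#' @param genomes Named list of `eps_genome` objects, or a character
#'   vector of genome directories for [read_genome()].
#' @param reference Reference bundle (cluster + catalog tibbles).
#' @param thresholds An [eps_thresholds()] list.
#' @param window,gap_threshold Passed to [scan_genome()].
#' @return Object of class `eps_scan`: list with `architectures` (named
#'   list), `summary` (one [glance()] row per genome plus a `failed`
#'   flag), `thresholds`.
#' @export
scan_cohort <- function(genomes, reference = synthetic_reference_cluster(),
                        thresholds = eps_thresholds(), window = 30,
                        gap_threshold = 3000) {
  if (is.character(genomes)) {
    dirs <- genomes
    genomes <- lapply(dirs, function(d) tryCatch(read_genome(d),
                                                 error = function(e) e))
    names(genomes) <- basename(dirs)
  }
  res <- purrr::imap(genomes, function(g, id) {
    if (!inherits(g, "eps_genome")) {
      msg <- if (inherits(g, "condition")) conditionMessage(g)
             else "not an eps_genome object"
      return(structure(list(genome_id = id, error = msg),
                       class = "eps_scan_failure"))
    }
    tryCatch(
      scan_genome(g, reference, thresholds, window, gap_threshold),
      error = function(e) structure(list(genome_id = id,
                                         error = conditionMessage(e)),
                                    class = "eps_scan_failure")
    )
  })
  summary <- purrr::map_dfr(res, function(r) {
    if (inherits(r, "eps_scan_failure")) {
      return(tibble(genome_id = r$genome_id, found = NA, failed = TRUE))
    }
    glance(r) |> mutate(failed = FALSE)
  })
  structure(list(architectures = res[!purrr::map_lgl(res, inherits,
                                                     "eps_scan_failure")],
                 summary = summary, thresholds = thresholds),
            class = "eps_scan")
}

#' @export
print.eps_scan <- function(x, ...) {
  cat("<eps_scan> ", nrow(x$summary), " genome(s): ",
      sum(x$summary$found, na.rm = TRUE), " with cluster, ",
      sum(!x$summary$found, na.rm = TRUE), " without, ",
      sum(x$summary$failed), " failed\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.eps_scan <- function(x, ...) {
  tibble(
    n_genomes = nrow(x$summary),
    n_found = sum(x$summary$found, na.rm = TRUE),
    n_negative = sum(!x$summary$found, na.rm = TRUE),
    n_failed = sum(x$summary$failed),
    n_split = sum(x$summary$split, na.rm = TRUE),
    n_excluded_contig_edge = sum(x$summary$excluded_contig_edge,
                                 na.rm = TRUE)
  )
}

#' @exportS3Method generics::tidy
tidy.eps_scan <- function(x, ...) {
  purrr::map_dfr(x$architectures, tidy)
}

#' Extract assigned slot protein sequences per gene
#'
#' For each reference label, the proteins assigned to that slot across
#' the scanned genomes (PRESENT and TRUNCATED slots; fragments and
#' pseudogenes carry no single translation). Optionally includes the
#' reference protein as taxon `"ref"`.
#'
#' @param scan An `eps_scan`.
#' @param genomes The named genome list that was scanned.
#' @param reference Reference bundle.
#' @param include_reference Add the reference taxon to every gene set.
#' @return Named list (per label) of named character vectors
#'   (taxon -> sequence).
#' @export
slot_sequences <- function(scan, genomes,
                           reference = synthetic_reference_cluster(),
                           include_reference = TRUE) {
  labels <- reference$cluster$label
  out <- lapply(labels, function(lb) {
    seqs <- c()
    for (a in scan$architectures) {
      row <- a$slots |> filter(.data$label == lb)
      if (nrow(row) != 1 || !row$status %in% c("PRESENT", "TRUNCATED")) next
      tag <- row$locus_tags[[1]][1]
      g <- genomes[[a$genome_id]]
      s <- g$link$sequence[g$link$locus_tag == tag]
      if (length(s) == 1 && !is.na(s)) seqs[a$genome_id] <- s
    }
    if (include_reference) {
      seqs["ref"] <- reference$cluster$sequence[
        reference$cluster$label == lb]
    }
    seqs
  })
  names(out) <- labels
  out
}

#' Neighbor-Joining tree of concatenated cluster proteins
#'
#' Per-gene MAFFT alignments of the assigned slot proteins, concatenated
#' in cluster order with all-gap blocks for absent genes, Poisson-
#' corrected p-distances under pairwise deletion, NJ, and seeded
#' bootstrap.
#'
#' @param scan An `eps_scan` (only genomes with a detected cluster
#'   contribute).
#' @param genomes The named genome list that was scanned.
#' @param reference Reference bundle.
#' @param n_replicates Bootstrap replicates (default 1000; 0 skips the
#'   bootstrap).
#' @param seed Integer seed for the bootstrap.
#' @param include_reference Include the reference taxon.
#' @return Object of class `eps_tree`: list with `tree` (`phylo`,
#'   node labels showing supports > 70), `support`, `alignment`,
#'   `blocks`, `mode = "cluster-proteins"`.
#' @export
cluster_protein_tree <- function(scan, genomes,
                                 reference = synthetic_reference_cluster(),
                                 n_replicates = 1000, seed = 1,
                                 include_reference = TRUE) {
  gene_seqs <- slot_sequences(scan, genomes, reference, include_reference)
  gene_seqs <- gene_seqs[vapply(gene_seqs, length, integer(1)) >= 2]
  if (length(gene_seqs) == 0) abort("no gene with >= 2 sequences")
  alns <- lapply(gene_seqs, align_sequences, mode = "protein")
  conc <- concatenate_alignments(alns)
  .finish_tree(conc, correction = "poisson", n_replicates, seed,
               mode = "cluster-proteins")
}

#' Five-gene MLSA Neighbor-Joining tree
#'
#' MAFFT alignments of the five housekeeping genes, the published
#' extraction ranges mapped through the reference row, concatenation,
#' Jukes-Cantor distances under pairwise deletion, NJ, and seeded
#' bootstrap.
#'
#' @param housekeeping Tibble `genome_id`/`gene`/`sequence` including
#'   the reference taxon rows.
#' @param reference_taxon Reference taxon name (default `"ref"`).
#' @param ranges Extraction ranges; default [mlsa_reference_ranges()].
#' @param n_replicates Bootstrap replicates (default 1000; 0 skips).
#' @param seed Integer seed.
#' @return An `eps_tree` (`mode = "mlsa"`).
#' @export
mlsa_tree <- function(housekeeping, reference_taxon = "ref",
                      ranges = mlsa_reference_ranges(),
                      n_replicates = 1000, seed = 1) {
  alns <- lapply(ranges$gene, function(g) {
    rows <- housekeeping |> filter(.data$gene == g)
    if (nrow(rows) < 2) abort(paste0("fewer than 2 sequences for ", g))
    align_sequences(setNames(rows$sequence, rows$genome_id), mode = "dna")
  })
  names(alns) <- ranges$gene
  conc <- mlsa_extract(alns, reference_taxon = reference_taxon,
                       ranges = ranges)
  .finish_tree(conc, correction = "jc", n_replicates, seed, mode = "mlsa")
}

.finish_tree <- function(conc, correction, n_replicates, seed, mode) {
  if (length(conc$alignment) < 4 && n_replicates > 0) {
    abort("bootstrap requires at least 4 taxa")
  }
  if (n_replicates > 0) {
    bs <- bootstrap_support(conc$alignment, n_replicates = n_replicates,
                            seed = seed, correction = correction)
    tree <- bs$tree
    support <- bs$support
  } else {
    tree <- nj_tree(p_distance_matrix(conc$alignment, correction))
    support <- NULL
  }
  structure(list(tree = tree, support = support,
                 alignment = conc$alignment, blocks = conc$blocks,
                 mode = mode, correction = correction,
                 n_replicates = n_replicates, seed = seed),
            class = "eps_tree")
}

#' @export
print.eps_tree <- function(x, ...) {
  cat("<eps_tree> ", x$mode, ": ", length(x$tree$tip.label), " taxa, ",
      nrow(x$blocks), " gene block(s), ",
      unique(nchar(x$alignment))[1], " columns, ", x$correction,
      " correction", sep = "")
  if (!is.null(x$support)) {
    cat(", ", x$n_replicates, " bootstrap replicates", sep = "")
  }
  cat("\n  ", ape::write.tree(x$tree), "\n", sep = "")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

#' Write a per-genome architecture record as JSON
#'
#' @param arch An `eps_architecture`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_architecture_json <- function(arch, path) {
  x <- list(
    genome_id = arch$genome_id,
    found = arch$found,
    seed_label = arch$seed_label,
    thresholds = unclass(arch$thresholds),
    slots = tidy(arch),
    insertions = if (nrow(arch$insertions) > 0) {
      tibble(after = arch$insertions$after,
             before = arch$insertions$before,
             locus_tags = purrr::map_chr(arch$insertions$locus_tags,
                                         paste, collapse = ";"),
             assigned = purrr::map_chr(arch$insertions$assigned,
                                       paste, collapse = ";"))
    } else NULL,
    split = arch$split,
    split_parts = arch$split_parts,
    separation_bp = arch$separation_bp,
    excluded_contig_edge = arch$excluded_contig_edge,
    synteny_fraction = arch$synteny_fraction
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Write the cohort architecture table as TSV
#'
#' Rows are genomes, columns are reference labels, cells are
#' `status:identity` (identity omitted for absent slots).
#'
#' @param scan An `eps_scan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(scan, path) {
  long <- tidy(scan) |>
    mutate(cell = ifelse(.data$status == "ABSENT", "ABSENT",
                         paste0(.data$status, ":",
                                round(.data$identity_pct, 1))))
  wide <- long |>
    select("genome_id", "label", "cell") |>
    tidyr::pivot_wider(names_from = "label", values_from = "cell")
  utils::write.table(wide, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
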