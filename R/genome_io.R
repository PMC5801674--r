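# Readers and writers for the NCBI assembly two-file convention:
# protein.faa (amino-acid FASTA keyed by protein_id) and
# cds_from_genomic.fna (nucleotide FASTA with [locus_tag=..] [location=..]
# bracket tokens). Internal coordinates are 0-based half-open; all
# user-facing text is 1-based inclusive.

#' Read an NCBI-style protein FASTA
#'
#' Parses `protein.faa`: one record per entry, `protein_id` taken from the
#' first whitespace-delimited header token, the remainder kept as the
#' product annotation. Trailing `*` stop symbols are stripped so that
#' protein lengths match the length semantics used by the alignment-length
#' ratios.
#'
#' @param path Path to a protein FASTA file.
#' @return A tibble with columns `protein_id`, `product`, `sequence`,
#'   `length` (residues).
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(paste0("empty protein FASTA: ", path))
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  products <- ifelse(grepl("\\s", headers),
                     sub("^\\S+\\s+", "", headers), "")
  seqs <- unname(sub("\\*+$", "", as.character(aa)))
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad)) {
    abort(paste0("non-amino-acid characters in protein records: ",
                 paste(ids[bad], collapse = ", ")))
  }
  if (any(nchar(seqs) == 0)) {
    abort(paste0("zero-length protein sequence: ",
                 paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  tibble(
    protein_id = unname(ids),
    product = unname(products),
    sequence = seqs,
    length = nchar(seqs)
  )
}

#' Parse an NCBI `[location=...]` token
#'
#' Handles plain `123..456`, `complement(...)` and `join(...)` forms.
#' `join(...)` collapses to its envelope and is flagged multi-segment;
#' sub-exon structure is never used downstream.
#'
#' @param text Location text (without the `[location=]` wrapper).
#' @return A list with `start` (0-based inclusive), `end` (0-based
#'   exclusive), `strand` (`"+"`/`"-"`) and `multi_segment` (logical).
#' @export
parse_ncbi_location <- function(text) {
  raw <- gsub("\\s", "", text)
  strand <- "+"
  body <- raw
  if (grepl("^complement\\(", body)) {
    strand <- "-"
    body <- sub("^complement\\((.*)\\)$", "\\1", body)
  }
  multi <- FALSE
  if (grepl("^join\\(", body)) {
    multi <- TRUE
    body <- sub("^join\\((.*)\\)$", "\\1", body)
  }
  # segments like 10..20 (possibly with <,> partial markers)
  segs <- strsplit(body, ",", fixed = TRUE)[[1]]
  m <- regmatches(segs, regexec("^[<>]?(\\d+)\\.\\.[<>]?(\\d+)$", segs))
  ok <- vapply(m, length, integer(1)) == 3L
  if (!all(ok) || length(segs) == 0) {
    abort(paste0("unparseable location: ", text))
  }
  starts <- vapply(m, function(x) as.integer(x[2]), integer(1))
  ends <- vapply(m, function(x) as.integer(x[3]), integer(1))
  list(
    start = min(starts) - 1L,
    end = max(ends),
    strand = strand,
    multi_segment = multi
  )
}

#' Format internal coordinates as NCBI location text
#'
#' Inverse of [parse_ncbi_location()] for single-segment features:
#' 0-based half-open in, 1-based inclusive text out.
#'
#' @param start,end Internal coordinates (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @return Location string, e.g. `"complement(123..456)"`.
#' @export
format_ncbi_location <- function(start, end, strand = "+") {
  body <- paste0(start + 1L, "..", end)
  ifelse(strand == "-", paste0("complement(", body, ")"), body)
}

#' Read CDS features from an NCBI `cds_from_genomic.fna`
#'
#' Parses the bracket-token headers: `[locus_tag=...]`, `[location=...]`,
#' optional `[protein_id=...]` and `[pseudo=true]`. The contig id is taken
#' from the first header token (`lcl|<contig>_cds_...` or plain). Ordinals
#' rank CDS along each contig by start coordinate. Headers lacking both a
#' locus_tag and a location are skipped with a warning.
#'
#' @param path Path to a cds_from_genomic FASTA file.
#' @return A tibble with columns `locus_tag`, `contig_id`, `start`, `end`
#'   (0-based half-open), `strand`, `pseudo`, `multi_segment`,
#'   `protein_id` (NA when absent) and `ordinal`.
#' @export
read_cds_features <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  nt <- Biostrings::readDNAStringSet(path)
  if (length(nt) == 0) abort(paste0("empty CDS FASTA: ", path))
  headers <- names(nt)

  token <- function(h, key) {
    m <- regmatches(h, regexec(paste0("\\[", key, "=([^]]*)\\]"), h))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  locus <- token(headers, "locus_tag")
  loc_text <- token(headers, "location")
  prot <- token(headers, "protein_id")
  pseudo <- !is.na(token(headers, "pseudo"))

  first_tok <- sub("\\s.*$", "", headers)
  contig <- sub("^lcl\\|", "", first_tok)
  contig <- sub("_cds.*$", "", contig)

  drop <- is.na(locus) & is.na(loc_text)
  if (any(drop)) {
    warn(paste0(sum(drop), " CDS header(s) lacking locus_tag and location",
                " skipped in ", basename(path)))
  }
  keep <- which(!drop)
  if (length(keep) == 0) abort(paste0("no usable CDS headers in ", path))
  missing_loc <- keep[is.na(loc_text[keep])]
  if (length(missing_loc) > 0) {
    abort(paste0("CDS without [location=]: ",
                 paste(locus[missing_loc], collapse = ", ")))
  }
  parsed <- lapply(loc_text[keep], parse_ncbi_location)
  feats <- tibble(
    locus_tag = locus[keep],
    contig_id = contig[keep],
    start = vapply(parsed, `[[`, integer(1), "start"),
    end = vapply(parsed, `[[`, integer(1), "end"),
    strand = vapply(parsed, `[[`, character(1), "strand"),
    pseudo = pseudo[keep],
    multi_segment = vapply(parsed, `[[`, logical(1), "multi_segment"),
    protein_id = prot[keep]
  )
  feats |>
    arrange(.data$contig_id, .data$start, .data$end) |>
    group_by(.data$contig_id) |>
    mutate(ordinal = row_number()) |>
    ungroup()
}

#' Link protein records to CDS features
#'
#' Joins through the CDS `[protein_id=...]` token (NCBI protein.faa headers
#' carry no locus tags). Pseudogene features legitimately lack a protein;
#' other unmatched records on either side are counted and reported.
#'
#' @param proteins Tibble from [read_protein_fasta()].
#' @param features Tibble from [read_cds_features()].
#' @param genome_id Identifier for the assembly.
#' @return An object of class `eps_genome`: a list with `genome_id`,
#'   `proteins`, `features`, and `link` (one row per CDS, protein columns
#'   NA where no translation exists).
#' @export
link_genome <- function(proteins, features, genome_id = "genome") {
  dup_p <- proteins$protein_id[duplicated(proteins$protein_id)]
  dup_f <- features$locus_tag[duplicated(features$locus_tag)]
  if (length(dup_p) > 0 || length(dup_f) > 0) {
    abort(paste0("duplicate identifiers: ",
                 paste(unique(c(dup_p, dup_f)), collapse = ", ")))
  }
  link <- features |>
    left_join(proteins, by = "protein_id")
  orphan_feat <- sum(!link$pseudo & is.na(link$sequence))
  orphan_prot <- sum(!proteins$protein_id %in% features$protein_id)
  if (orphan_feat > 0) {
    inform(paste0(genome_id, ": ", orphan_feat,
                  " non-pseudo CDS without a protein record"))
  }
  if (orphan_prot > 0) {
    inform(paste0(genome_id, ": ", orphan_prot,
                  " protein record(s) without a CDS feature"))
  }
  structure(
    list(genome_id = genome_id, proteins = proteins,
         features = features, link = link),
    class = "eps_genome"
  )
}

#' @export
print.eps_genome <- function(x, ...) {
  cat("<eps_genome> ", x$genome_id, "\n", sep = "")
  cat("  ", nrow(x$proteins), " proteins, ", nrow(x$features),
      " CDS features on ", length(unique(x$features$contig_id)),
      " contig(s), ", sum(x$features$pseudo), " pseudo\n", sep = "")
  invisible(x)
}

#' Read a genome directory
#'
#' Expects `protein.faa` and `cds_from_genomic.fna` under `dir`; both are
#' required.
#'
#' @param dir Directory containing the two files.
#' @param genome_id Assembly identifier; defaults to the directory name.
#' @return An `eps_genome`.
#' @export
read_genome <- function(dir, genome_id = basename(dir)) {
  p <- file.path(dir, "protein.faa")
  f <- file.path(dir, "cds_from_genomic.fna")
  link_genome(read_protein_fasta(p), read_cds_features(f), genome_id)
}

#' Write a genome back to the two-file convention
#'
#' Emits `protein.faa` and `cds_from_genomic.fna` under `dir` in the same
#' dialect the readers consume, so that a read/write/read round trip is
#' field-by-field identical. CDS nucleotide bodies are written as literal
#' `N` runs of the feature span length when real sequence is not tracked.
#'
#' @param genome An `eps_genome`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- genome$proteins
  prot_lines <- character(0)
  if (nrow(p) > 0) {
    hdr <- paste0(">", p$protein_id,
                  ifelse(p$product == "", "", paste0(" ", p$product)))
    prot_lines <- as.vector(rbind(hdr, p$sequence))
  }
  writeLines(prot_lines, file.path(dir, "protein.faa"))

  f <- genome$features |> arrange(.data$contig_id, .data$start)
  hdr <- paste0(
    ">lcl|", f$contig_id, "_cds_", f$locus_tag,
    " [locus_tag=", f$locus_tag, "]",
    ifelse(is.na(f$protein_id), "", paste0(" [protein_id=", f$protein_id, "]")),
    ifelse(f$pseudo, " [pseudo=true]", ""),
    " [location=", format_ncbi_location(f$start, f$end, f$strand), "]"
  )
  body <- strrep("N", f$end - f$start)
  writeLines(as.vector(rbind(hdr, body)),
             file.path(dir, "cds_from_genomic.fna"))
  invisible(dir)
}
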