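# Distance phylogenetics: p-distances with pairwise deletion, Poisson and
# Jukes-Cantor corrections, Neighbor-Joining (Saitou-Nei, via ape) with
# negative branch lengths clamped to zero, seeded column-resampling
# bootstrap, concatenation of per-gene protein alignments, and the
# five-gene MLSA extraction in reference coordinates.

.aln_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  stopifnot(!is.null(names(alignment)))
  w <- unique(nchar(alignment))
  if (length(w) != 1) abort("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(unname(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

.aln_strings <- function(m) {
  setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

GAP_CHARS <- c("-", ".")

#' Proportion of differing sites between two aligned rows
#'
#' Pairwise deletion: columns where either row carries a gap are
#' excluded; p is the fraction of the remaining columns that differ.
#'
#' @param a,b Aligned sequences of equal length (strings).
#' @return p in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("rows must have equal length")
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  keep <- !(x %in% GAP_CHARS | y %in% GAP_CHARS)
  if (!any(keep)) abort("no comparable columns (all gapped)")
  mean(x[keep] != y[keep])
}

#' Poisson correction for protein distances
#'
#' d = -ln(1 - p); undefined at p >= 1.
#'
#' @param p Proportion(s) of differing sites, in `[0, 1)`.
#' @return Corrected distance(s).
#' @export
poisson_correct <- function(p) {
  if (any(p < 0 | p >= 1)) abort("poisson correction requires 0 <= p < 1")
  -log(1 - p)
}

#' Jukes-Cantor correction for nucleotide distances
#'
#' d = -(3/4) ln(1 - (4/3) p); undefined at p >= 0.75.
#'
#' @param p Proportion(s) of differing sites, in `[0, 0.75)`.
#' @return Corrected distance(s).
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0 | p >= 0.75)) {
    abort("Jukes-Cantor correction requires 0 <= p < 0.75")
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' Pairwise distance matrix from an alignment
#'
#' p-distances under pairwise deletion, optionally corrected (Poisson for
#' proteins, Jukes-Cantor for nucleotides).
#'
#' @param alignment Named character vector of aligned rows, or a
#'   character matrix with taxa as rownames.
#' @param correction `"none"`, `"poisson"` or `"jc"`.
#' @return Symmetric numeric matrix with taxa dimnames.
#' @export
p_distance_matrix <- function(alignment,
                              correction = c("none", "poisson", "jc")) {
  correction <- match.arg(correction)
  m <- .aln_matrix(alignment)
  n <- nrow(m)
  if (n < 2) abort("need at least 2 taxa")
  gap <- matrix(m %in% GAP_CHARS, nrow = n)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      keep <- !(gap[i, ] | gap[j, ])
      if (!any(keep)) abort(paste0("no comparable columns between ",
                                   rownames(m)[i], " and ", rownames(m)[j]))
      p <- mean(m[i, keep] != m[j, keep])
      d <- switch(correction, none = p, poisson = poisson_correct(p),
                  jc = jukes_cantor(p))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-Joining tree
#'
#' Saitou-Nei agglomeration on a symmetric distance matrix; negative
#' branch lengths (an artifact of the NJ algebra) are clamped to zero and
#' the clamped total is reported as an attribute.
#'
#' @param D Symmetric distance matrix with taxa dimnames.
#' @return An unrooted `phylo`; `attr(, "clamped")` carries the summed
#'   negative branch length that was clamped.
#' @export
nj_tree <- function(D) {
  if (!isSymmetric(unname(as.matrix(D)), tol = 1e-8)) {
    abort("distance matrix must be symmetric")
  }
  D <- as.matrix(D)
  if (nrow(D) == 2) {
    tr <- ape::read.tree(text = paste0("(", rownames(D)[1], ":",
                                       D[1, 2] / 2, ",", rownames(D)[2],
                                       ":", D[1, 2] / 2, ");"))
    attr(tr, "clamped") <- 0
    return(tr)
  }
  if (nrow(D) == 3) {
    # closed form: leaf i gets (d_ij + d_ik - d_jk) / 2
    len <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
             (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
             (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    clamped <- -sum(pmin(len, 0))
    len <- pmax(len, 0)
    tr <- ape::read.tree(text = paste0(
      "(", rownames(D)[1], ":", len[1], ",", rownames(D)[2], ":", len[2],
      ",", rownames(D)[3], ":", len[3], ");"))
    attr(tr, "clamped") <- clamped
    return(tr)
  }
  tr <- ape::nj(D)
  clamped <- -sum(pmin(tr$edge.length, 0))
  tr$edge.length <- pmax(tr$edge.length, 0)
  attr(tr, "clamped") <- clamped
  tr
}

#' Bootstrap supports for a tree by column resampling
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate under the same distance settings, and reports for each
#' internal edge of the full-data tree the percentage of replicates
#' containing that bipartition. Seeded and bit-reproducible.
#'
#' @param alignment Named character vector or matrix of aligned rows.
#' @param n_replicates Number of replicates (>= 1; surveys typically use
#'   1000).
#' @param seed Integer seed.
#' @param correction Distance correction, as in [p_distance_matrix()].
#' @return List: `tree` (the full-data NJ tree with `node.label` set to
#'   the support percentages) and `support` (numeric vector per internal
#'   node, in `[0, 100]`).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000, seed = 1,
                              correction = "none") {
  stopifnot(n_replicates >= 1)
  m <- .aln_matrix(alignment)
  if (nrow(m) < 4) abort("bootstrap requires at least 4 taxa")
  full <- nj_tree(p_distance_matrix(m, correction))
  boots <- withr::with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      nj_tree(p_distance_matrix(m[, cols, drop = FALSE], correction))
    })
  })
  counts <- ape::prop.clades(full, part = ape::prop.part(boots),
                             rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_replicates
  full$node.label <- format_support_labels(support)
  list(tree = full, support = support)
}

#' Display filter for bootstrap supports
#'
#' Supports are shown only when above the display threshold (the
#' convention used in published trees: values above 70 from 1000
#' replicates); others become empty labels. The underlying numeric
#' support vector is unaffected.
#'
#' @param support Numeric supports in `[0, 100]`.
#' @param min_show Display threshold (default 70, exclusive).
#' @return Character labels.
#' @export
format_support_labels <- function(support, min_show = 70) {
  ifelse(support > min_show, as.character(round(support)), "")
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' @param t1,t2 `phylo` objects over the same taxon set.
#' @return Non-negative integer; 0 means identical topologies.
#' @export
robinson_foulds <- function(t1, t2) {
  as.integer(ape::dist.topo(ape::unroot(t1), ape::unroot(t2),
                            method = "PH85"))
}

# ---- alignment construction ------------------------------------------------

#' Align sequences with MAFFT
#'
#' Thin wrapper over the MAFFT binary (`--auto --quiet`), the aligner
#' used for the published MLSA. Sequences must share one alphabet.
#' Externally produced alignments can be supplied via
#' [import_alignment()] instead.
#'
#' @param sequences Named character vector (>= 2 sequences).
#' @param mode `"protein"` or `"dna"`.
#' @return Named character vector of aligned rows (equal lengths).
#' @export
align_sequences <- function(sequences, mode = c("protein", "dna")) {
  mode <- match.arg(mode)
  if (length(sequences) < 2) abort("need at least 2 sequences")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    abort("sequences must have unique names")
  }
  looks_dna <- !grepl("[^ACGTNacgtn]", sequences)
  if (mode == "dna" && !all(looks_dna)) {
    abort("mixed alphabets: non-nucleotide characters in dna mode")
  }
  if (mode == "protein" && all(looks_dna)) {
    warn("sequences look nucleotide but mode is protein")
  }
  mafft <- Sys.which("mafft")
  if (mafft == "") abort("mafft not found on PATH")
  tmp_in <- tempfile(fileext = ".fasta")
  tmp_out <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  writeLines(as.vector(rbind(paste0(">", names(sequences)),
                             unname(sequences))), tmp_in)
  status <- system2(mafft, c("--auto", "--quiet", tmp_in),
                    stdout = tmp_out, stderr = FALSE)
  if (status != 0) abort(paste0("mafft failed with status ", status))
  import_alignment(tmp_out)
}

#' Import an aligned FASTA
#'
#' Rows must have equal lengths; imported verbatim (uppercased).
#'
#' @param path Aligned FASTA path.
#' @return Named character vector of aligned rows.
#' @export
import_alignment <- function(path) {
  s <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(s))
  names(rows) <- sub("\\s.*$", "", names(s))
  if (length(unique(nchar(rows))) != 1) {
    abort("imported alignment rows have unequal lengths")
  }
  rows
}

#' Concatenate per-gene alignments with gap fill
#'
#' Blocks are concatenated in the given order; a taxon absent from a
#' block receives an all-gap row of that block's width (absent genes are
#' tolerated rather than dropping the genome). Taxa absent from every
#' block are excluded with a warning.
#'
#' @param alignments Named list of named character vectors (per-gene
#'   alignments).
#' @param taxa Optional taxon order; defaults to the union across blocks.
#' @return List: `alignment` (named character vector), `blocks` (tibble
#'   `gene`/`start`/`end`/`width`, 1-based column ranges).
#' @export
concatenate_alignments <- function(alignments, taxa = NULL) {
  stopifnot(length(alignments) >= 1)
  all_taxa <- unique(unlist(lapply(alignments, names)))
  taxa <- taxa %||% all_taxa
  missing_everywhere <- setdiff(taxa, all_taxa)
  if (length(missing_everywhere) > 0) {
    warn(paste0("taxa absent from every block excluded: ",
                paste(missing_everywhere, collapse = ", ")))
    taxa <- setdiff(taxa, missing_everywhere)
  }
  widths <- vapply(alignments, function(a) unique(nchar(a))[1], numeric(1))
  ends <- cumsum(widths)
  blocks <- tibble(
    gene = names(alignments) %||% as.character(seq_along(alignments)),
    start = as.integer(ends - widths + 1),
    end = as.integer(ends),
    width = as.integer(widths)
  )
  rows <- vapply(taxa, function(tx) {
    paste(vapply(seq_along(alignments), function(k) {
      a <- alignments[[k]]
      if (tx %in% names(a)) a[[tx]] else strrep("-", widths[k])
    }, character(1)), collapse = "")
  }, character(1))
  list(alignment = rows, blocks = blocks)
}

#' Published MLSA extraction ranges
#'
#' The five housekeeping genes and the 1-based reference-sequence
#' position ranges concatenated for the MLSA phylogeny (reference-strain
#' numbering): pyrH 1-562, gapA 227-893, mreB 391-892, gyrB 442-1027,
#' topA 448-1073 - 2943 reference positions in total.
#'
#' @return Tibble `gene`/`start`/`end`.
#' @export
mlsa_reference_ranges <- function() {
  tibble(
    gene = c("pyrH", "gapA", "mreB", "gyrB", "topA"),
    start = c(1L, 227L, 391L, 442L, 448L),
    end = c(562L, 893L, 892L, 1027L, 1073L)
  )
}

#' Extract and concatenate the MLSA ranges
#'
#' Maps each 1-based reference-sequence range to alignment columns
#' through the reference row's gap pattern (a block spans the columns of
#' the first through last reference residue of the range, including any
#' internal gap columns) and concatenates the extracted blocks in the
#' stated gene order.
#'
#' @param alignments Named list of per-gene alignments, each containing
#'   the reference taxon.
#' @param reference_taxon Name of the reference row (default `"ref"`).
#' @param ranges Tibble `gene`/`start`/`end`; default
#'   [mlsa_reference_ranges()].
#' @return List as in [concatenate_alignments()].
#' @export
mlsa_extract <- function(alignments, reference_taxon = "ref",
                         ranges = mlsa_reference_ranges()) {
  missing_genes <- setdiff(ranges$gene, names(alignments))
  if (length(missing_genes) > 0) {
    abort(paste0("missing alignments for: ",
                 paste(missing_genes, collapse = ", ")))
  }
  blocks <- lapply(seq_len(nrow(ranges)), function(i) {
    g <- ranges$gene[i]
    a <- alignments[[g]]
    if (!reference_taxon %in% names(a)) {
      abort(paste0("reference taxon '", reference_taxon,
                   "' absent from ", g, " alignment"))
    }
    ref_chars <- strsplit(a[[reference_taxon]], "")[[1]]
    res_pos <- cumsum(!ref_chars %in% GAP_CHARS)
    if (ranges$end[i] > max(res_pos)) {
      abort(paste0(g, ": range end ", ranges$end[i],
                   " exceeds reference length ", max(res_pos)))
    }
    c1 <- which(res_pos == ranges$start[i] & !ref_chars %in% GAP_CHARS)[1]
    c2 <- which(res_pos == ranges$end[i] & !ref_chars %in% GAP_CHARS)[1]
    vapply(a, function(row) substr(row, c1, c2), character(1))
  })
  names(blocks) <- ranges$gene
  concatenate_alignments(blocks)
}
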