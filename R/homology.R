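# Pairwise local protein alignment and the expectation-value screen.
# The search step is a self-contained equivalent of a blastp scan: optimal
# Smith-Waterman under BLOSUM62 with BLAST+ protein gap costs (open 11,
# extend 1), and Karlin-Altschul statistics with the published gapped
# BLOSUM62 constants. Tabular output from an external BLAST+ run can be
# imported instead via read_blast_tsv().

KA_LAMBDA <- 0.267
KA_K <- 0.041

.check_aa <- function(x, what = "sequence") {
  bad <- regmatches(x, regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", x))
  if (length(bad) > 0 && nchar(bad) > 0) {
    abort(paste0("illegal character '", bad, "' in ", what))
  }
  invisible(x)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman under BLOSUM62 with affine gap penalties (open 11,
#' extend 1 - BLAST+ protein defaults). Identity is computed over aligned
#' columns including gap columns (BLAST convention); `Lmatch` is the
#' number of alignment columns.
#'
#' @param query,subject Amino-acid strings (non-empty; 20-letter alphabet
#'   plus X).
#' @return One-row tibble: `score` (raw Smith-Waterman score), `Lmatch`,
#'   `identity_pct`, `Lprot1` (query length), `Lprot2` (subject length),
#'   `q_start`, `q_end` (1-based aligned query range), `s_start`, `s_end`.
#' @export
local_align <- function(query, subject) {
  if (nchar(query) == 0 || nchar(subject) == 0) {
    abort("local_align requires non-empty sequences")
  }
  .check_aa(query, "query")
  .check_aa(subject, "subject")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  aligned_q <- as.character(Biostrings::pattern(pa))
  tibble(
    score = Biostrings::score(pa),
    Lmatch = nchar(aligned_q),
    identity_pct = Biostrings::pid(pa, type = "PID1"),
    Lprot1 = nchar(query),
    Lprot2 = nchar(subject),
    q_start = Biostrings::start(Biostrings::pattern(pa)),
    q_end = Biostrings::end(Biostrings::pattern(pa)),
    s_start = Biostrings::start(Biostrings::subject(pa)),
    s_end = Biostrings::end(Biostrings::subject(pa))
  )
}

#' Karlin-Altschul expectation value
#'
#' E = K * m * n * exp(-lambda * S) with the gapped BLOSUM62 constants
#' K = 0.041, lambda = 0.267; `m` is the query length and `n` the total
#' residue count of the searched proteome.
#'
#' @param score Raw alignment score(s).
#' @param query_len Query length in residues (positive).
#' @param db_len Searched database size in residues (positive).
#' @return Expectation value(s), always > 0.
#' @export
estimate_evalue <- function(score, query_len, db_len) {
  if (any(query_len <= 0) || any(db_len <= 0)) {
    abort("query_len and db_len must be positive")
  }
  if (any(!is.finite(score))) abort("score must be finite")
  KA_K * query_len * db_len * exp(-KA_LAMBDA * score)
}

#' Bit score from a raw score
#'
#' S' = (lambda * S - ln K) / ln 2 under the same gapped constants.
#'
#' @param score Raw score(s).
#' @return Bit score(s).
#' @export
bit_score <- function(score) {
  (KA_LAMBDA * score - log(KA_K)) / log(2)
}

#' Search a genome proteome with a labelled query set
#'
#' Aligns every query against every protein of the genome and keeps hits
#' passing the expectation screen. Hits are returned sorted by
#' (query label, E-value, descending score, subject locus) so downstream
#' calling is deterministic.
#'
#' @param queries Tibble with columns `label` and `sequence` (the reference
#'   cluster or auxiliary catalog).
#' @param genome An `eps_genome`.
#' @param evalue_max Expectation screen (default the 1e-25 ortholog screen;
#'   pass `Inf` to keep everything).
#' @return Tibble of hits: `query_label`, `subject_locus`, `protein_id`,
#'   `score`, `bitscore`, `evalue`, `identity_pct`, `Lmatch`, `Lprot1`,
#'   `Lprot2`, `q_start`, `q_end`.
#' @export
search_proteome <- function(queries, genome, evalue_max = 1e-25) {
  stopifnot(inherits(genome, "eps_genome"))
  subjects <- genome$link |> filter(!is.na(.data$sequence))
  if (nrow(subjects) == 0) {
    warn(paste0(genome$genome_id, ": empty proteome"))
    return(empty_hits())
  }
  db_len <- sum(subjects$length)
  subj_set <- Biostrings::AAStringSet(setNames(subjects$sequence,
                                               subjects$locus_tag))
  res <- purrr::map_dfr(seq_len(nrow(queries)), function(i) {
    q <- queries$sequence[i]
    pa <- Biostrings::pairwiseAlignment(
      subj_set, Biostrings::AAString(q),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1
    )
    aligned_subject_side <- Biostrings::pattern(pa) # one per subject
    tibble(
      query_label = queries$label[i],
      subject_locus = subjects$locus_tag,
      protein_id = subjects$protein_id,
      score = Biostrings::score(pa),
      Lmatch = nchar(as.character(aligned_subject_side)),
      identity_pct = Biostrings::pid(pa, type = "PID1"),
      Lprot1 = nchar(q),
      Lprot2 = subjects$length,
      q_start = Biostrings::start(Biostrings::subject(pa)),
      q_end = Biostrings::end(Biostrings::subject(pa)),
      evalue = estimate_evalue(Biostrings::score(pa), nchar(q), db_len)
    )
  })
  res |>
    mutate(bitscore = bit_score(.data$score)) |>
    filter(.data$evalue < evalue_max) |>
    arrange(.data$query_label, .data$evalue, desc(.data$bitscore),
            .data$subject_locus) |>
    select("query_label", "subject_locus", "protein_id", "score",
           "bitscore", "evalue", "identity_pct", "Lmatch", "Lprot1",
           "Lprot2", "q_start", "q_end")
}

empty_hits <- function() {
  tibble(
    query_label = character(), subject_locus = character(),
    protein_id = character(), score = numeric(), bitscore = numeric(),
    evalue = numeric(), identity_pct = numeric(), Lmatch = integer(),
    Lprot1 = integer(), Lprot2 = integer(), q_start = integer(),
    q_end = integer()
  )
}

#' Import BLAST+ tabular output as alignment hits
#'
#' Adapter for `-outfmt "6 qseqid sseqid pident length evalue bitscore"`
#' (tab-separated, no header), mapped onto the hit table used by the
#' built-in search. Query/subject lengths must be supplied so the
#' alignment-length ratios can be computed.
#'
#' @param path TSV path.
#' @param query_lengths Named integer vector: query label -> length.
#' @param subject_lengths Named integer vector: locus tag -> length.
#' @return Hit tibble compatible with [call_orthologs()].
#' @export
read_blast_tsv <- function(path, query_lengths, subject_lengths) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("qseqid", "sseqid", "pident",
                                         "length", "evalue", "bitscore"),
                           stringsAsFactors = FALSE)
  tibble(
    query_label = raw$qseqid,
    subject_locus = raw$sseqid,
    protein_id = NA_character_,
    score = NA_real_,
    bitscore = raw$bitscore,
    evalue = raw$evalue,
    identity_pct = raw$pident,
    Lmatch = as.integer(raw$length),
    Lprot1 = as.integer(query_lengths[raw$qseqid]),
    Lprot2 = as.integer(subject_lengths[raw$sseqid]),
    q_start = NA_integer_,
    q_end = NA_integer_
  ) |>
    arrange(.data$query_label, .data$evalue, desc(.data$bitscore),
            .data$subject_locus)
}
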