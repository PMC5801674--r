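# The alignment-length-ratio statistics and the ortholog acceptance
# criteria: MinLrap = Lmatch / min(Lprot1, Lprot2), MaxLrap =
# Lmatch / max(Lprot1, Lprot2). Both equal to 1 means the two whole
# proteins align over their full lengths.

#' Ortholog-calling thresholds
#'
#' The four acceptance criteria: expectation value below `evalue_max`,
#' identity above `identity_min`, both alignment-length ratios at least
#' `lrap_min` ("close to 1"), and a protein size ratio
#' max(Lprot1,Lprot2)/min(Lprot1,Lprot2) of at most `size_ratio_max`
#' ("similar protein sizes"). The first two are published values; the
#' last two quantify the qualitative criteria and are configurable.
#'
#' @param evalue_max Expectation-value ceiling (default 1e-25).
#' @param identity_min Identity floor in percent (default 40).
#' @param lrap_min Floor for MinLrap and MaxLrap (default 0.8).
#' @param size_ratio_max Ceiling on the protein length ratio (default 1.5).
#' @return A named list of class `eps_thresholds`.
#' @export
eps_thresholds <- function(evalue_max = 1e-25, identity_min = 40,
                           lrap_min = 0.8, size_ratio_max = 1.5) {
  stopifnot(evalue_max > 0, identity_min >= 0, identity_min <= 100,
            lrap_min > 0, lrap_min <= 1, size_ratio_max >= 1)
  structure(list(evalue_max = evalue_max, identity_min = identity_min,
                 lrap_min = lrap_min, size_ratio_max = size_ratio_max),
            class = "eps_thresholds")
}

#' Alignment-length ratios
#'
#' MinLrap = Lmatch/min(Lprot1, Lprot2); MaxLrap = Lmatch/max(Lprot1,
#' Lprot2). Vectorised; exact ratios, no clamping. MaxLrap never exceeds
#' MinLrap since it divides by the larger length.
#'
#' @param Lmatch Alignment length(s) in columns (positive).
#' @param Lprot1,Lprot2 The two protein lengths (positive).
#' @return Tibble with columns `min_lrap`, `max_lrap`.
#' @export
compute_lrap <- function(Lmatch, Lprot1, Lprot2) {
  if (any(Lmatch <= 0) || any(Lprot1 <= 0) || any(Lprot2 <= 0)) {
    abort("compute_lrap requires positive lengths")
  }
  tibble(
    min_lrap = Lmatch / pmin(Lprot1, Lprot2),
    max_lrap = Lmatch / pmax(Lprot1, Lprot2)
  )
}

.fail_reasons <- function(hits, th) {
  lr <- compute_lrap(hits$Lmatch, hits$Lprot1, hits$Lprot2)
  size_ratio <- pmax(hits$Lprot1, hits$Lprot2) /
    pmin(hits$Lprot1, hits$Lprot2)
  purrr::pmap(
    list(hits$evalue >= th$evalue_max,
         hits$identity_pct <= th$identity_min,
         lr$min_lrap < th$lrap_min | lr$max_lrap < th$lrap_min,
         size_ratio > th$size_ratio_max),
    function(e, i, l, s) c("EVALUE", "IDENTITY", "LRAP", "SIZE")[c(e, i, l, s)]
  )
}

#' Call the best ortholog per query label
#'
#' For each query label, hits (sorted by E-value, ties broken by higher
#' bit score then subject locus) are evaluated against all four criteria;
#' the first fully passing hit becomes the call. When no hit passes, the
#' call is ABSENT and carries the failure reasons of the least-failing
#' hit. Labels with no hits at all are ABSENT with no reasons.
#'
#' @param hits Hit tibble from [search_proteome()] (may be pre-screened).
#' @param thresholds An [eps_thresholds()] list.
#' @param labels Labels to report; defaults to those present in `hits`.
#' @return Tibble with one row per label: `query_label`, `subject_locus`
#'   (NA when ABSENT), `evalue`, `identity_pct`, `min_lrap`, `max_lrap`,
#'   `passed`, `fail_reasons` (list column).
#' @export
call_orthologs <- function(hits, thresholds = eps_thresholds(),
                           labels = NULL) {
  labels <- labels %||% unique(hits$query_label)
  purrr::map_dfr(labels, function(lb) {
    h <- hits |>
      filter(.data$query_label == lb) |>
      arrange(.data$evalue, desc(.data$bitscore), .data$subject_locus)
    if (nrow(h) == 0) {
      return(tibble(query_label = lb, subject_locus = NA_character_,
                    evalue = NA_real_, identity_pct = NA_real_,
                    min_lrap = NA_real_, max_lrap = NA_real_,
                    passed = FALSE, fail_reasons = list(character(0))))
    }
    reasons <- .fail_reasons(h, thresholds)
    n_fail <- lengths(reasons)
    pick <- if (any(n_fail == 0)) which(n_fail == 0)[1] else
      which.min(n_fail)
    lr <- compute_lrap(h$Lmatch[pick], h$Lprot1[pick], h$Lprot2[pick])
    tibble(
      query_label = lb,
      subject_locus = if (n_fail[pick] == 0) h$subject_locus[pick]
                      else NA_character_,
      evalue = h$evalue[pick],
      identity_pct = h$identity_pct[pick],
      min_lrap = lr$min_lrap,
      max_lrap = lr$max_lrap,
      passed = n_fail[pick] == 0,
      fail_reasons = reasons[pick]
    )
  })
}

#' Select the seed gene for context walking
#'
#' Returns the first label with a passing call, in priority order A, B, C,
#' G, O, R (the most conserved genes, A "usually" first), then the
#' remaining labels in cluster order. `NA` when nothing passes: the genome
#' is cluster-negative.
#'
#' @param calls Call tibble from [call_orthologs()].
#' @param cluster_order Reference label order (default the 16 cluster
#'   labels).
#' @return A label or `NA_character_`.
#' @export
select_seed <- function(calls, cluster_order = eps_labels()) {
  priority <- unique(c("A", "B", "C", "G", "O", "R", cluster_order))
  priority <- priority[priority %in% calls$query_label]
  passed <- calls$query_label[calls$passed]
  hit <- priority[priority %in% passed]
  if (length(hit) == 0) NA_character_ else hit[1]
}

#' Reference cluster gene labels
#'
#' The 16 genes of the reference exopolysaccharide biosynthesis cluster in
#' genomic order (labelled after the Aliivibrio fischeri syp orthologs;
#' E and M are not part of the reference cluster and live in the auxiliary
#' catalog).
#'
#' @return Character vector of labels.
#' @export
eps_labels <- function() {
  c("A", "B", "C", "D", "F", "G", "H", "I", "J", "K", "L", "N",
    "O", "P", "Q", "R")
}
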