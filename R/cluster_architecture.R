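# Reconstruction of the orthologous cluster from a seed gene by
# genomic-context walking, and classification of every architectural
# variation: absent slots, pseudogenes, fragmented and truncated genes,
# insertions between cluster genes, and cluster splits within or across
# contigs.
#
# Slot assignment deliberately relaxes the strict ortholog call to the
# E-value + identity screens only: truncated subjects (MaxLrap below the
# floor with MinLrap above it) and gene fragments fail the length-ratio
# and size criteria by construction yet must still be assigned to their
# slot. The strict call governs seed selection and cluster detection.

#' Scan one genome for the reference cluster
#'
#' End-to-end per-genome reconstruction: proteome search, ortholog calls,
#' seed selection, context walking, slot classification, insertion
#' identification, split detection and synteny scoring.
#'
#' @param genome An `eps_genome`.
#' @param reference Reference bundle from [synthetic_reference_cluster()]
#'   or a list with tibbles `cluster` and `catalog`.
#' @param thresholds An [eps_thresholds()] list.
#' @param window Context window in CDS ordinals around the seed
#'   (default 30).
#' @param gap_threshold Same-contig split threshold in bp (default 3000).
#' @return An `eps_architecture` object; see [tidy.eps_architecture()].
#' @export
scan_genome <- function(genome, reference = synthetic_reference_cluster(),
                        thresholds = eps_thresholds(), window = 30,
                        gap_threshold = 3000) {
  queries <- reference$cluster |> select("label", "sequence")
  hits <- search_proteome(queries, genome,
                          evalue_max = thresholds$evalue_max)
  calls <- call_orthologs(hits, thresholds, labels = reference$cluster$label)
  seed <- select_seed(calls, cluster_order = reference$cluster$label)
  if (is.na(seed)) {
    return(structure(
      list(genome_id = genome$genome_id, found = FALSE,
           seed_label = NA_character_,
           slots = tibble(label = reference$cluster$label,
                          status = "ABSENT", locus_tags = list(character(0)),
                          identity_pct = NA_real_, min_lrap = NA_real_,
                          max_lrap = NA_real_, contig_id = NA_character_),
           insertions = empty_insertions(), split = FALSE,
           split_parts = list(), separation_bp = NA_integer_,
           synteny_fraction = NA_real_, excluded_contig_edge = FALSE,
           calls = calls, thresholds = thresholds),
      class = "eps_architecture"))
  }
  arch <- walk_context(hits, calls, genome, reference, seed,
                       thresholds = thresholds, window = window)
  arch <- detect_split(arch, genome, gap_threshold = gap_threshold)
  arch$synteny_fraction <- synteny_fraction(arch, genome, reference)
  arch$insertions <- identify_insertions(arch, genome, reference$catalog,
                                         thresholds)
  arch
}

empty_insertions <- function() {
  tibble(after = character(), before = character(),
         locus_tags = list(), assigned = list())
}

#' Walk the genomic context around the seed and assign slots
#'
#' Examines CDS within `window` ordinals of the seed feature on its
#' contig, plus passing calls on other contigs, and assigns each
#' reference label its best candidate hit (greedy by E-value; a subject
#' serves at most one label). Adjacent extra subjects aligning to
#' disjoint regions of the same reference protein (< 20% overlap) become
#' fragment parts; in-window pseudo features flanked by assigned slots
#' are attributed to the unique missing label between the flanks;
#' unassigned in-window CDS between two assigned slots become insertion
#' candidates.
#'
#' @param hits Hit tibble from [search_proteome()].
#' @param calls Call tibble from [call_orthologs()].
#' @param genome An `eps_genome`.
#' @param reference Reference bundle.
#' @param seed Seed label from [select_seed()].
#' @param thresholds An [eps_thresholds()] list.
#' @param window Ordinal window (default 30).
#' @return An `eps_architecture` (split fields not yet populated).
#' @export
walk_context <- function(hits, calls, genome, reference, seed,
                         thresholds = eps_thresholds(), window = 30) {
  ref_labels <- reference$cluster$label
  feats <- genome$features
  seed_locus <- calls$subject_locus[calls$query_label == seed]
  seed_feat <- feats |> filter(.data$locus_tag == seed_locus)
  if (nrow(seed_feat) != 1 || is.na(seed_feat$start)) {
    abort(paste0("seed feature missing coordinates: ", seed_locus))
  }
  in_window <- feats |>
    filter(.data$contig_id == seed_feat$contig_id,
           abs(.data$ordinal - seed_feat$ordinal) <= window)

  # candidates: E + identity screens; in-window, or fully passing calls
  # on other contigs (clusters split across contigs)
  passing_other <- calls |>
    filter(.data$passed) |>
    left_join(feats |> select("locus_tag", "contig_id"),
              by = c(subject_locus = "locus_tag")) |>
    filter(.data$contig_id != seed_feat$contig_id)
  cand <- hits |>
    filter(.data$evalue < thresholds$evalue_max,
           .data$identity_pct > thresholds$identity_min) |>
    filter(.data$subject_locus %in% in_window$locus_tag |
             .data$subject_locus %in% passing_other$subject_locus) |>
    arrange(.data$evalue, desc(.data$bitscore), .data$subject_locus)

  assigned <- tibble(label = character(), locus_tag = character(),
                     identity_pct = numeric(), Lmatch = integer(),
                     Lprot1 = integer(), Lprot2 = integer(),
                     q_start = integer(), q_end = integer())
  for (i in seq_len(nrow(cand))) {
    h <- cand[i, ]
    if (h$query_label %in% assigned$label ||
        h$subject_locus %in% assigned$locus_tag) next
    assigned <- bind_rows(assigned, tibble(
      label = h$query_label, locus_tag = h$subject_locus,
      identity_pct = h$identity_pct, Lmatch = h$Lmatch,
      Lprot1 = h$Lprot1, Lprot2 = h$Lprot2,
      q_start = h$q_start, q_end = h$q_end))
  }

  # fragment augmentation: unassigned subjects adjacent to an assigned
  # feature, hitting the same label over a disjoint reference region
  frag_parts <- list()
  feat_ord <- feats |> select("locus_tag", "contig_id", "ordinal")
  for (j in seq_len(nrow(assigned))) {
    a <- assigned[j, ]
    a_feat <- feats |> filter(.data$locus_tag == a$locus_tag)
    extra <- cand |>
      filter(.data$query_label == a$label,
             !.data$subject_locus %in% assigned$locus_tag) |>
      left_join(feat_ord, by = c(subject_locus = "locus_tag")) |>
      filter(.data$contig_id == a_feat$contig_id,
             abs(.data$ordinal - a_feat$ordinal) <= 2)
    if (nrow(extra) == 0) next
    ref_len <- a$Lprot1
    ov <- pmax(0, pmin(extra$q_end, a$q_end) -
                 pmax(extra$q_start, a$q_start) + 1)
    shorter <- pmin(extra$q_end - extra$q_start + 1, a$q_end - a$q_start + 1)
    disjoint <- ov / shorter < 0.2
    if (any(disjoint)) {
      frag_parts[[a$label]] <- extra$subject_locus[disjoint]
    }
  }

  # slot statuses
  slots <- purrr::map_dfr(ref_labels, function(lb) {
    a <- assigned |> filter(.data$label == lb)
    if (nrow(a) == 0) {
      return(tibble(label = lb, status = "ABSENT",
                    locus_tags = list(character(0)),
                    identity_pct = NA_real_, min_lrap = NA_real_,
                    max_lrap = NA_real_, contig_id = NA_character_))
    }
    ctg <- feats$contig_id[feats$locus_tag == a$locus_tag]
    lr <- compute_lrap(a$Lmatch, a$Lprot1, a$Lprot2)
    parts <- frag_parts[[lb]]
    if (!is.null(parts)) {
      # order fragment parts genomically
      tags <- c(a$locus_tag, parts)
      ord <- feats |> filter(.data$locus_tag %in% tags) |>
        arrange(.data$start) |> pull(.data$locus_tag)
      return(tibble(label = lb, status = "FRAGMENTED",
                    locus_tags = list(ord),
                    identity_pct = a$identity_pct, min_lrap = lr$min_lrap,
                    max_lrap = lr$max_lrap, contig_id = ctg))
    }
    status <- if (lr$max_lrap < thresholds$lrap_min &&
                    lr$min_lrap >= thresholds$lrap_min) "TRUNCATED"
              else "PRESENT"
    tibble(label = lb, status = status, locus_tags = list(a$locus_tag),
           identity_pct = a$identity_pct, min_lrap = lr$min_lrap,
           max_lrap = lr$max_lrap, contig_id = ctg)
  })

  # genomic order of assigned features on the seed contig
  assigned_tags <- unlist(slots$locus_tags)
  ctx <- in_window |>
    mutate(assigned_label = purrr::map_chr(.data$locus_tag, function(t) {
      w <- which(purrr::map_lgl(slots$locus_tags, ~ t %in% .x))
      if (length(w) == 0) NA_character_ else slots$label[w[1]]
    })) |>
    arrange(.data$start)

  # pseudogene attribution: pseudo CDS between two assigned slots with
  # exactly one reference label missing between the flanks
  pseudo_rows <- which(ctx$pseudo & is.na(ctx$assigned_label))
  for (pr in pseudo_rows) {
    left_lab <- ctx$assigned_label[seq_len(pr - 1)]
    left_lab <- tail(left_lab[!is.na(left_lab)], 1)
    right_lab <- ctx$assigned_label[-seq_len(pr)]
    right_lab <- head(right_lab[!is.na(right_lab)], 1)
    if (length(left_lab) == 0 || length(right_lab) == 0) next
    i1 <- match(left_lab, ref_labels)
    i2 <- match(right_lab, ref_labels)
    if (is.na(i1) || is.na(i2) || abs(i2 - i1) < 2) next
    between <- ref_labels[seq(min(i1, i2) + 1, max(i1, i2) - 1)]
    missing <- between[slots$status[match(between, slots$label)] == "ABSENT"]
    if (length(missing) != 1) next
    k <- match(missing, slots$label)
    slots$status[k] <- "PSEUDOGENE"
    slots$locus_tags[[k]] <- ctx$locus_tag[pr]
    slots$contig_id[k] <- ctx$contig_id[pr]
    ctx$assigned_label[pr] <- missing
  }

  # insertion candidates: unassigned, non-pseudo CDS strictly between
  # two assigned slots, grouped into runs
  ins <- empty_insertions()
  lab_idx <- which(!is.na(ctx$assigned_label))
  if (length(lab_idx) >= 2) {
    for (g in seq_len(length(lab_idx) - 1)) {
      lo <- lab_idx[g]
      hi <- lab_idx[g + 1]
      if (hi - lo <= 1) next
      mid <- ctx[seq(lo + 1, hi - 1), ]
      mid <- mid |> filter(!.data$pseudo)
      if (nrow(mid) == 0) next
      ins <- bind_rows(ins, tibble(
        after = ctx$assigned_label[lo], before = ctx$assigned_label[hi],
        locus_tags = list(mid$locus_tag),
        assigned = list(rep(NA_character_, nrow(mid)))))
    }
  }

  structure(
    list(genome_id = genome$genome_id, found = TRUE, seed_label = seed,
         slots = slots, insertions = ins, split = FALSE,
         split_parts = list(), separation_bp = NA_integer_,
         synteny_fraction = NA_real_, excluded_contig_edge = FALSE,
         calls = calls, thresholds = thresholds),
    class = "eps_architecture")
}

#' Detect cluster splits and contig-edge truncation
#'
#' A cluster is split when its assigned slots span two or more contigs,
#' or when a same-contig intergenic gap between consecutive assigned
#' slots exceeds `gap_threshold` (default 3000 bp; a 5 kb separation must
#' count as split). `separation_bp` is the intergenic distance between
#' the flanking CDS boundaries of a same-contig split.
#' `excluded_contig_edge` is raised when the parts terminate within two
#' CDS of distinct contig ends - such genomes were excluded from the
#' original survey but are reported (flagged) here.
#'
#' @param arch An `eps_architecture` from [walk_context()].
#' @param genome The scanned `eps_genome`.
#' @param gap_threshold Same-contig split threshold in bp.
#' @return The updated architecture.
#' @export
detect_split <- function(arch, genome, gap_threshold = 3000) {
  feats <- genome$features
  slot_map <- arch$slots |>
    filter(.data$status != "ABSENT") |>
    select("label", "locus_tags") |>
    tidyr::unnest(cols = "locus_tags") |>
    rename(slot_locus = "locus_tags")
  if (nrow(slot_map) < 2) return(arch)
  # walk over every cluster-attributed CDS (slots + insertions) so that
  # multi-gene insertions do not masquerade as intergenic separations
  ctx <- tibble(locus_tag = c(slot_map$slot_locus,
                              unlist(arch$insertions$locus_tags))) |>
    distinct() |>
    left_join(feats |> select("locus_tag", "contig_id", "start", "end",
                              "ordinal"),
              by = "locus_tag") |>
    left_join(slot_map, by = c(locus_tag = "slot_locus")) |>
    arrange(.data$contig_id, .data$start)

  parts <- split(ctx, ctx$contig_id)
  arch$split_parts <- purrr::imap(parts, function(p, ctg)
    list(contig_id = ctg, labels = unique(p$label[!is.na(p$label)])))
  names(arch$split_parts) <- NULL

  if (length(parts) >= 2) {
    arch$split <- TRUE
  } else {
    p <- parts[[1]]
    gaps <- p$start[-1] - p$end[-nrow(p)]
    if (length(gaps) > 0 && any(gaps > gap_threshold)) {
      arch$split <- TRUE
      arch$separation_bp <- as.integer(max(gaps))
      k <- which.max(gaps)
      lab <- function(rows) unique(p$label[rows][!is.na(p$label[rows])])
      arch$split_parts <- list(
        list(contig_id = p$contig_id[1], labels = lab(seq_len(k))),
        list(contig_id = p$contig_id[1], labels = lab(seq(k + 1, nrow(p)))))
    }
  }

  if (arch$split && length(parts) >= 2) {
    contig_n <- feats |> group_by(.data$contig_id) |>
      summarise(n_cds = max(.data$ordinal), .groups = "drop")
    at_edge <- vapply(names(parts), function(ctg) {
      p <- parts[[ctg]]
      n_cds <- contig_n$n_cds[contig_n$contig_id == ctg]
      min(p$ordinal) <= 2 || n_cds - max(p$ordinal) < 2
    }, logical(1))
    arch$excluded_contig_edge <- sum(at_edge) >= 2
  }
  arch
}

#' Synteny fraction of an architecture
#'
#' Among reference labels with status PRESENT, the fraction of adjacent
#' label pairs (in reference order) whose features are also genomically
#' adjacent - same contig, no intervening assigned or inserted CDS, and
#' consistent orientation.
#'
#' @param arch An `eps_architecture`.
#' @param genome The scanned genome.
#' @param reference Reference bundle.
#' @return A fraction in `[0, 1]`, or `NA` with fewer than two PRESENT
#'   slots.
#' @export
synteny_fraction <- function(arch, genome, reference) {
  feats <- genome$features
  present <- arch$slots |> filter(.data$status == "PRESENT")
  if (nrow(present) < 2) return(NA_real_)
  pres_labels <- reference$cluster$label[reference$cluster$label %in%
                                           present$label]
  # all cluster-attributed CDS (assigned slots + insertions)
  cluster_tags <- c(unlist(arch$slots$locus_tags),
                    unlist(arch$insertions$locus_tags))
  ctx <- feats |> filter(.data$locus_tag %in% cluster_tags) |>
    arrange(.data$contig_id, .data$start)
  tag_of <- function(lb) {
    present$locus_tags[[match(lb, present$label)]][1]
  }
  n_adj <- length(pres_labels) - 1
  ok <- 0L
  for (i in seq_len(n_adj)) {
    t1 <- tag_of(pres_labels[i])
    t2 <- tag_of(pres_labels[i + 1])
    r1 <- ctx |> filter(.data$locus_tag == t1)
    r2 <- ctx |> filter(.data$locus_tag == t2)
    if (r1$contig_id != r2$contig_id) next
    pos1 <- which(ctx$locus_tag == t1)
    pos2 <- which(ctx$locus_tag == t2)
    if (abs(pos1 - pos2) != 1) next
    if (r1$strand != r2$strand) next
    ok <- ok + 1L
  }
  ok / n_adj
}

#' Identify inserted genes against the auxiliary catalog
#'
#' Each translated inserted CDS is aligned against the auxiliary query
#' catalog under the full ortholog criteria; the best fully passing
#' catalog label is assigned, otherwise UNKNOWN. Untranslated (pseudo)
#' insertions stay UNKNOWN.
#'
#' @param arch An `eps_architecture`.
#' @param genome The scanned genome.
#' @param catalog Auxiliary catalog tibble (`label`, `sequence`).
#' @param thresholds An [eps_thresholds()] list.
#' @return The insertion tibble with the `assigned` list column filled.
#' @export
identify_insertions <- function(arch, genome, catalog,
                                thresholds = eps_thresholds()) {
  ins <- arch$insertions
  if (nrow(ins) == 0) return(ins)
  link <- genome$link
  db_len <- sum(link$length, na.rm = TRUE)
  ins$assigned <- purrr::map(ins$locus_tags, function(tags) {
    vapply(tags, function(t) {
      seq <- link$sequence[link$locus_tag == t]
      if (length(seq) != 1 || is.na(seq)) return("UNKNOWN")
      best <- "UNKNOWN"
      best_e <- Inf
      for (j in seq_len(nrow(catalog))) {
        al <- local_align(catalog$sequence[j], seq)
        ev <- estimate_evalue(al$score, al$Lprot1, db_len)
        lr <- compute_lrap(al$Lmatch, al$Lprot1, al$Lprot2)
        size_ratio <- max(al$Lprot1, al$Lprot2) / min(al$Lprot1, al$Lprot2)
        pass <- ev < thresholds$evalue_max &&
          al$identity_pct > thresholds$identity_min &&
          lr$min_lrap >= thresholds$lrap_min &&
          lr$max_lrap >= thresholds$lrap_min &&
          size_ratio <= thresholds$size_ratio_max
        if (pass && ev < best_e) {
          best <- catalog$label[j]
          best_e <- ev
        }
      }
      best
    }, character(1), USE.NAMES = FALSE)
  })
  ins
}

#' @export
print.eps_architecture <- function(x, ...) {
  cat("<eps_architecture> ", x$genome_id, "\n", sep = "")
  if (!x$found) {
    cat("  cluster not detected\n")
    return(invisible(x))
  }
  st <- table(factor(x$slots$status,
                     levels = c("PRESENT", "TRUNCATED", "FRAGMENTED",
                                "PSEUDOGENE", "ABSENT")))
  cat("  seed ", x$seed_label, "; ",
      paste(names(st), st, sep = ":", collapse = " "), "\n", sep = "")
  if (nrow(x$insertions) > 0) {
    cat("  insertions:",
        paste0("(", x$insertions$after, ",", x$insertions$before, ")x",
               lengths(x$insertions$locus_tags), collapse = " "), "\n")
  }
  if (x$split) {
    cat("  split",
        if (!is.na(x$separation_bp)) paste0("(", x$separation_bp, " bp)"),
        if (x$excluded_contig_edge) "[contig-edge]", "\n")
  }
  cat("  synteny fraction:", format(x$synteny_fraction, digits = 3), "\n")
  invisible(x)
}

#' Tidy an architecture into one row per slot
#'
#' @param x An `eps_architecture`.
#' @param ... Unused.
#' @return Tibble: `genome_id`, `label`, `status`, `locus_tags`
#'   (semicolon-joined), `identity_pct`, `min_lrap`, `max_lrap`,
#'   `contig_id`.
#' @exportS3Method generics::tidy
tidy.eps_architecture <- function(x, ...) {
  x$slots |>
    mutate(genome_id = x$genome_id,
           locus_tags = purrr::map_chr(.data$locus_tags, paste,
                                       collapse = ";")) |>
    select("genome_id", "label", "status", "locus_tags", "identity_pct",
           "min_lrap", "max_lrap", "contig_id")
}

#' One-row summary of an architecture
#'
#' @param x An `eps_architecture`.
#' @param ... Unused.
#' @return One-row tibble with detection flag, seed, status counts,
#'   insertion count, split fields and synteny fraction.
#' @exportS3Method generics::glance
glance.eps_architecture <- function(x, ...) {
  tibble(
    genome_id = x$genome_id,
    found = x$found,
    seed_label = if (is.na(x$seed_label)) NA_character_ else x$seed_label,
    n_present = sum(x$slots$status == "PRESENT"),
    n_truncated = sum(x$slots$status == "TRUNCATED"),
    n_fragmented = sum(x$slots$status == "FRAGMENTED"),
    n_pseudogene = sum(x$slots$status == "PSEUDOGENE"),
    n_absent = sum(x$slots$status == "ABSENT"),
    n_insertions = nrow(x$insertions),
    split = x$split,
    separation_bp = x$separation_bp,
    excluded_contig_edge = x$excluded_contig_edge,
    synteny_fraction = x$synteny_fraction
  )
}
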