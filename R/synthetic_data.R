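# Seeded generators for synthetic genomes with planted eps clusters.
# Fixtures emulate every architectural variation class observed in real
# Vibrionaceae assemblies: gene deletion, insertion (catalog or foreign),
# pseudogenization, fragmentation, truncation, sequence divergence, and
# cluster splitting within or across contigs. Each genome carries a
# ground-truth manifest from which the expected architecture is derived
# deterministically.

# Robinson-Robinson-like amino-acid background frequencies.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_FREQ <- c(0.078, 0.051, 0.045, 0.054, 0.019, 0.043, 0.063, 0.074,
             0.022, 0.051, 0.091, 0.057, 0.022, 0.039, 0.052, 0.071,
             0.058, 0.013, 0.032, 0.065)
NT_ALPHABET <- c("A", "C", "G", "T")

.random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = AA_FREQ),
        collapse = "")
}

.random_dna <- function(len) {
  paste(sample(NT_ALPHABET, len, replace = TRUE), collapse = "")
}

.shuffle_seq <- function(seq) {
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

#' Synthetic reference cluster and auxiliary query catalog
#'
#' Deterministically generates a stand-in for the 16-protein reference
#' exopolysaccharide biosynthesis cluster (labels A-R in genomic order)
#' plus the auxiliary query catalog used to identify inserted genes
#' (E, M, PABC, the betaine ABC transporter trio, GFAT, transposase and
#' integrase exemplars). Sequences are synthetic random proteins with
#' realistic per-role lengths; the real reference proteins are not
#' bundled. Fixed internal seed, so every session sees the same
#' reference.
#'
#' @return List with two tibbles, `cluster` and `catalog`, each with
#'   columns `label`, `product`, `sequence`, `length`.
#' @export
synthetic_reference_cluster <- function() {
  cluster_def <- tibble(
    label = eps_labels(),
    product = c(
      "anti-sigma factor antagonist",
      "regulatory protein",
      "polysaccharide export protein Wza",
      "chain length regulator Wzc",
      "hybrid sensor kinase",
      "sigma-54 dependent response regulator",
      "glycosyltransferase",
      "glycosyltransferase",
      "glycosyltransferase",
      "flippase Wzx",
      "polymerase Wzy",
      "glycosyltransferase",
      "chain length determinant Wzz",
      "glycosyltransferase",
      "glycosyltransferase",
      "undecaprenyl-phosphate sugar phosphotransferase"
    ),
    length = c(115L, 260L, 380L, 710L, 590L, 445L, 320L, 305L, 350L,
               470L, 410L, 335L, 355L, 380L, 300L, 225L)
  )
  catalog_def <- tibble(
    label = c("E", "M", "PABC", "BETAINE_ABC_SBP", "BETAINE_ABC_PERM",
              "BETAINE_ABC_ATP", "GFAT", "TRANSPOSASE", "INTEGRASE"),
    product = c(
      "two-component response regulator",
      "O-acetyltransferase",
      "phosphonate ABC transporter periplasmic component",
      "glycine betaine ABC transporter substrate-binding protein",
      "glycine betaine ABC transporter permease",
      "glycine betaine ABC transporter ATP-binding protein",
      "glutamine-fructose-6-phosphate aminotransferase",
      "transposase",
      "integrase"
    ),
    length = c(480L, 200L, 300L, 310L, 280L, 350L, 610L, 300L, 330L)
  )
  withr::with_seed(271828, {
    cluster_def$sequence <- vapply(cluster_def$length, .random_protein,
                                   character(1))
    catalog_def$sequence <- vapply(catalog_def$length, .random_protein,
                                   character(1))
  })
  list(
    cluster = cluster_def |> select("label", "product", "sequence", "length"),
    catalog = catalog_def |> select("label", "product", "sequence", "length")
  )
}

#' Read a labelled reference-cluster FASTA
#'
#' Reads a multi-FASTA whose headers are `>LABEL optional product text`,
#' the on-disk form of a reference cluster or auxiliary catalog.
#'
#' @param path FASTA path.
#' @return Tibble with `label`, `product`, `sequence`, `length`.
#' @export
read_reference_cluster <- function(path) {
  p <- read_protein_fasta(path)
  p |> rename(label = "protein_id")
}

#' Evolve a protein (or DNA) sequence to a target identity
#'
#' Point substitutions at uniformly drawn distinct positions; the number
#' of substituted positions is `round((1 - target) * length)`, every
#' substitution changes the residue, so the realized identity is within
#' half a position of the target (inside the documented +/- 0.02 band for
#' sequences of 30+ residues). Deterministic under `seed`.
#'
#' @param sequence Input sequence (length >= 30).
#' @param target_identity Target fractional identity in (0, 1].
#' @param seed Integer seed.
#' @param alphabet `"protein"` or `"dna"`.
#' @return The diverged sequence (same length).
#' @export
evolve_protein <- function(sequence, target_identity, seed,
                           alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (target_identity > 1 || target_identity <= 0) {
    abort("target_identity must be in (0, 1]")
  }
  n <- nchar(sequence)
  if (n < 30) abort("sequence too short to evolve (need >= 30)")
  k <- round((1 - target_identity) * n)
  if (k == 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  letters_pool <- if (alphabet == "protein") AA_ALPHABET else NT_ALPHABET
  freqs <- if (alphabet == "protein") AA_FREQ else rep(0.25, 4)
  withr::with_seed(seed, {
    pos <- sample.int(n, k)
    for (p in pos) {
      keep <- letters_pool != chars[p]
      chars[p] <- sample(letters_pool[keep], 1, prob = freqs[keep])
    }
  })
  paste(chars, collapse = "")
}

# ---- event constructors ----------------------------------------------------

#' Architectural event specifications
#'
#' Constructors for the event list consumed by [plant_genome()]. Each
#' mirrors a variation class observed in real clusters: `ev_delete`
#' removes genes; `ev_diverge` evolves them to a target identity;
#' `ev_pseudogenize` flags the CDS `[pseudo=true]` and drops the protein;
#' `ev_fragment` splits one gene into two CDS at a fractional breakpoint;
#' `ev_truncate` keeps only the head of the protein; `ev_split_same_contig`
#' replaces the intergenic gap before the first listed label with a spacer
#' of `spacer_bp` (so the planted separation is recovered exactly);
#' `ev_split_contigs` moves the listed labels to a second contig
#' (`at_edges = TRUE` places both parts at contig ends, the situation the
#' survey excluded); `ev_insert_catalog` / `ev_insert_foreign` place genes
#' between the two flanking labels.
#'
#' @param labels,label Reference label(s) targeted.
#' @param identity Target fractional identity for diverged/inserted genes.
#' @param breakpoint Fractional breakpoint for fragmentation.
#' @param keep Fraction of the protein kept by truncation.
#' @param spacer_bp Separation in bp for a same-contig split.
#' @param at_edges Place both split parts at contig ends.
#' @param after,before Flanking labels for insertions.
#' @param n Number of foreign genes to insert.
#' @return A list of class `eps_event`.
#' @name eps_events
NULL

.ev <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "eps_event")
}

#' @rdname eps_events
#' @export
ev_delete <- function(labels) .ev("DELETE", labels = labels)

#' @rdname eps_events
#' @export
ev_diverge <- function(identity, labels = NULL)
  .ev("DIVERGE", labels = labels, identity = identity)

#' @rdname eps_events
#' @export
ev_pseudogenize <- function(labels) .ev("PSEUDOGENIZE", labels = labels)

#' @rdname eps_events
#' @export
ev_fragment <- function(label, breakpoint = 0.5)
  .ev("FRAGMENT", labels = label, breakpoint = breakpoint)

#' @rdname eps_events
#' @export
ev_truncate <- function(label, keep = 0.5)
  .ev("TRUNCATE", labels = label, keep = keep)

#' @rdname eps_events
#' @export
ev_split_same_contig <- function(labels, spacer_bp)
  .ev("SPLIT_SAME_CONTIG", labels = labels, spacer_bp = spacer_bp)

#' @rdname eps_events
#' @export
ev_split_contigs <- function(labels, at_edges = FALSE)
  .ev("SPLIT_CONTIGS", labels = labels, at_edges = at_edges)

#' @rdname eps_events
#' @export
ev_insert_catalog <- function(labels, after, before, identity = 0.9)
  .ev("INSERT_CATALOG", labels = labels, after = after, before = before,
      identity = identity)

#' @rdname eps_events
#' @export
ev_insert_foreign <- function(n, after, before)
  .ev("INSERT_FOREIGN", n = n, after = after, before = before)

# ---- genome planting -------------------------------------------------------

#' Plant a synthetic genome with (or without) an eps cluster
#'
#' Builds a genome in the NCBI two-file convention: composition-shuffled
#' decoy proteins as background, the cluster genes in reference order with
#' 20-200 bp intergenic gaps, then the event list applied. Returns the
#' linked genome together with a ground-truth manifest whose expected
#' architecture is derived from the events deterministically.
#'
#' @param reference Tibble `label`/`sequence` to plant (usually
#'   `synthetic_reference_cluster()$cluster`, possibly pre-evolved).
#' @param events List of [eps_events] objects.
#' @param background_genes Number of decoy proteins (default 40).
#' @param seed Integer seed.
#' @param genome_id Genome identifier.
#' @param plant_cluster `FALSE` builds a decoy-only (cluster-negative)
#'   genome.
#' @param catalog Auxiliary catalog used by `ev_insert_catalog` (default
#'   the synthetic catalog).
#' @return List with `genome` (an `eps_genome`) and `manifest` (see
#'   Details).
#' @details The manifest is a list: `genome_id`, `seed`, `has_cluster`,
#'   `events`, `expected_slots` (tibble label/status), `expected_insertions`
#'   (tibble after/before/labels), `expected_split` (list with `split`,
#'   `separation_bp`, `excluded_contig_edge`), and `planted_identity`
#'   (named vector label -> fractional identity to the planting source).
#' @export
plant_genome <- function(reference, events = list(), background_genes = 40,
                         seed = 1, genome_id = "synthetic",
                         plant_cluster = TRUE,
                         catalog = synthetic_reference_cluster()$catalog) {
  kinds <- vapply(events, `[[`, character(1), "kind")
  status_kinds <- c("DELETE", "PSEUDOGENIZE", "FRAGMENT", "TRUNCATE")
  touched <- unlist(lapply(events[kinds %in% status_kinds], `[[`, "labels"))
  if (anyDuplicated(touched)) {
    abort(paste0("contradictory events on label(s): ",
                 paste(unique(touched[duplicated(touched)]), collapse = ", ")))
  }

  withr::with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 64)

    # decoy background: composition-shuffled copies of reference+catalog
    pool <- c(reference$sequence, catalog$sequence)
    decoys <- tibble(
      kind = "decoy",
      label = NA_character_,
      sequence = vapply(pool[rep_len(seq_along(pool), background_genes)],
                        .shuffle_seq, character(1), USE.NAMES = FALSE),
      pseudo = FALSE,
      strand = sample(c("+", "-"), background_genes, replace = TRUE)
    )

    slots <- tibble(label = reference$label, status = "PRESENT")
    planted_identity <- setNames(rep(1, nrow(reference)), reference$label)
    genes <- tibble(kind = "cluster", label = reference$label,
                    sequence = reference$sequence, pseudo = FALSE,
                    strand = "+")
    expected_ins <- tibble(after = character(), before = character(),
                           labels = list())
    expected_split <- list(split = FALSE, separation_bp = NA_integer_,
                           excluded_contig_edge = FALSE)
    spacer_before <- character(0) # labels preceded by a spacer
    spacer_bp <- integer(0)
    second_contig <- character(0)
    at_edges <- FALSE
    si <- 1L

    apply_one <- function(ev) {
      switch(ev$kind,
        DIVERGE = {
          targets <- ev$labels %||% genes$label[genes$kind == "cluster"]
          for (lb in targets) {
            i <- which(genes$label == lb & genes$kind == "cluster")
            genes$sequence[i] <<- evolve_protein(genes$sequence[i],
                                                 ev$identity,
                                                 sub_seeds[si])
            si <<- si + 1L
            planted_identity[lb] <<- ev$identity
          }
        },
        DELETE = {
          genes <<- genes |> filter(!(.data$kind == "cluster" &
                                        .data$label %in% ev$labels))
          slots$status[slots$label %in% ev$labels] <<- "ABSENT"
        },
        PSEUDOGENIZE = {
          i <- which(genes$label %in% ev$labels & genes$kind == "cluster")
          genes$pseudo[i] <<- TRUE
          slots$status[slots$label %in% ev$labels] <<- "PSEUDOGENE"
        },
        TRUNCATE = {
          i <- which(genes$label == ev$labels & genes$kind == "cluster")
          n <- nchar(genes$sequence[i])
          genes$sequence[i] <<- substr(genes$sequence[i], 1,
                                       floor(n * ev$keep))
          slots$status[slots$label == ev$labels] <<- "TRUNCATED"
        },
        FRAGMENT = {
          i <- which(genes$label == ev$labels & genes$kind == "cluster")
          s <- genes$sequence[i]
          b <- floor(nchar(s) * ev$breakpoint)
          part1 <- genes[i, ] |> mutate(sequence = substr(s, 1, b))
          part2 <- genes[i, ] |> mutate(sequence = substr(s, b + 1, nchar(s)))
          genes <<- bind_rows(
            if (i > 1) genes[seq_len(i - 1), ],
            part1, part2,
            if (i < nrow(genes)) genes[seq(i + 1, nrow(genes)), ]
          )
          slots$status[slots$label == ev$labels] <<- "FRAGMENTED"
        },
        INSERT_CATALOG = {
          rows <- catalog |> filter(.data$label %in% ev$labels)
          rows <- rows[match(ev$labels, rows$label), ]
          ins <- tibble(
            kind = "insert", label = rows$label,
            sequence = vapply(seq_len(nrow(rows)), function(j) {
              s <- evolve_protein(rows$sequence[j], ev$identity,
                                  sub_seeds[si + j - 1L])
              s
            }, character(1)),
            pseudo = FALSE, strand = "+"
          )
          si <<- si + nrow(rows)
          pos <- which(genes$label == ev$after & genes$kind == "cluster")
          genes <<- bind_rows(genes[seq_len(pos), ], ins,
                              genes[seq(pos + 1, nrow(genes)), ])
          expected_ins <<- bind_rows(expected_ins,
                                     tibble(after = ev$after,
                                            before = ev$before,
                                            labels = list(ev$labels)))
        },
        INSERT_FOREIGN = {
          lens <- sample(150:450, ev$n, replace = TRUE)
          ins <- tibble(
            kind = "insert", label = "FOREIGN",
            sequence = vapply(lens, .random_protein, character(1)),
            pseudo = FALSE, strand = "+"
          )
          pos <- which(genes$label == ev$after & genes$kind == "cluster")
          genes <<- bind_rows(genes[seq_len(pos), ], ins,
                              genes[seq(pos + 1, nrow(genes)), ])
          expected_ins <<- bind_rows(expected_ins,
                                     tibble(after = ev$after,
                                            before = ev$before,
                                            labels = list(rep("UNKNOWN",
                                                              ev$n))))
        },
        SPLIT_SAME_CONTIG = {
          spacer_before <<- c(spacer_before, ev$labels[1])
          spacer_bp <<- c(spacer_bp, as.integer(ev$spacer_bp))
          expected_split <<- list(split = TRUE,
                                  separation_bp = as.integer(ev$spacer_bp),
                                  excluded_contig_edge = FALSE)
        },
        SPLIT_CONTIGS = {
          second_contig <<- ev$labels
          at_edges <<- isTRUE(ev$at_edges)
          expected_split <<- list(split = TRUE,
                                  separation_bp = NA_integer_,
                                  excluded_contig_edge = isTRUE(ev$at_edges))
        },
        abort(paste0("unknown event kind: ", ev$kind))
      )
    }
    # apply DIVERGE first so that status events act on diverged sequences
    for (ev in events[kinds == "DIVERGE"]) apply_one(ev)
    for (ev in events[kinds != "DIVERGE"]) apply_one(ev)

    if (!plant_cluster) {
      genes <- genes[0, ]
      slots$status <- "ABSENT"
      expected_ins <- expected_ins[0, ]
      expected_split <- list(split = FALSE, separation_bp = NA_integer_,
                             excluded_contig_edge = FALSE)
    }

    # ---- layout ----
    on_ctg2 <- genes$kind == "cluster" & genes$label %in% second_contig
    n_before <- ceiling(nrow(decoys) / 2)
    layout1 <- if (plant_cluster && at_edges) {
      # cluster tail flush with the contig end
      bind_rows(decoys[seq_len(nrow(decoys)), ], genes[!on_ctg2, ])
    } else {
      bind_rows(decoys[seq_len(n_before), ], genes[!on_ctg2, ],
                decoys[seq(n_before + 1, nrow(decoys)), ])
    }
    layout1$contig <- "ctg1"
    layouts <- layout1
    if (any(on_ctg2)) {
      layout2 <- genes[on_ctg2, ]
      layout2$contig <- "ctg2"
      layouts <- bind_rows(layouts, layout2)
    }

    # coordinates: CDS length 3*aa+3; gaps 20-200 bp; spacers override
    layouts <- layouts |>
      group_by(.data$contig) |>
      mutate(idx = row_number()) |>
      ungroup()
    gaps <- sample(20:200, nrow(layouts), replace = TRUE)
    for (j in seq_along(spacer_before)) {
      k <- which(layouts$label == spacer_before[j] &
                   layouts$kind == "cluster")
      if (length(k) == 1) gaps[k] <- spacer_bp[j]
    }
    coords <- layouts |>
      group_by(.data$contig) |>
      mutate(
        cds_len = 3L * nchar(.data$sequence) + 3L,
        gap = {
          g <- gaps[dplyr::cur_group_rows()]
          g[1] <- 100L # leading margin
          g
        },
        end = cumsum(.data$gap + .data$cds_len),
        start = .data$end - .data$cds_len
      ) |>
      ungroup()

    locus <- sprintf("%s_%05d", toupper(genome_id),
                     seq_len(nrow(coords)) * 5L)
    coords$locus_tag <- locus
    coords$protein_id <- ifelse(coords$pseudo, NA_character_,
                                paste0("SYN_", locus))

    features <- coords |>
      mutate(contig_id = paste0(toupper(genome_id), "_", .data$contig),
             multi_segment = FALSE) |>
      select("locus_tag", "contig_id", "start", "end", "strand",
             "pseudo", "multi_segment", "protein_id") |>
      arrange(.data$contig_id, .data$start) |>
      group_by(.data$contig_id) |>
      mutate(ordinal = row_number()) |>
      ungroup()

    proteins <- coords |>
      filter(!.data$pseudo) |>
      mutate(
        product = dplyr::case_when(
          kind == "cluster" ~ paste0("eps cluster protein ", label),
          kind == "insert" ~ "inserted gene product",
          TRUE ~ "hypothetical protein"
        ),
        length = nchar(.data$sequence)
      ) |>
      select("protein_id", "product", "sequence", "length")

    planted_loci <- coords |>
      filter(.data$kind %in% c("cluster", "insert")) |>
      select("label", "locus_tag", "pseudo")
  })

  genome <- suppressMessages(
    link_genome(proteins, features, genome_id = genome_id)
  )
  manifest <- list(
    genome_id = genome_id,
    seed = seed,
    has_cluster = plant_cluster && nrow(planted_loci) > 0,
    events = events,
    expected_slots = slots,
    expected_insertions = expected_ins,
    expected_split = expected_split,
    planted_identity = planted_identity,
    planted_loci = planted_loci
  )
  list(genome = genome, manifest = manifest)
}

# ---- cohorts ---------------------------------------------------------------

#' Event lists for the default synthetic survey cohort
#'
#' Thirty genomes: 21 with a planted cluster (70% prevalence, as in real
#' Vibrionaceae surveys) covering every variation class - intact clusters
#' at several divergence levels, I+J / K / K+L deletions, L
#' pseudogenization, fragmented glycosyltransferases, truncated F,
#' catalog insertions (E, PABC, betaine trio between D and F; GFAT
#' between H and N), a foreign insertion, PQR separated by 60000 bp and
#' by 5000 bp, a cross-contig split at contig edges - and 9 decoy-only
#' genomes.
#'
#' @return Named list: per genome, a list with `events` and
#'   `plant_cluster`.
#' @export
default_cohort_events <- function() {
  ev <- function(..., plant = TRUE) list(events = list(...),
                                         plant_cluster = plant)
  list(
    g01 = ev(ev_diverge(0.95)),
    g02 = ev(ev_diverge(0.85)),
    g03 = ev(ev_diverge(0.75)),
    g04 = ev(ev_diverge(0.70), ev_delete(c("I", "J"))),
    g05 = ev(ev_diverge(0.80), ev_delete(c("I", "J"))),
    g06 = ev(ev_diverge(0.72), ev_delete("K")),
    g07 = ev(ev_diverge(0.68), ev_delete(c("K", "L")),
             ev_insert_catalog("E", after = "D", before = "F")),
    g08 = ev(ev_diverge(0.78), ev_pseudogenize("L")),
    g09 = ev(ev_diverge(0.82), ev_fragment("J", breakpoint = 0.5)),
    g10 = ev(ev_diverge(0.76), ev_truncate("F", keep = 0.5)),
    g11 = ev(ev_diverge(0.88), ev_insert_catalog("E", after = "D",
                                                 before = "F")),
    g12 = ev(ev_diverge(0.71), ev_insert_catalog("PABC", after = "D",
                                                 before = "F")),
    g13 = ev(ev_diverge(0.83),
             ev_insert_catalog(c("BETAINE_ABC_SBP", "BETAINE_ABC_PERM",
                                 "BETAINE_ABC_ATP"),
                               after = "D", before = "F")),
    g14 = ev(ev_diverge(0.66), ev_delete(c("I", "J")),
             ev_insert_catalog("GFAT", after = "H", before = "N")),
    g15 = ev(ev_diverge(0.74), ev_insert_foreign(1, after = "D",
                                                 before = "F")),
    g16 = ev(ev_diverge(0.81),
             ev_split_same_contig(c("P", "Q", "R"), spacer_bp = 60000)),
    g17 = ev(ev_diverge(0.77),
             ev_split_same_contig(c("P", "Q", "R"), spacer_bp = 5000)),
    g18 = ev(ev_diverge(0.79),
             ev_split_contigs(c("P", "Q", "R"), at_edges = TRUE)),
    g19 = ev(ev_diverge(0.84), ev_fragment("H", breakpoint = 0.45),
             ev_pseudogenize("I")),
    g20 = ev(ev_diverge(0.69), ev_truncate("F", keep = 0.55),
             ev_delete("K")),
    g21 = ev(ev_diverge(0.62)),
    g22 = ev(plant = FALSE), g23 = ev(plant = FALSE),
    g24 = ev(plant = FALSE), g25 = ev(plant = FALSE),
    g26 = ev(plant = FALSE), g27 = ev(plant = FALSE),
    g28 = ev(plant = FALSE), g29 = ev(plant = FALSE),
    g30 = ev(plant = FALSE)
  )
}

#' Build the default synthetic survey cohort
#'
#' Instantiates [default_cohort_events()] as linked genomes with
#' manifests, deterministically under `seed`.
#'
#' @param seed Integer master seed; per-genome seeds are derived from it.
#' @param background_genes Decoys per genome (default 40).
#' @return List with `genomes` (named list of `eps_genome`), `manifests`
#'   (named list) and `reference` (the synthetic reference bundle).
#' @export
default_cohort <- function(seed = 20180206, background_genes = 40) {
  ref <- synthetic_reference_cluster()
  spec <- default_cohort_events()
  g_seeds <- withr::with_seed(seed,
                              sample.int(.Machine$integer.max - 1L,
                                         length(spec)))
  out <- purrr::imap(spec, function(cfg, id) {
    plant_genome(ref$cluster, events = cfg$events,
                 background_genes = background_genes,
                 seed = g_seeds[[match(id, names(spec))]],
                 genome_id = id, plant_cluster = cfg$plant_cluster,
                 catalog = ref$catalog)
  })
  list(
    genomes = purrr::map(out, "genome"),
    manifests = purrr::map(out, "manifest"),
    reference = ref
  )
}

# balanced 8-leaf guide topology with the reference attached at the root
.guide_newick <- function() {
  "(((g1,g2),(g3,g4)),((g5,g6),(g7,g8)),ref);"
}

#' Generate a cohort evolved down a known guide tree
#'
#' Eight genomes (plus the reference taxon) related by a fixed balanced
#' guide topology. Cluster proteins and the five housekeeping genes
#' (pyrH, gapA, mreB, gyrB, topA, as nucleotide sequences long enough to
#' carry the published MLSA extraction ranges) accumulate point
#' substitutions along each edge, so the true topology is known and both
#' the cluster-protein tree and the MLSA tree can be scored against it.
#'
#' @param seed Integer seed.
#' @param edge_sub Substitution fraction per tree edge (default 0.03;
#'   the central edge uses twice this so the root split carries strong
#'   signal).
#' @param background_genes Decoys per genome.
#' @return List: `genomes` (named list of `eps_genome`, 8 leaves),
#'   `manifests`, `reference` (bundle), `guide_tree` (`phylo`, 9 taxa
#'   including `"ref"`), `housekeeping` (tibble genome_id/gene/sequence
#'   including the `ref` rows), `hk_ranges` (the MLSA extraction ranges).
#' @export
generate_cohort <- function(seed = 42, edge_sub = 0.03,
                            background_genes = 40) {
  ref <- synthetic_reference_cluster()
  hk_len <- c(pyrH = 630L, gapA = 900L, mreB = 900L, gyrB = 1050L,
              topA = 1104L)
  withr::with_seed(seed, {
    hk_root <- vapply(hk_len, .random_dna, character(1))
    seeds <- sample.int(.Machine$integer.max - 1L, 512)
  })
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  mutate_set <- function(prot, hk, frac) {
    prot$sequence <- vapply(prot$sequence, function(s)
      evolve_protein(s, 1 - frac, next_seed()), character(1),
      USE.NAMES = FALSE)
    hk <- vapply(hk, function(s)
      evolve_protein(s, 1 - frac, next_seed(), alphabet = "dna"),
      character(1))
    list(prot = prot, hk = hk)
  }

  root <- list(prot = ref$cluster, hk = hk_root)
  # two sides of the central split; central edge gets double weight
  left <- mutate_set(root$prot, root$hk, edge_sub * 2)
  right <- mutate_set(root$prot, root$hk, edge_sub * 2)
  l1 <- mutate_set(left$prot, left$hk, edge_sub)   # (g1,g2) ancestor
  l2 <- mutate_set(left$prot, left$hk, edge_sub)   # (g3,g4) ancestor
  r1 <- mutate_set(right$prot, right$hk, edge_sub)
  r2 <- mutate_set(right$prot, right$hk, edge_sub)
  leaves <- list(
    g1 = mutate_set(l1$prot, l1$hk, edge_sub),
    g2 = mutate_set(l1$prot, l1$hk, edge_sub),
    g3 = mutate_set(l2$prot, l2$hk, edge_sub),
    g4 = mutate_set(l2$prot, l2$hk, edge_sub),
    g5 = mutate_set(r1$prot, r1$hk, edge_sub),
    g6 = mutate_set(r1$prot, r1$hk, edge_sub),
    g7 = mutate_set(r2$prot, r2$hk, edge_sub),
    g8 = mutate_set(r2$prot, r2$hk, edge_sub)
  )

  out <- purrr::imap(leaves, function(lf, id) {
    plant_genome(lf$prot, events = list(),
                 background_genes = background_genes,
                 seed = next_seed(), genome_id = id,
                 catalog = ref$catalog)
  })
  hk_tbl <- bind_rows(
    purrr::imap_dfr(leaves, function(lf, id)
      tibble(genome_id = id, gene = names(lf$hk),
             sequence = unname(lf$hk))),
    tibble(genome_id = "ref", gene = names(hk_root),
           sequence = unname(hk_root))
  )
  list(
    genomes = purrr::map(out, "genome"),
    manifests = purrr::map(out, "manifest"),
    reference = ref,
    guide_tree = ape::read.tree(text = .guide_newick()),
    housekeeping = hk_tbl,
    hk_ranges = mlsa_reference_ranges()
  )
}
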