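# Context walking and classification of every architectural variation
# class, checked end-to-end against generator manifests.

test_that("an intact planted cluster reconstructs as all-PRESENT", {
  f <- fix_intact()
  a <- f$arch
  expect_true(a$found)
  expect_equal(a$seed_label, "A")
  expect_true(all(a$slots$status == "PRESENT"))
  expect_equal(a$slots$label, eps_labels())
  expect_equal(nrow(a$insertions), 0)
  expect_false(a$split)
  expect_equal(a$synteny_fraction, 1.0)
  # identity close to the planted 85% divergence target
  expect_true(all(abs(a$slots$identity_pct - 85) < 4))
})

test_that("every slot has exactly one status and tags match its rules", {
  a <- fix_case("mixed", list(ev_diverge(0.8), ev_truncate("F", 0.5),
                              ev_fragment("J", 0.5),
                              ev_pseudogenize("L")))$arch
  expect_equal(sort(a$slots$label), sort(eps_labels()))
  n_tags <- lengths(a$slots$locus_tags)
  expect_true(all(n_tags[a$slots$status %in% c("PRESENT", "TRUNCATED",
                                               "PSEUDOGENE")] == 1))
  expect_true(all(n_tags[a$slots$status == "FRAGMENTED"] >= 2))
  expect_true(all(n_tags[a$slots$status == "ABSENT"] == 0))
})

test_that("deletions, pseudogenes, fragments and truncations are classified", {
  cases <- list(
    list(name = "delIJ", events = list(ev_diverge(0.7),
                                       ev_delete(c("I", "J")))),
    list(name = "delKL", events = list(ev_diverge(0.68),
                                       ev_delete(c("K", "L")))),
    list(name = "pseL", events = list(ev_diverge(0.78),
                                      ev_pseudogenize("L"))),
    list(name = "fraJ", events = list(ev_diverge(0.82),
                                      ev_fragment("J", 0.5))),
    list(name = "truF", events = list(ev_diverge(0.76),
                                      ev_truncate("F", 0.5)))
  )
  for (cs in cases) {
    f <- fix_case(cs$name, cs$events)
    got <- tidy(f$arch)
    exp <- f$pg$manifest$expected_slots
    cmp <- dplyr::left_join(exp, got, by = "label",
                            suffix = c("_exp", "_got"))
    expect_equal(cmp$status_got, cmp$status_exp,
                 label = paste0(cs$name, " statuses"))
  }
})

test_that("a truncated subject shows MinLrap near 1 but low MaxLrap", {
  a <- fix_case("truF", list(ev_diverge(0.76),
                             ev_truncate("F", 0.5)))$arch
  row <- a$slots[a$slots$label == "F", ]
  expect_equal(row$status, "TRUNCATED")
  expect_gte(row$min_lrap, 0.8)
  expect_lt(row$max_lrap, 0.8)
})

test_that("fragment parts cover disjoint regions of the reference gene", {
  f <- fix_case("fraJ", list(ev_diverge(0.82), ev_fragment("J", 0.5)))
  row <- f$arch$slots[f$arch$slots$label == "J", ]
  expect_equal(row$status, "FRAGMENTED")
  tags <- row$locus_tags[[1]]
  expect_equal(length(tags), 2)
  # both parts are the planted fragment loci, in genomic order
  planted <- f$pg$manifest$planted_loci
  expect_equal(tags, planted$locus_tag[planted$label == "J"])
})

test_that("insertions between D and F are detected and identified", {
  f <- fix_case("insE", list(ev_diverge(0.88),
                             ev_insert_catalog("E", after = "D",
                                               before = "F")))
  ins <- f$arch$insertions
  expect_equal(nrow(ins), 1)
  expect_equal(ins$after, "D")
  expect_equal(ins$before, "F")
  expect_equal(ins$assigned[[1]], "E")

  trio <- fix_case("trio", list(
    ev_diverge(0.83),
    ev_insert_catalog(c("BETAINE_ABC_SBP", "BETAINE_ABC_PERM",
                        "BETAINE_ABC_ATP"), after = "D", before = "F")
  ))$arch$insertions
  expect_equal(lengths(trio$locus_tags), 3)
  expect_equal(trio$assigned[[1]],
               c("BETAINE_ABC_SBP", "BETAINE_ABC_PERM", "BETAINE_ABC_ATP"))

  foreign <- fix_case("insX", list(ev_diverge(0.74),
                                   ev_insert_foreign(1, after = "D",
                                                     before = "F")))
  expect_equal(foreign$arch$insertions$assigned[[1]], "UNKNOWN")
})

test_that("same-contig separations are recovered exactly and flag a split", {
  s60 <- fix_case("s60", list(ev_diverge(0.81),
                              ev_split_same_contig(c("P", "Q", "R"),
                                                   60000)))$arch
  expect_true(s60$split)
  expect_equal(s60$separation_bp, 60000L)
  expect_false(s60$excluded_contig_edge)
  expect_equal(length(s60$split_parts), 2)
  expect_setequal(s60$split_parts[[2]]$labels, c("P", "Q", "R"))

  s5 <- fix_case("s5", list(ev_diverge(0.77),
                            ev_split_same_contig(c("P", "Q", "R"),
                                                 5000)))$arch
  expect_true(s5$split)
  expect_equal(s5$separation_bp, 5000L)

  # a contiguous cluster with ordinary intergenic gaps is not split
  expect_false(fix_intact()$arch$split)
})

test_that("clusters split across contig ends are flagged for exclusion", {
  a <- fix_case("sctg", list(ev_diverge(0.79),
                             ev_split_contigs(c("P", "Q", "R"),
                                              at_edges = TRUE)))$arch
  expect_true(a$split)
  expect_true(a$excluded_contig_edge)
  expect_true(is.na(a$separation_bp))
  ctgs <- vapply(a$split_parts, `[[`, character(1), "contig_id")
  expect_equal(length(unique(ctgs)), 2)
})

test_that("synteny fraction matches an independent adjacency recount", {
  ref <- fix_ref()
  # one insertion breaks exactly one adjacency among the PRESENT labels
  f <- fix_case("insE", list(ev_diverge(0.88),
                             ev_insert_catalog("E", after = "D",
                                               before = "F")))
  a <- f$arch
  n_adj <- length(eps_labels()) - 1
  expect_equal(a$synteny_fraction, (n_adj - 1) / n_adj)
  expect_equal(a$synteny_fraction,
               synteny_oracle(a, f$pg$genome, ref$cluster$label))

  # a fully shuffled gene order: fraction equals the brute-force count
  perm <- withr::with_seed(31, sample(nrow(ref$cluster)))
  shuf <- plant_genome(ref$cluster[perm, ],
                       events = list(ev_diverge(0.85)),
                       seed = 17, genome_id = "shuffled")
  as <- scan_genome(shuf$genome, ref)
  expect_true(all(as$slots$status == "PRESENT"))
  expect_equal(as$synteny_fraction,
               synteny_oracle(as, shuf$genome, ref$cluster$label))
  expect_lt(as$synteny_fraction, 0.5)
})

test_that("a cluster-negative genome reports not-found with all slots absent", {
  neg <- memo("neg_scan", {
    pg <- plant_genome(fix_ref()$cluster, seed = 23, genome_id = "neg",
                       plant_cluster = FALSE)
    scan_genome(pg$genome, fix_ref())
  })
  expect_false(neg$found)
  expect_true(all(neg$slots$status == "ABSENT"))
  expect_true(is.na(neg$seed_label))
})
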