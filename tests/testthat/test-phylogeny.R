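# Distances, corrections, NJ against the exhaustive least-squares
# oracle, bootstrap, concatenation and the MLSA extraction.

test_that("p-distance uses pairwise deletion", {
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("AAAA", "AATT"), 0.5)
  expect_equal(p_distance("A-CT", "AGCT"), 0) # 3 comparable columns
  expect_error(p_distance("----", "AAAA"), "no comparable")
  expect_error(p_distance("AA", "AAA"), "equal length")
})

test_that("distance corrections match their closed forms on a p grid", {
  p <- seq(0, 0.98, by = 0.01)
  expect_equal(poisson_correct(p), -log(1 - p), tolerance = 1e-12)
  expect_equal(poisson_correct(0.5), 0.6931472, tolerance = 1e-6)
  pj <- seq(0, 0.74, by = 0.01)
  expect_equal(jukes_cantor(pj), -0.75 * log(1 - 4 * pj / 3),
               tolerance = 1e-12)
  expect_equal(jukes_cantor(0.3), 0.3831192, tolerance = 1e-6)
  # domain boundaries
  expect_error(poisson_correct(1), "p < 1")
  expect_error(jukes_cantor(0.75), "p < 0.75")
  # strictly increasing, and d -> p to first order near 0
  expect_true(all(diff(poisson_correct(p)) > 0))
  expect_true(all(diff(jukes_cantor(pj)) > 0))
  expect_equal(poisson_correct(1e-4), 1e-4, tolerance = 1e-4)
  expect_equal(jukes_cantor(1e-4), 1e-4, tolerance = 1e-4)
})

test_that("NJ small cases follow the closed forms", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(D2)
  expect_equal(sum(t2$edge.length), 0.4)

  D3 <- matrix(c(0, 0.3, 0.5,
                 0.3, 0, 0.6,
                 0.5, 0.6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  len <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(len[["a"]], (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-12)
  expect_equal(len[["b"]], (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-12)
  expect_equal(len[["c"]], (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-12)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ recovers additive trees exactly (least-squares oracle)", {
  for (cfg in list(c(n = 4, seed = 21), c(n = 6, seed = 22))) {
    ra <- random_additive(cfg[["n"]], cfg[["seed"]])
    nj <- nj_tree(ra$D)
    oracle <- ls_oracle_tree(ra$D)
    expect_lt(oracle$ssq, 1e-20)
    expect_equal(robinson_foulds(nj, oracle$tree), 0)
    expect_equal(robinson_foulds(nj, ra$tree), 0)
    # branch lengths agree through the path metric
    m1 <- ape::cophenetic.phylo(nj)
    m2 <- ape::cophenetic.phylo(oracle$tree)
    expect_equal(m1[rownames(m2), colnames(m2)], m2, tolerance = 1e-8)
  }
})

test_that("negative NJ branches are clamped and reported", {
  # a slightly non-additive matrix that induces a negative branch
  D <- matrix(c(0, 0.1, 0.5, 0.55,
                0.1, 0, 0.52, 0.2,
                0.5, 0.52, 0, 0.6,
                0.55, 0.2, 0.6, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped"), 0)
})

test_that("bootstrap is seeded, bounded and certain on a clean split", {
  # two well-separated pairs: aa|bb split in every informative column
  aln <- c(a1 = strrep("A", 60), a2 = strrep("A", 60),
           b1 = strrep("C", 60), b2 = strrep("C", 60))
  noise <- c("G", "T")
  aln <- vapply(seq_along(aln), function(i) {
    s <- strsplit(aln[i], "")[[1]]
    s[seq(i, 60, by = 7)] <- noise[1 + i %% 2]
    paste(s, collapse = "")
  }, character(1)) |> setNames(c("a1", "a2", "b1", "b2"))
  bs <- bootstrap_support(aln, n_replicates = 100, seed = 5)
  expect_true(all(bs$support >= 0 & bs$support <= 100))
  internal <- bs$support[-1] # root pseudo-node carries no bipartition
  expect_equal(max(internal), 100)
  # identical seed, identical supports; different seed may differ
  bs2 <- bootstrap_support(aln, n_replicates = 100, seed = 5)
  expect_identical(bs$support, bs2$support)
})

test_that("the display filter hides supports at or below 70", {
  expect_equal(format_support_labels(c(100, 71, 70, 12)),
               c("100", "71", "", ""))
})

test_that("concatenation gap-fills absent genes without changing width", {
  alns <- list(
    g1 = c(a = "MKTA", b = "MKTA", c = "MATA"),
    g2 = c(a = "WWPG", b = "WLPG")
  )
  conc <- concatenate_alignments(alns)
  expect_equal(unique(nchar(conc$alignment)), 8L)
  expect_equal(conc$alignment[["c"]], "MATA----")
  expect_equal(conc$blocks$start, c(1L, 5L))
  expect_equal(conc$blocks$end, c(4L, 8L))
  # single-gene cohort reduces to that gene's alignment
  one <- concatenate_alignments(alns[1])
  expect_equal(one$alignment, alns$g1)
  expect_warning(
    concatenate_alignments(alns, taxa = c("a", "b", "c", "zz")),
    "absent from every block")
})

test_that("MLSA extraction yields 2943 reference positions on gap-free rows", {
  ranges <- mlsa_reference_ranges()
  widths <- ranges$end - ranges$start + 1
  lens <- c(pyrH = 630, gapA = 900, mreB = 900, gyrB = 1050, topA = 1104)
  alns <- withr::with_seed(77, lapply(lens, function(L) {
    ref <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    oth <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    c(ref = ref, x = oth)
  }))
  conc <- mlsa_extract(alns, reference_taxon = "ref")
  expect_equal(unique(nchar(conc$alignment)), as.integer(sum(widths)))
  expect_equal(sum(widths), 2943)
  expect_equal(conc$blocks$width, as.integer(widths))
})

test_that("MLSA block columns follow the reference gap pattern", {
  ranges <- mlsa_reference_ranges()
  lens <- c(pyrH = 630, gapA = 900, mreB = 900, gyrB = 1050, topA = 1104)
  alns <- withr::with_seed(78, lapply(lens, function(L) {
    ref <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    c(ref = ref, x = paste(sample(c("A", "C", "G", "T"), L, TRUE),
                           collapse = ""))
  }))
  # inject 3 gap columns inside the pyrH range of the reference row
  a <- alns$pyrH
  ins <- function(s, at, ch) paste0(substr(s, 1, at), ch,
                                    substr(s, at + 1, nchar(s)))
  a["ref"] <- ins(a[["ref"]], 100, "---")
  a["x"] <- ins(a[["x"]], 100, "GGG")
  alns$pyrH <- a
  conc <- mlsa_extract(alns, reference_taxon = "ref")
  # pyrH block widens by the 3 internal gaps; ref residues stay 562
  expect_equal(conc$blocks$width[1], 565L)
  ref_block <- substr(conc$alignment[["ref"]], 1, 565)
  expect_equal(sum(strsplit(ref_block, "")[[1]] != "-"), 562)
  # gap-only columns elsewhere leave the extracted widths unchanged
  b <- alns$gapA
  b["ref"] <- ins(b[["ref"]], 5, "--")
  b["x"] <- ins(b[["x"]], 5, "--")
  alns$gapA <- b
  conc2 <- mlsa_extract(alns, reference_taxon = "ref")
  expect_equal(conc2$blocks$width, conc$blocks$width)

  short <- list(pyrH = c(ref = strrep("A", 100), x = strrep("C", 100)))
  expect_error(
    mlsa_extract(short, ranges = mlsa_reference_ranges()[1, ]),
    "exceeds")
})

test_that("identical sequences align gap-free and imports are verbatim", {
  s <- fix_ref()$cluster$sequence[2]
  aln <- align_sequences(c(x = s, y = s), mode = "protein")
  expect_equal(unname(nchar(aln)), c(nchar(s), nchar(s)))
  expect_false(any(grepl("-", aln)))

  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1", "MK-TA", ">t2", "MKWTA"), path)
  imp <- import_alignment(path)
  expect_equal(imp, c(t1 = "MK-TA", t2 = "MKWTA"))
  writeLines(c(">t1", "MK-TA", ">t2", "MKWT"), path)
  expect_error(import_alignment(path), "unequal")
})
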