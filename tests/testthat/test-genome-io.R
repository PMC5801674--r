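# NCBI two-file convention: header token parsing, coordinate
# conventions, linking, and round trips.

test_that("NCBI location strings parse to 0-based half-open coordinates", {
  plain <- parse_ncbi_location("123..456")
  expect_equal(plain$start, 122L)
  expect_equal(plain$end, 456L)
  expect_equal(plain$strand, "+")
  expect_false(plain$multi_segment)

  comp <- parse_ncbi_location("complement(123..456)")
  expect_equal(comp$start, 122L)
  expect_equal(comp$end, 456L)
  expect_equal(comp$strand, "-")

  joined <- parse_ncbi_location("join(10..20,30..40)")
  expect_equal(joined$start, 9L)
  expect_equal(joined$end, 40L)
  expect_true(joined$multi_segment)

  partial <- parse_ncbi_location("complement(<5..>99)")
  expect_equal(partial$start, 4L)
  expect_equal(partial$end, 99L)

  expect_error(parse_ncbi_location("oops"), "unparseable")
})

test_that("coordinate text round-trips through the internal convention", {
  for (case in list(c(0L, 10L, "+"), c(121L, 456L, "-"), c(5L, 6L, "+"))) {
    txt <- format_ncbi_location(as.integer(case[1]), as.integer(case[2]),
                                case[3])
    back <- parse_ncbi_location(txt)
    expect_equal(back$start, as.integer(case[1]))
    expect_equal(back$end, as.integer(case[2]))
    expect_equal(back$strand, case[3])
  }
})

test_that("protein FASTA reading extracts ids, products and lengths", {
  path <- withr::local_tempfile(fileext = ".faa")
  write_fasta(
    c("WP_1 hypothetical protein [Vibrio sp.]", "WP_2", "WP_3 stop test"),
    c(strrep("M", 100), "MKT", "MKTAYIA*"),
    path
  )
  p <- read_protein_fasta(path)
  expect_equal(nrow(p), 3)
  expect_equal(p$protein_id, c("WP_1", "WP_2", "WP_3"))
  expect_equal(p$product[1], "hypothetical protein [Vibrio sp.]")
  expect_equal(p$length[1], 100L)
  # trailing stop symbol stripped so Lprot semantics hold
  expect_equal(p$sequence[3], "MKTAYIA")
  expect_equal(p$length[3], 7L)
})

test_that("protein FASTA rejects bad input", {
  path <- withr::local_tempfile(fileext = ".faa")
  writeLines(character(0), path)
  expect_error(read_protein_fasta(path), "empty")
  write_fasta("W1", "MKTZXB", path)
  expect_error(read_protein_fasta(path), "non-amino-acid")
  expect_error(read_protein_fasta(file.path(tempdir(), "nope.faa")),
               "not found")
})

test_that("cds_from_genomic headers parse tokens, strand and ordinals", {
  path <- withr::local_tempfile(fileext = ".fna")
  write_fasta(
    c(paste0("lcl|ctgA_cds_1 [locus_tag=G_00005] [protein_id=P1] ",
             "[location=101..200]"),
      paste0("lcl|ctgA_cds_2 [locus_tag=G_00010] ",
             "[location=complement(301..400)] [pseudo=true]"),
      paste0("lcl|ctgB_cds_3 [locus_tag=G_00015] [protein_id=P3] ",
             "[location=join(10..20,30..40)]")),
    c(strrep("A", 100), strrep("C", 100), strrep("G", 31)),
    path
  )
  f <- read_cds_features(path)
  expect_equal(nrow(f), 3)
  a <- f[f$locus_tag == "G_00005", ]
  expect_equal(a$start, 100L)
  expect_equal(a$end, 200L)
  expect_equal(a$strand, "+")
  expect_false(a$pseudo)
  b <- f[f$locus_tag == "G_00010", ]
  expect_equal(b$strand, "-")
  expect_true(b$pseudo)
  expect_true(is.na(b$protein_id))
  j <- f[f$locus_tag == "G_00015", ]
  expect_true(j$multi_segment)
  expect_equal(j$start, 9L)
  expect_equal(j$end, 40L)
  # ordinals rank by start within each contig
  expect_equal(f$ordinal[f$contig_id == "ctgA"], c(1L, 2L))
  expect_equal(f$ordinal[f$contig_id == "ctgB"], 1L)
})

test_that("headers lacking locus_tag and location are skipped with warning", {
  path <- withr::local_tempfile(fileext = ".fna")
  write_fasta(
    c("lcl|ctgA_cds_1 [locus_tag=G_1] [location=1..9]", "lcl|junk header"),
    c("ATGATGATG", "ATG"),
    path
  )
  expect_warning(f <- read_cds_features(path), "skipped")
  expect_equal(nrow(f), 1)
})

test_that("linking joins through protein_id and flags duplicates", {
  proteins <- tibble::tibble(
    protein_id = c("P1", "P2"), product = "x",
    sequence = c("MKTAYIAKQR", "MWWTTNNPPG"), length = 10L
  )
  features <- tibble::tibble(
    locus_tag = c("L1", "L2", "L3"), contig_id = "c1",
    start = c(0L, 100L, 200L), end = c(30L, 130L, 230L), strand = "+",
    pseudo = c(FALSE, FALSE, TRUE), multi_segment = FALSE,
    protein_id = c("P1", "P2", NA), ordinal = 1:3
  )
  g <- link_genome(proteins, features, "t")
  expect_s3_class(g, "eps_genome")
  expect_equal(sum(!is.na(g$link$sequence)), 2)
  # pseudo feature without protein is legitimate, not an orphan
  expect_message(link_genome(proteins, features, "t"), NA)

  expect_error(
    link_genome(proteins[c(1, 1), ], features, "t"), "duplicate")
  expect_error(
    link_genome(proteins, features[c(1, 1, 2), ], "t"), "duplicate")
})

test_that("a planted genome survives a write/read round trip", {
  pg <- plant_genome(fix_ref()$cluster,
                     events = list(ev_diverge(0.8), ev_pseudogenize("L")),
                     seed = 5, genome_id = "rt", background_genes = 10)
  dir <- withr::local_tempdir()
  write_genome_files(pg$genome, dir)
  back <- read_genome(dir, "rt")
  expect_equal(back$proteins, pg$genome$proteins)
  expect_equal(
    back$features |> dplyr::select(-multi_segment),
    pg$genome$features |>
      dplyr::arrange(contig_id, start) |>
      dplyr::select(-multi_segment)
  )
  expect_equal(sum(back$features$pseudo), 1)
})
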