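# MinLrap/MaxLrap statistics and the four-part ortholog acceptance rule.

test_that("alignment length ratios follow their defining formulas", {
  # both ratios 1 exactly when both whole proteins align
  expect_equal(compute_lrap(100, 100, 100),
               tibble::tibble(min_lrap = 1, max_lrap = 1))
  expect_equal(compute_lrap(50, 50, 100),
               tibble::tibble(min_lrap = 1, max_lrap = 0.5))
  expect_equal(compute_lrap(90, 120, 100),
               tibble::tibble(min_lrap = 0.9, max_lrap = 0.75))
  expect_error(compute_lrap(10, 0, 100), "positive")
})

test_that("lrap agrees with an independent recomputation on random triples", {
  withr::with_seed(1234, {
    Lm <- sample.int(2000, 1e4, replace = TRUE)
    L1 <- sample.int(2000, 1e4, replace = TRUE)
    L2 <- sample.int(2000, 1e4, replace = TRUE)
  })
  lr <- compute_lrap(Lm, L1, L2)
  expect_equal(lr$min_lrap, Lm / pmin(L1, L2))
  expect_equal(lr$max_lrap, Lm / pmax(L1, L2))
  # dividing by the larger length always gives the smaller ratio
  expect_true(all(lr$max_lrap <= lr$min_lrap))
  expect_true(all(lr$max_lrap > 0))
})

make_hit <- function(label = "A", locus = "L1", evalue = 1e-30,
                     identity = 60, Lmatch = 95L, L1n = 100L,
                     L2n = 100L, bits = 200) {
  tibble::tibble(
    query_label = label, subject_locus = locus, protein_id = NA_character_,
    score = NA_real_, bitscore = bits, evalue = evalue,
    identity_pct = identity, Lmatch = Lmatch, Lprot1 = L1n, Lprot2 = L2n,
    q_start = 1L, q_end = Lmatch
  )
}

test_that("each acceptance criterion rejects exactly its own failure mode", {
  th <- eps_thresholds()
  pass <- call_orthologs(make_hit(), th)
  expect_true(pass$passed)
  expect_equal(pass$fail_reasons[[1]], character(0))

  weak_e <- call_orthologs(make_hit(evalue = 1e-20), th)
  expect_false(weak_e$passed)
  expect_equal(weak_e$fail_reasons[[1]], "EVALUE")

  weak_id <- call_orthologs(make_hit(identity = 35), th)
  expect_false(weak_id$passed)
  expect_equal(weak_id$fail_reasons[[1]], "IDENTITY")

  short <- call_orthologs(make_hit(Lmatch = 70L), th)
  expect_false(short$passed)
  expect_equal(short$fail_reasons[[1]], "LRAP")

  sized <- call_orthologs(make_hit(Lmatch = 100L, L2n = 200L), th)
  expect_false(sized$passed)
  expect_setequal(sized$fail_reasons[[1]], c("LRAP", "SIZE"))

  # boundary semantics: E strictly below 1e-25, identity strictly above 40
  expect_false(call_orthologs(make_hit(evalue = 1e-25), th)$passed)
  expect_false(call_orthologs(make_hit(identity = 40), th)$passed)
  expect_true(call_orthologs(make_hit(evalue = 1e-26, identity = 40.1),
                             th)$passed)
})

test_that("the first fully passing hit wins; otherwise the least-failing one reports", {
  th <- eps_thresholds()
  hits <- dplyr::bind_rows(
    make_hit(locus = "BAD", evalue = 1e-40, identity = 30),
    make_hit(locus = "GOOD", evalue = 1e-30)
  )
  call <- call_orthologs(hits, th)
  expect_true(call$passed)
  expect_equal(call$subject_locus, "GOOD")

  none <- dplyr::bind_rows(
    make_hit(locus = "X", evalue = 1e-40, identity = 30, Lmatch = 60L),
    make_hit(locus = "Y", evalue = 1e-35, identity = 30)
  )
  call2 <- call_orthologs(none, th)
  expect_false(call2$passed)
  expect_true(is.na(call2$subject_locus))
  expect_equal(call2$fail_reasons[[1]], "IDENTITY") # the least-failing hit
})

test_that("labels with no hits report ABSENT with empty reasons", {
  calls <- call_orthologs(make_hit(label = "A"), eps_thresholds(),
                          labels = c("A", "B"))
  expect_equal(calls$passed, c(TRUE, FALSE))
  expect_true(is.na(calls$subject_locus[2]))
  expect_equal(calls$fail_reasons[[2]], character(0))
})

test_that("calling is threshold-monotone: relaxing never loses a call", {
  strict <- eps_thresholds()
  loose <- eps_thresholds(evalue_max = 1e-20, identity_min = 30,
                          lrap_min = 0.6, size_ratio_max = 2.5)
  withr::with_seed(99, {
    for (k in 1:50) {
      h <- make_hit(evalue = 10^-sample(10:40, 1),
                    identity = runif(1, 20, 95),
                    Lmatch = sample(40:150, 1),
                    L1n = sample(80:150, 1), L2n = sample(80:150, 1))
      h$Lmatch <- min(h$Lmatch, max(h$Lprot1, h$Lprot2))
      if (call_orthologs(h, strict)$passed) {
        expect_true(call_orthologs(h, loose)$passed)
      }
    }
  })
})

test_that("seed selection follows the conservation priority order", {
  calls <- tibble::tibble(query_label = eps_labels(),
                          passed = rep(TRUE, 16))
  expect_equal(select_seed(calls), "A")
  calls$passed[calls$query_label == "A"] <- FALSE
  expect_equal(select_seed(calls), "B")
  # with regulators gone, C passes next among A,B,C,G,O,R
  calls$passed[calls$query_label %in% c("B", "G", "O", "R")] <- FALSE
  expect_equal(select_seed(calls), "C")
  # only a mid-cluster GT left: falls back to cluster order
  calls$passed <- calls$query_label == "J"
  expect_equal(select_seed(calls), "J")
  calls$passed <- FALSE
  expect_true(is.na(select_seed(calls)))
})
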