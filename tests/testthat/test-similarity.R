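test_that("closed-form P1 reproduces the canonical uniform-pair values", {
  p_ac <- p1_analytic(encode_sequence("AAAA"), encode_sequence("CCCC"))
  p_at <- p1_analytic(encode_sequence("AAAA"), encode_sequence("TTTT"))
  p_ag <- p1_analytic(encode_sequence("AAAA"), encode_sequence("GGGG"))
  expect_equal(round(p_ac, 3), 0.146)
  expect_equal(round(p_at, 3), 0.371)
  expect_equal(p_ag, 0.5)
  expect_equal(p1_analytic(encode_sequence("AAAA"),
                           encode_sequence("AAAA")), 0)
})

test_that("closed-form P1 rejects mismatched padded lengths", {
  expect_error(p1_analytic(encode_sequence("AAAA"), encode_sequence("AA")),
               "mismatch")
})

test_that("similarity score is 1 - 2*p1 on [0, 0.5] and rejects beyond", {
  expect_equal(similarity_score(0), 1)
  expect_equal(similarity_score(0.5), 0)
  expect_equal(round(similarity_score(0.146), 3), 0.708)
  # the formula applied to a measured 0.378 gives 0.244
  expect_equal(similarity_score(0.378), 0.244)
  expect_error(similarity_score(0.7), "outside")
  expect_error(similarity_score(-0.1), "outside")
})

test_that("padding correction removes the guaranteed-match contribution", {
  expect_equal(similarity_corrected(0.2, 4, 0), similarity_score(0.2))

  # one real A position against G, padded with three matching G's
  ref <- encode_sequence("A")   # k = 0; force shared 2-index-qubit register
  refp <- encode_sequence("A", min_index_qubits = 2L)
  cmpp <- encode_sequence("G", min_index_qubits = 2L)
  p1 <- p1_analytic(refp, cmpp)
  expect_equal(p1, 0.125)  # (1 - 3/4)/2 with cos(pi/2 - 0) = 0
  expect_equal(similarity_corrected(p1, 1, 3), 0)

  # identical padded pair stays at 1
  a <- encode_sequence("ACG")
  b <- encode_sequence("ACG")
  expect_equal(similarity_corrected(p1_analytic(a, b), 3, 1), 1)
})

test_that("seqsim orchestrates all three methods coherently", {
  exact <- 0.5 * (1 - cos(pi / 2 - pi / 12))

  rs <- seqsim("AAAA", "AAAA", method = "analytic")
  expect_s3_class(rs, "seqsim")
  expect_equal(rs$similarity, 1)
  expect_equal(rs$p1, 0)

  sv <- seqsim("AAAA", "TTTT", method = "statevector")
  expect_equal(sv$p1, exact, tolerance = 1e-9)
  expect_equal(sv$similarity, 1 - 2 * sv$p1)

  sh <- seqsim("AAAA", "TTTT", method = "shots", shots = 8000, seed = 123)
  expect_equal(sum(sh$counts), 8000L)
  expect_equal(sh$p1, sh$counts[["1"]] / 8000)
  band <- 3 * sqrt(exact * (1 - exact) / 8000)
  expect_lt(abs(sh$p1 - exact), band * 2)  # generous single-seed check
  expect_error(seqsim("AAAA", "TTTT", method = "shots"), "seed")
})

test_that("unequal lengths require explicit padding", {
  expect_error(seqsim("AAAA", "AAA"), "pad")
  res <- seqsim("AAAA", "AAA", pad = TRUE)
  # the cross-length fill faces a real residue, so it counts as compared
  expect_equal(res$n_real, 4L)
  expect_equal(res$n_pad, 0L)
  expect_equal(res$p1, 0.125)  # A vs pad-G mismatch at the filled position
  expect_true(is.na(res$similarity_corrected))

  # joint padding beyond the longer length is corrected for
  res5 <- seqsim("ACGTA", "ACGTT", pad = FALSE)
  expect_equal(res5$n_real, 5L)
  expect_equal(res5$n_pad, 3L)
  expect_equal(res5$similarity_corrected,
               similarity_corrected(res5$p1, 5, 3))
})

test_that("comparison is symmetric and self-comparison is perfect", {
  set.seed(71)
  for (rep in 1:10) {
    a <- random_seq(sample(1:8, 1))
    b <- random_seq(nchar(a))
    expect_equal(seqsim(a, b)$p1, seqsim(b, a)$p1, tolerance = 1e-12)
    expect_equal(seqsim(a, b, method = "statevector")$p1,
                 seqsim(b, a, method = "statevector")$p1, tolerance = 1e-9)
    expect_equal(seqsim(a, a)$similarity, 1)
    expect_equal(seqsim(a, a, method = "statevector")$p1, 0,
                 tolerance = 1e-12)
  }
  # smallest case: single residue, k = 0, two-qubit circuit
  qc <- build_comparison_circuit(encode_sequence("A"), encode_sequence("A"))
  expect_equal(qc$n_qubits, 2L)
  expect_equal(strip_p1(run_statevector(qc), 0L), 0, tolerance = 1e-12)
})

test_that("P1 grows with the single-position angle gap", {
  gaps <- seq(0, pi, length.out = 13)
  p1s <- vapply(gaps, function(g) {
    m <- angle_map(c(A = 0, B = g), pad_symbol = "A")
    p1_analytic(encode_sequence("A", m), encode_sequence("B", m))
  }, numeric(1))
  expect_true(all(diff(p1s) >= -1e-12))
  expect_equal(p1s[1], 0)
  expect_equal(p1s[13], 0.5 * (1 - cos(pi / 2)))
})

test_that("shot estimator error shrinks within binomial bounds", {
  exact <- 0.5 * (1 - cos(pi / 2 - pi / 12))
  for (shots in c(1e2, 1e4, 1e6)) {
    est <- sample_strip(exact, shots, seed = 2024)$counts[["1"]] / shots
    expect_lt(abs(est - exact), 3 * sqrt(exact * (1 - exact) / shots))
  }
})

test_that("results serialize to schema-conformant JSON and one-row TSV", {
  res <- seqsim("AAAA", "TTTT", method = "shots", shots = 1000, seed = 9,
                ref_id = "s1", cmp_id = "s2")
  parsed <- jsonlite::fromJSON(seqsim_json(res))
  schema <- jsonlite::fromJSON(system.file("extdata",
                                           "comparison_result_schema.json",
                                           package = "frqiseq"))
  expect_true(all(schema$required %in% names(parsed)))
  expect_type(parsed$p1, "double")
  expect_true(parsed$method %in% c("analytic", "statevector", "shots"))
  expect_equal(parsed$counts[["0"]] + parsed$counts[["1"]], 1000L)

  tsv <- seqsim_tsv(res)
  rows <- strsplit(tsv, "\n")[[1]]
  expect_length(rows, 2L)
  expect_equal(strsplit(rows[1], "\t")[[1]][1], "ref_id")
  expect_equal(strsplit(rows[2], "\t")[[1]][1], "s1")
})

test_that("simulate() resamples shot estimates around the exact P1", {
  res <- seqsim("AAAA", "TTTT", method = "statevector")
  draws <- simulate(res, nsim = 20, seed = 5, shots = 8000)
  expect_length(draws, 20L)
  exact <- res$p1
  expect_lt(max(abs(draws - exact)), 5 * sqrt(exact * (1 - exact) / 8000))
  expect_identical(draws, simulate(res, nsim = 20, seed = 5, shots = 8000))
})
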