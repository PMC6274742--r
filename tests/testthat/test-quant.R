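test_that("symmetric counts give an Rsc of exactly zero", {
  expect_identical(compute_rsc(5, 5, 100, 100), 0)
  expect_identical(compute_rsc(0, 0, 50, 50), 0)
})

test_that("Rsc matches its closed form on a worked example", {
  # log2(11.25/6.25) + log2(96.25/91.25), evaluated independently
  expect_equal(compute_rsc(n_s = 10, n_n = 5, t_s = 100, t_n = 100),
               rsc_oracle(10, 5, 100, 100), tolerance = 1e-12)
  expect_equal(compute_rsc(10, 5, 100, 100), 0.9249589, tolerance = 1e-7)
})

test_that("Rsc rejects invalid inputs instead of clamping", {
  expect_error(compute_rsc(10, 5, 8, 100), "totals")
  expect_error(compute_rsc(10, 5, 100, 4), "totals")
  expect_error(compute_rsc(-1, 5, 100, 100), "nonnegative")
  expect_error(compute_rsc(1, 1, 10, 10, f = 0), "positive")
  expect_error(compute_rsc(1, 1, 10, 10, f = -2), "positive")
})

test_that("classification uses strict thresholds", {
  cfg <- quant_config()
  expect_equal(classify_rsc(c(2.0601, 1.459, -2.277, -1.505), cfg),
               c("up", "up", "down", "down"))
  expect_equal(classify_rsc(c(1, -1, 0.999, -0.999, 0), cfg),
               rep("unchanged", 5))
  expect_error(quant_config(up_threshold = 0, down_threshold = 0),
               "strictly below")
  expect_error(quant_config(f = 0), "positive")
})

test_that("NSAF is the length-normalized relative abundance", {
  cm1 <- count_matrix(matrix(c(7L, 3L), ncol = 2,
                             dimnames = list("P1", c("a", "b"))),
                      lengths = c(P1 = 150L))
  expect_equal(compute_nsaf(cm1, "a"), c(P1 = 1))

  cm2 <- count_matrix(matrix(c(4L, 2L, 1L, 1L), ncol = 2,
                             dimnames = list(c("P1", "P2"), c("a", "b"))),
                      lengths = c(P1 = 100L, P2 = 200L))
  # 0.04 and 0.01 normalized
  expect_equal(compute_nsaf(cm2, "a"), c(P1 = 0.8, P2 = 0.2))

  n <- 8L
  cmn <- count_matrix(matrix(rep(5L, 2 * n), ncol = 2,
                             dimnames = list(sprintf("P%d", 1:n),
                                             c("a", "b"))),
                      lengths = setNames(rep(300L, n), sprintf("P%d", 1:n)))
  expect_equal(unname(compute_nsaf(cmn, "b")), rep(1 / n, n))
})

test_that("NSAF handles zero counts and validates its inputs", {
  cm <- count_matrix(matrix(c(4L, 0L, 0L, 6L), ncol = 2,
                            dimnames = list(c("P1", "P2"), c("a", "b"))),
                     lengths = c(P1 = 100L, P2 = 100L))
  expect_equal(compute_nsaf(cm, "a"), c(P1 = 1, P2 = 0))
  cm_missing <- count_matrix(cm$counts, lengths = c(P1 = 100L))
  expect_error(compute_nsaf(cm_missing, "a"), "P2")
  cm_zero <- count_matrix(matrix(c(1L, 0L, 0L, 0L), ncol = 2,
                                 dimnames = list(c("P1", "P2"),
                                                 c("a", "b"))),
                          lengths = c(P1 = 100L, P2 = 100L))
  expect_error(compute_nsaf(cm_zero, "b"), "all spectral counts are zero")
})

test_that("quantify produces one classified row per protein", {
  cm <- count_matrix(matrix(c(5L, 9L, 5L, 9L), ncol = 2,
                            dimnames = list(c("P1", "P2"), c("a", "b"))),
                     lengths = c(P1 = 100L, P2 = 200L))
  q <- quantify(cm)
  expect_equal(nrow(q), 2L)
  expect_equal(q$rsc, c(0, 0))
  expect_equal(q$de_class, rep("unchanged", 2))
  dc <- attr(q, "de_counts")
  expect_equal(sum(dc), nrow(q))
})

test_that("a planted strong fold change is classified up", {
  # one 8-fold protein in a deep experiment; background symmetric
  acc <- sprintf("P%02d", 1:11)
  counts <- matrix(rep(c(1000L, 1000L), each = 10), ncol = 2,
                   dimnames = list(acc[1:10], c("normal", "stz")))
  counts <- rbind(counts, P11 = c(10L, 80L))
  cm <- count_matrix(counts, c("normal", "stz"),
                     lengths = setNames(rep(200L, 11), rownames(counts)))
  q <- quantify(cm)
  row <- q[q$accession == "P11", ]
  expect_equal(row$de_class, "up")
  # equals the scalar oracle with this matrix's totals
  expect_equal(row$rsc,
               rsc_oracle(80, 10, sum(counts[, 2]), sum(counts[, 1])),
               tolerance = 1e-12)
})

test_that("swapping conditions negates Rsc for every protein", {
  set.seed(7)
  for (i in 1:20) {
    cm <- random_count_matrix(n = 30)
    swapped <- count_matrix(cm$counts[, 2:1],
                            conditions = rev(cm$conditions),
                            lengths = cm$lengths)
    q1 <- quantify(cm, sort = FALSE)
    q2 <- quantify(swapped, sort = FALSE)
    expect_equal(q1$rsc, -q2$rsc, tolerance = 1e-12)
  }
})

test_that("Rsc approaches log2 of the count ratio for deep experiments", {
  # ratio 2 at n_n = 500 against totals of 1e6: the sampling-depth term
  # is negligible and Rsc operationalizes a two-fold change
  rsc <- compute_rsc(n_s = 1000, n_n = 500, t_s = 1e6, t_n = 1e6)
  expect_lt(abs(rsc - log2(2)), 0.05)
})

test_that("vectorized quantify agrees with scalar evaluation", {
  set.seed(21)
  for (i in 1:50) {
    cm <- random_count_matrix(n = 15)
    q <- quantify(cm, sort = FALSE)
    t_n <- cm$totals[[1]]
    t_s <- cm$totals[[2]]
    scalar <- vapply(seq_len(nrow(cm$counts)), function(j)
      compute_rsc(cm$counts[j, 2], cm$counts[j, 1], t_s, t_n),
      numeric(1))
    expect_equal(q$rsc, scalar, tolerance = 1e-12)
    expect_equal(sum(q[[paste0("nsaf_", cm$conditions[1])]]), 1,
                 tolerance = 1e-12)
    expect_equal(sum(q[[paste0("nsaf_", cm$conditions[2])]]), 1,
                 tolerance = 1e-12)
  }
})

test_that("quant tables sort by decreasing Rsc with accession tie-break", {
  cm <- count_matrix(matrix(c(5L, 1L, 8L, 5L, 1L, 8L), ncol = 2,
                            dimnames = list(c("PB", "PC", "PA"),
                                            c("a", "b"))),
                     lengths = c(PB = 100L, PC = 100L, PA = 100L))
  q <- quantify(cm)
  expect_equal(q$rsc, sort(q$rsc, decreasing = TRUE))
  # all rsc equal 0 here, so order falls back to accession
  expect_equal(q$accession, c("PA", "PB", "PC"))
})
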