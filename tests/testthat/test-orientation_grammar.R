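test_that("pattern enumeration reproduces the k-plet combinatorics", {
  expect_equal(nrow(enumerate_patterns(1)), 2)
  expect_setequal(enumerate_patterns(1)$pattern, c(">", "<"))

  e3 <- enumerate_patterns(3)
  expect_equal(nrow(e3), 8)
  expect_equal(as.vector(table(e3$class)), c(2, 2, 2, 2))

  e4 <- enumerate_patterns(4)
  expect_equal(nrow(e4), 16)
  expect_equal(as.vector(table(e4$class)[c("Same", "Conv", "Div", "ConvDiv")]),
               c(2, 3, 3, 8))
  expect_error(enumerate_patterns(5), "1..4")
})

test_that("classification matches the tabulated classes for every pattern", {
  pats <- names(ORACLE_CLASSES)
  expect_equal(as.character(classify_pattern(pats)),
               unname(ORACLE_CLASSES))
  expect_error(classify_pattern(">x<"), "only '>' and '<'")
  expect_error(classify_pattern(">"), "length >= 2")
})

test_that("theoretical class proportions come out of the brute force", {
  expect_equal(theoretical_class_proportions(2),
               c(Same = 0.5, Conv = 0.25, Div = 0.25))
  expect_equal(theoretical_class_proportions(3),
               c(Same = 0.25, Conv = 0.25, Div = 0.25, ConvDiv = 0.25))
  expect_equal(theoretical_class_proportions(4),
               c(Same = 0.125, Conv = 0.1875, Div = 0.1875, ConvDiv = 0.5))
})

test_that("k-plet extraction is a stride-1 sliding window", {
  s <- sites_from_orientations("><><")
  k2 <- extract_kplets(s, 2)
  expect_equal(k2$pattern, c("><", "<>", "><"))
  expect_equal(nrow(extract_kplets(s, 3)), 4 - 3 + 1)
  # spans from midpoints
  s2 <- sites_from_orientations(">><", midpoints = list(c(0, 10000, 30000)))
  expect_equal(extract_kplets(s2, 3)$span_bp, 30000)
  expect_warning(out <- extract_kplets(sites_from_orientations("><"), 3),
                 "no sequence")
  expect_equal(nrow(out), 0)
})

test_that("triplet classes annotate interior sites only", {
  s <- assign_triplet_classes(sites_from_orientations("><>"))
  expect_equal(as.character(s$triplet_class), c(NA, "ConvDiv", NA))
  s2 <- assign_triplet_classes(sites_from_orientations("><"))
  expect_true(all(is.na(s2$triplet_class)))
  # arm ends of a multi-arm table are unassigned independently
  s3 <- assign_triplet_classes(sites_from_orientations(">>><", "<<>>"))
  expect_equal(sum(is.na(s3$triplet_class)), 4)
})

test_that("class counting agrees with the substring-lookup oracle", {
  cc <- count_classes(sites_from_orientations(">>>>"), 2)
  expect_equal(unname(cc$counts["Same"]), 3)
  expect_equal(cc$total, 3)

  set.seed(42)
  for (rep in 1:25) {
    n_arms <- sample(1:3, 1)
    oris <- replicate(n_arms, paste(sample(c(">", "<"), sample(3:40, 1),
                                           replace = TRUE), collapse = ""))
    s <- sites_from_orientations(as.list(oris))
    for (K in 2:4) {
      want <- Reduce(`+`, lapply(oris, function(o)
        oracle_count_classes(strsplit(o, "")[[1]], K)))
      got <- count_classes(s, K)
      expect_equal(got$counts, want)
      expect_equal(got$total,
                   sum(pmax(0, nchar(oris) - K + 1)))
    }
  }
})

test_that("Pearson chi-square test against fixed proportions", {
  # observed exactly at expectation
  r <- class_chisq_test(c(Same = 25, Conv = 25, Div = 25, ConvDiv = 25),
                        theoretical_class_proportions(3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # hand-computed: (10-20)^2/20 + (30-20)^2/20 = 10
  r2 <- class_chisq_test(c(a = 10, b = 30), c(a = 0.5, b = 0.5))
  expect_equal(r2$statistic, 10)
  expect_equal(r2$df, 1)
  expect_error(class_chisq_test(c(a = 1, b = 1), c(a = 1, b = 0)),
               "zero expected")
})

test_that("genome-wide tri-plet counts give the reported significance", {
  counts <- c(Same = 16017, Conv = 15305, Div = 15304, ConvDiv = 14369)
  r <- class_chisq_test(counts, theoretical_class_proportions(3))
  expect_equal(r$p_value, 2.34e-19, tolerance = 0.005)
})

test_that("randomization test is calibrated", {
  # observed counts exactly at the theoretical proportions -> distance 0
  s <- sites_from_orientations(">>><<<", "><><")
  # choose a sequence whose tri-plet classes are exactly uniform: use the
  # distance of a constructed count vector directly instead
  rt <- randomization_test(sites_from_orientations(
    paste(rep(c(">", "<"), each = 2), collapse = "")), 2,
    n_reps = 200, seed = 1)
  expect_true(rt$p_raw >= 0 && rt$p_raw <= 1)
  expect_length(rt$null_distances, 200)

  # strong planted orientation bias is detected
  set.seed(9)
  ori <- paste(sample(c(">", "<"), 20000, TRUE, prob = c(0.65, 0.35)),
               collapse = "")
  rt2 <- randomization_test(sites_from_orientations(ori), 3,
                            n_reps = 200, seed = 2)
  expect_equal(rt2$p_raw, 0)
  expect_lt(rt2$p_adjusted, 0.01)
  expect_error(randomization_test(s, 2, n_reps = 0), "n_reps")
})

test_that("per-sequence Conv/Div skews obey the alternation bounds", {
  set.seed(7)
  for (rep in 1:200) {
    o <- sample(c(">", "<"), sample(2:60, 1), replace = TRUE)
    c2 <- oracle_count_classes(o, 2)
    c3 <- oracle_count_classes(o, 3)
    expect_lte(abs(c2["Conv"] - c2["Div"]), 1)
    expect_lte(abs(c3["Conv"] - c3["Div"]), 2)
  }
})

test_that("maximal genome-wide skews over 42 arms are 42/84/126", {
  for (K in 2:4) {
    r <- max_class_skew(K, n_arms = 42, max_len = 8)
    expect_equal(r$per_sequence_bound, K - 1)
    expect_equal(r$genome_wide_bound, 42 * (K - 1))
    att <- oracle_count_classes(strsplit(r$attaining_sequence, "")[[1]], K)
    expect_equal(abs(att["Conv"] - att["Div"]), c(Conv = K - 1))
  }
})
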