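test_that("rule induction maps each count to its majority outcome", {
  counts <- matrix(c(2, 2, 2, 2, 1, 1), ncol = 1,
                   dimnames = list(NULL, "osc_1"))
  rule <- induce_rule(counts, labels = c(1, 1, 1, 0, 0, 0))
  expect_identical(unname(rule$class_of_count[["2"]]), 1L)
  expect_identical(unname(rule$class_of_count[["1"]]), 0L)
  # ties go to nonresponsive
  tie <- induce_rule(matrix(rep(3L, 4), ncol = 1), labels = c(0, 1, 0, 1))
  expect_identical(unname(tie$class_of_count[["3"]]), 0L)
  # the output oscillator minimizes training errors, lowest index on ties
  counts2 <- cbind(osc_1 = c(1L, 1L, 2L, 2L), osc_2 = c(1L, 2L, 1L, 2L))
  rule2 <- induce_rule(counts2, labels = c(0, 0, 1, 1))
  expect_identical(rule2$output_oscillator, 1L)
  expect_equal(attr(rule2, "training_accuracy"), 1)
})

test_that("induced rules attain the exhaustive-best training accuracy", {
  set.seed(4012)
  for (i in 1:100) {
    n <- sample(10:30, 1)
    counts <- cbind(osc_1 = sample(0:3, n, replace = TRUE),
                    osc_2 = sample(0:4, n, replace = TRUE))
    labels <- sample(0:1, n, replace = TRUE)
    rule <- induce_rule(counts, labels)
    acc <- evaluate_rule(rule, counts, labels)$accuracy
    expect_equal(acc, brute_force_best_accuracy(counts, labels))
    # never worse than the constant classifier on training data
    expect_gte(acc, max(mean(labels == 0), mean(labels == 1)))
  }
})

test_that("evaluation reports accuracy and outcome-stratified confusion", {
  all_one <- maxima_rule(responsive = 0:11, nonresponsive = integer(),
                         output_oscillator = 1)
  counts <- matrix(sample(0:5, 20, replace = TRUE), ncol = 1)
  ev <- evaluate_rule(all_one, counts, labels = rep(1L, 20))
  expect_equal(ev$accuracy, 1)
  ev0 <- evaluate_rule(all_one, counts, labels = rep(0L, 20))
  expect_equal(ev0$accuracy, 0)
  # confusion cells partition the record set by true class
  set.seed(99)
  labels <- sample(0:1, 50, replace = TRUE)
  counts <- matrix(sample(0:3, 50, replace = TRUE), ncol = 1)
  rule <- induce_rule(counts, labels)
  ev2 <- evaluate_rule(rule, counts, labels)
  expect_equal(ev2$correct_nonresponsive + ev2$wrong_nonresponsive,
               sum(labels == 0))
  expect_equal(ev2$correct_responsive + ev2$wrong_responsive,
               sum(labels == 1))
  expect_equal(ev2$accuracy,
               (ev2$correct_nonresponsive + ev2$correct_responsive) / 50)
})

test_that("unseen counts fall back as configured", {
  rule <- maxima_rule(responsive = c(1, 3), nonresponsive = c(0, 2),
                      output_oscillator = 1, fallback_class = 0L)
  expect_identical(predict(rule, c(1, 7, 0, 99)), c(1L, 0L, 0L, 0L))
  # induced rules fall back to the global training majority
  rule2 <- induce_rule(matrix(c(1L, 1L, 2L), ncol = 1),
                       labels = c(1, 1, 0))
  expect_identical(rule2$fallback_class, 1L)
  expect_identical(predict(rule2, 55), 1L)
})

test_that("a count claimed by both classes resolves to nonresponsive", {
  expect_warning(
    rule <- maxima_rule(responsive = c(2, 3), nonresponsive = 3:8,
                        output_oscillator = 1),
    "both responsive and nonresponsive")
  expect_identical(unname(rule$class_of_count[["3"]]), 0L)
})

test_that("histogram bins are equal-width with the documented edges", {
  # the RPS7 range splits into bins of width 1102.482
  vals <- c(1142.48, 12167.3, seq(2000, 12000, length.out = 20))
  labels <- rep_len(0:1, length(vals))
  rule <- fit_histogram(vals, labels)
  expect_length(rule$edges, 11)
  expect_equal(rule$edges[1], 1142.48)
  expect_equal(rule$edges[2], 2244.962, tolerance = 1e-6)
  expect_equal(rule$edges[11], 12167.3)
  expect_equal(unique(round(diff(rule$edges), 6)), 1102.482)
  # every training value falls in exactly one bin
  bins <- findInterval(vals, rule$edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
  expect_true(all(bins >= 1 & bins <= 10))
  # the top edge is inclusive
  expect_identical(length(predict(rule, 12167.3)), 1L)
})

test_that("histogram classifier separates separable data and rejects degenerate input", {
  vals <- c(rnorm(50, 10, 0.5), rnorm(50, 30, 0.5))
  labels <- rep(0:1, each = 50)
  rule <- fit_histogram(vals, labels)
  expect_equal(attr(rule, "training_accuracy"), 1)
  expect_equal(evaluate_rule(rule, vals, labels)$accuracy, 1)
  expect_error(fit_histogram(rep(5, 10), rep_len(0:1, 10)), "degenerate")
})

test_that("the published readout rules load as printed", {
  rules <- suppressWarnings(published_rules())
  expect_length(rules, 15)
  r13 <- rules[["gene_13"]]
  expect_identical(sort(as.integer(names(r13$class_of_count)[r13$class_of_count == 1L])),
                   c(1L, 3L, 4L, 5L, 9L, 10L))
  expect_identical(sort(as.integer(names(r13$class_of_count)[r13$class_of_count == 0L])),
                   c(0L, 2L, 6L, 7L, 8L))
  expect_identical(r13$output_oscillator, 3L)
  expect_identical(r13$fallback_class, 0L)
  # the gene-12 file stores the printed count conflict; loading resolves it
  expect_warning(read_rule_json(system.file("extdata", "rules", "table4",
                                            "gene_12.json",
                                            package = "concilium")),
                 "both responsive and nonresponsive")
})

test_that("rules round-trip through JSON and tidy into tables", {
  rule <- maxima_rule(responsive = c(1, 4), nonresponsive = c(0, 2, 3),
                      output_oscillator = 2, gene = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_rule_json(rule, path)
  back <- read_rule_json(path)
  expect_equal(back, rule)
  td <- generics::tidy(rule)
  expect_identical(td$count, c(0L, 1L, 2L, 3L, 4L))
  expect_identical(td$class, c(0L, 1L, 0L, 0L, 1L))
  gl <- generics::glance(rule)
  expect_identical(gl$output_oscillator, 2L)
})

test_that("constant baselines score the class priors", {
  labels <- c(rep(0L, 126), rep(1L, 113))
  bl <- constant_baseline(labels)
  expect_equal(bl$accuracy[bl$rule == "always_responsive"], 113 / 239)
  expect_equal(bl$accuracy[bl$rule == "always_nonresponsive"], 126 / 239)
})
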