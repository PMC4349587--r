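post_vec <- function(...) {
  v <- c(...)
  stats::setNames(v, c("P1", "P2", "F1", "F2", "BC1", "BC2"))
}

test_that("the composite decision rules fire in the documented order", {
  flat <- post_vec(1, 1, 1, 1, 1, 1) / 6
  # q1 in the pure bands wins regardless of the six-class posterior
  expect_equal(classify_individual(0.95, post_vec(0, 0, 1, 0, 0, 0))$final, "LJ")
  expect_equal(classify_individual(0.05, flat)$final, "LS")
  expect_equal(classify_individual(0.9, flat)$final, "LJ")   # inclusive edge
  expect_equal(classify_individual(0.1, flat)$final, "LS")
  # hybrid with a confident six-class winner
  rec <- classify_individual(0.5, post_vec(0.05, 0.05, 0.8, 0.04, 0.03, 0.03))
  expect_equal(rec$final, "F1")
  expect_equal(rec$rule, "six_class_posterior")
  expect_false(rec$conflict)
  # hybrid signal vs parental six-class winner: recorded with conflict flag
  confl <- classify_individual(0.5, post_vec(0.9, 0.02, 0.02, 0.02, 0.02, 0.02))
  expect_equal(confl$final, "LJ")
  expect_true(confl$conflict)
  # fallback bands for unassignable hybrids
  expect_equal(classify_individual(0.8, post_vec(0.4, 0.12, 0.12, 0.12, 0.12, 0.12) / 1)$final, "BCJ")
  expect_equal(classify_individual(0.2, flat)$final, "BCS")
  expect_equal(classify_individual(0.5, flat)$final, "Fn")
  expect_equal(classify_individual(0.3, flat)$final, "Fn")   # closed Fn band
  expect_equal(classify_individual(0.7, flat)$final, "Fn")
  expect_error(classify_individual(1.2, flat), "q1")
})

test_that("every (q1, posterior) pair yields exactly one category", {
  set.seed(4)
  cats <- hz_categories()
  for (q1 in seq(0, 1, by = 0.05)) {
    for (r in 1:5) {
      p <- post_vec(runif_simplex(6))
      rec <- classify_individual(q1, p)
      expect_length(rec$final, 1L)
      expect_true(rec$final %in% cats)
      expect_true(nzchar(rec$rule))
    }
  }
})

test_that("population composition reproduces the printed H9 arithmetic", {
  # truth-level records: an H9-like mixed population of 26 with 10 F1,
  # 5 F2, 3 Fn -> intermediate = 18, parental = 8
  finals <- c("LJ", "LS", rep("F1", 10), rep("F2", 5), rep("Fn", 3), rep("BC1J", 6))
  records <- data.frame(individual = seq_along(finals), final = finals,
                        stringsAsFactors = FALSE)
  q1 <- c(0.95, 0.03, runif(10, 0.45, 0.55), runif(5, 0.4, 0.6),
          runif(3, 0.35, 0.65), runif(6, 0.72, 0.88))
  comp <- population_composition(records, q1, rep("H9", 26), seed = 1)
  expect_equal(unname(comp$counts["H9", "Total"]), 26L)
  expect_equal(comp$grouping$intermediate, 18)
  expect_equal(comp$grouping$parental, 8)
  expect_equal(comp$grouping$parental + comp$grouping$intermediate,
               comp$grouping$total)
  # all-parental population has zero intermediates
  rec2 <- data.frame(individual = 1:20, final = rep(c("LJ", "LS"), 10),
                     stringsAsFactors = FALSE)
  comp2 <- population_composition(rec2, c(runif(10, 0.92, 1), runif(10, 0, 0.08)),
                                  rep("P", 20), seed = 1)
  expect_equal(comp2$grouping$intermediate, 0)
})

test_that("efficiency, accuracy and performance follow their definitions", {
  # 50 true F1: 40 assigned F1 correctly, 5 non-F1 wrongly assigned F1
  truth <- c(rep("F1", 50), rep("LJ", 5))
  assigned <- c(rep("F1", 40), rep("unassigned", 10), rep("F1", 5))
  rep1 <- evaluate_performance(truth, assigned)
  m <- rep1$metrics[rep1$metrics$class == "F1", ]
  expect_equal(m$efficiency, 0.8)
  expect_equal(m$accuracy, 40 / 45)
  expect_equal(m$performance, 0.8 * 40 / 45)
  # perfect assignment
  perf <- evaluate_performance(c("A", "B"), c("A", "B"))
  expect_true(all(perf$metrics$efficiency == 1 & perf$metrics$accuracy == 1 &
                  perf$metrics$performance == 1))
  # performance <= min(efficiency, accuracy); undefined accuracy stays NA
  set.seed(6)
  classes <- c("LJ", "LS", "F1", "F2")
  truth2 <- sample(classes, 200, replace = TRUE)
  assigned2 <- ifelse(runif(200) < 0.3, "unassigned",
                      sample(c(classes[1:3]), 200, replace = TRUE))
  rep2 <- evaluate_performance(truth2, assigned2)
  ok <- !is.na(rep2$metrics$accuracy)
  expect_true(all(rep2$metrics$performance[ok] <=
                  pmin(rep2$metrics$efficiency[ok], rep2$metrics$accuracy[ok]) + 1e-12))
  expect_true(is.na(rep2$metrics$accuracy[rep2$metrics$class == "F2"]))
  expect_true(is.na(rep2$metrics$performance[rep2$metrics$class == "F2"]))
  # confusion rows sum to the class sample sizes
  expect_equal(unname(rowSums(rep2$confusion)),
               unname(as.vector(table(factor(truth2, levels = rep2$metrics$class)))))
  expect_error(evaluate_performance(character(0), character(0)), "empty")
})

test_that("classify_all aligns records with inputs", {
  post <- rbind(post_vec(0.9, 0.02, 0.02, 0.02, 0.02, 0.02),
                post_vec(0.02, 0.9, 0.02, 0.02, 0.02, 0.02),
                post_vec(0.05, 0.05, 0.8, 0.04, 0.03, 0.03))
  rownames(post) <- c("a", "b", "c")
  recs <- classify_all(c(0.97, 0.02, 0.5), post)
  expect_equal(recs$final, c("LJ", "LS", "F1"))
  expect_equal(recs$individual, c("a", "b", "c"))
  expect_error(classify_all(c(0.5), post), "disagree")
})
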