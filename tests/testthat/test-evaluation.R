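test_that("stratified splitting honors the per-class rounding rule", {
  labels <- rep(c("A", "B"), each = 10)
  sp <- stratified_split(labels, 0.2, seed = 1)
  expect_equal(sum(labels[sp$test] == "A"), 2)
  expect_equal(sum(labels[sp$test] == "B"), 2)

  lab5 <- c(rep("C", 2), rep("D", 5))
  sp5 <- stratified_split(lab5, 0.2, seed = 1)
  expect_equal(sum(lab5[sp5$test] == "D"), 1)  # max(1, round(1.0)) = 1

  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_error(stratified_split(c("A", "A", "B"), 0.2, 1), "at least 2")
})

test_that("split proportions follow max(1, round(f * n)) for all class sizes", {
  for (n in 2:50) {
    labels <- c(rep("x", n), rep("y", 60))
    sp <- stratified_split(labels, 0.2, seed = n)
    expect_equal(sum(labels[sp$test] == "x"),
                 min(n - 1, max(1, round(0.2 * n))), info = n)
  }
})

test_that("accuracy is plain correct-over-total and permutation-invariant", {
  expect_equal(accuracy(c("a", "b", "c", "d"), c("a", "b", "c", "x")), 0.75)
  expect_equal(accuracy(letters[1:5], letters[1:5]), 1.0)
  expect_equal(accuracy(rep("a", 4), rep("b", 4)), 0.0)
  expect_error(accuracy(character(0), character(0)), "empty")

  set.seed(3)
  p <- sample(letters[1:3], 20, replace = TRUE)
  a <- sample(letters[1:3], 20, replace = TRUE)
  perm <- sample(20)
  expect_equal(accuracy(p[perm], a[perm]), accuracy(p, a))
})

test_that("confusion matrices tally, conserve and normalize by row", {
  cm <- confusion(c("A", "B", "B"), c("A", "A", "B"), classes = c("A", "B"))
  expect_equal(unname(cm$counts), rbind(c(1L, 1L), c(0L, 1L)))
  expect_equal(sum(cm$counts), 3)
  expect_equal(unname(rowSums(cm$normalized)), c(1, 1))

  perfect <- confusion(letters[1:4], letters[1:4])
  expect_equal(unname(diag(perfect$normalized)), rep(1, 4))
  expect_equal(sum(perfect$counts) - sum(diag(perfect$counts)), 0)

  expect_error(confusion("Z", "A", classes = c("A", "B")), "outside")
})

test_that("roc curves reproduce closed-form cases", {
  r1 <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r1$summary, 1.0)
  r2 <- roc_curve(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(r2$summary, 0.5)
  r3 <- roc_curve(c(0.9, 0.8, 0.3), c(1, 0, 1))
  expect_equal(r3$summary, 0.5)
  expect_true(all(diff(r3$points$x) >= 0))
  expect_error(roc_curve(c(0.1, 0.2), c(TRUE, TRUE)), "negative")
})

test_that("trapezoidal auc equals the pair-counting statistic", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    member <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))  # induce ties
    expect_equal(roc_curve(scores, member)$summary, auc_pairs(scores, member),
                 tolerance = 1e-9)
  }
})

test_that("pr curves reproduce closed-form cases", {
  p1 <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(p1$summary, 1.0)
  # single positive ranked last of three distinct scores
  p2 <- pr_curve(c(0.9, 0.5, 0.2), c(FALSE, FALSE, TRUE))
  expect_equal(p2$summary, 1 / 3)
  expect_true(all(p2$points$x >= 0 & p2$points$x <= 1))
  expect_true(all(p2$points$y >= 0 & p2$points$y <= 1))
  expect_error(pr_curve(c(0.4, 0.3), c(FALSE, FALSE)), "positive")
})

test_that("a full report is internally consistent and hits the ceiling on separable data", {
  cl <- list(embeddings = rbind(matrix(rnorm(40, sd = 0.05), 10),
                                matrix(rnorm(40, 3, sd = 0.05), 10),
                                matrix(rnorm(40, -3, sd = 0.05), 10)),
             labels = rep(c("a", "b", "c"), each = 10))
  fc <- fit_classifier(classifier_spec("knn", k = 3), cl$embeddings, cl$labels)
  rep_ <- full_report(fc, cl$embeddings, cl$labels)
  expect_equal(rep_$accuracy,
               sum(diag(rep_$confusion$counts)) / sum(rep_$confusion$counts),
               tolerance = 1e-12)
  expect_length(rep_$per_class_curves, 3)
  for (cv in rep_$per_class_curves) {
    expect_equal(cv$roc$summary, 1.0)
    expect_equal(cv$pr$summary, 1.0)
  }
  expect_equal(rep_$accuracy, 1.0)

  dir <- withr::local_tempdir()
  write_report_json(rep_, file.path(dir, "r.json"))
  back <- jsonlite::read_json(file.path(dir, "r.json"))
  expect_equal(back$accuracy, 1.0)
})
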