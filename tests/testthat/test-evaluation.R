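test_that("negative sampling honors the ratio, exclusion, and the pool cap", {
  pos <- tibble::tibble(drug = c("d1", "d2", "d3"),
                        protein = c("p1", "p2", "p3"))
  drugs <- sprintf("d%d", 1:20); prots <- sprintf("p%d", 1:20)
  neg <- sample_negatives(pos, drugs, prots, ratio = 10, seed = 1)
  expect_equal(nrow(neg), 30)
  expect_true(all(neg$label == 0))
  keys <- function(x) paste(x$drug, x$protein)
  expect_length(intersect(keys(neg), keys(pos)), 0)
  expect_false(any(duplicated(keys(neg))))
  expect_identical(sample_negatives(pos, drugs, prots, 10, seed = 1), neg)

  # 2x2 universe with 2 positives: only 2 negatives exist
  pos2 <- tibble::tibble(drug = c("a", "b"), protein = c("x", "y"))
  expect_warning(
    neg2 <- sample_negatives(pos2, c("a", "b"), c("x", "y"), ratio = 10,
                             seed = 2),
    "pool exhausted")
  expect_equal(nrow(neg2), 2)
  expect_setequal(keys(neg2), c("a y", "b x"))

  full <- tidyr::expand_grid(drug = "a", protein = "x")
  expect_error(sample_negatives(full, "a", "x", 1, seed = 1, exclude = full),
               "empty negative pool")
})

test_that("fold plans satisfy the scenario contracts", {
  b <- tiny_bench(seed = 1)
  keys <- function(x) paste(x$drug, x$protein)

  warm <- make_folds(b$positives, "warm", k = 5, ratio = 2, seed = 1)
  test_pos <- lapply(warm$folds, function(f) keys(f$test[f$test$label == 1, ]))
  # pairwise disjoint and jointly exhaustive
  expect_equal(sort(unlist(test_pos)), sort(keys(b$positives)))
  expect_false(any(duplicated(unlist(test_pos))))

  cd <- make_folds(b$positives, "cold_drug", k = 4, ratio = 2, seed = 2)
  for (f in cd$folds) {
    expect_length(intersect(unique(f$train$drug), unique(f$test$drug)), 0)
  }
  cp <- make_folds(b$positives, "cold_protein", k = 4, ratio = 2, seed = 3)
  for (f in cp$folds) {
    expect_length(intersect(unique(f$train$protein), unique(f$test$protein)),
                  0)
  }
  # negatives never collide with known positives, anywhere
  for (plan in list(warm, cd, cp)) {
    for (f in plan$folds) {
      both <- dplyr::bind_rows(f$train, f$test)
      expect_length(intersect(keys(both[both$label == 0, ]),
                              keys(b$positives)), 0)
    }
  }
})

test_that("ten drugs in ten cold folds test exactly one drug each", {
  set.seed(4)
  pos <- tibble::tibble(drug = rep(sprintf("d%02d", 1:10), each = 2),
                        protein = sample(sprintf("p%02d", 1:8), 20, TRUE)) |>
    dplyr::distinct()
  plan <- make_folds(pos, "cold_drug", k = 10, ratio = 1, seed = 4,
                     proteins = sprintf("p%02d", 1:8))
  tested <- vapply(plan$folds, function(f)
    length(unique(f$test$drug[f$test$label == 1])), 0L)
  expect_equal(tested, rep(1L, 10))
})

test_that("fold construction rejects impossible configurations", {
  pos <- tibble::tibble(drug = c("d1", "d2"), protein = c("p1", "p2"))
  expect_error(make_folds(pos, "cold_drug", k = 5, ratio = 1, seed = 1),
               "2 distinct drugs")
})

test_that("AUROC: closed cases and the exhaustive pairwise oracle", {
  expect_equal(auroc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  expect_equal(auroc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)), 0.75)
  expect_error(auroc(c(1, 1), c(0.1, 0.2)), "both classes")

  set.seed(12)
  for (rep in 1:50) {
    n <- sample(5:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), sample(1:3, 1))  # force some ties
    expect_equal(auroc(labels, scores), oracle_auroc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUPR: closed cases and the threshold-recomputation oracle", {
  expect_equal(aupr(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1.0)
  # single positive ranked last among m items
  m <- 5
  expect_equal(aupr(c(rep(0, m - 1), 1), seq(m, 1)), 1 / m)
  expect_error(aupr(c(0, 0), c(0.1, 0.2)), "no positive")

  set.seed(13)
  for (rep in 1:50) {
    n <- sample(5:50, 1)
    labels <- c(1, rbinom(n - 1, 1, 0.3))
    scores <- round(runif(n), sample(1:3, 1))
    expect_equal(aupr(labels, scores), oracle_aupr(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("AUPR of random scores approaches the positive prevalence", {
  set.seed(14)
  vals <- vapply(1:20, function(i) {
    labels <- rbinom(1e4, 1, 1 / 11)
    aupr(labels, runif(1e4))
  }, 0)
  expect_equal(mean(vals), 1 / 11, tolerance = 0.01)
})

test_that("cross-validation plumbing: oracle scorer, shape, determinism", {
  b <- tiny_bench(seed = 2)
  oracle <- function(fold, kg, config) fold$test$label
  ev <- cross_validate(b$positives, b$kg, dti_config(seed = 2),
                       scenario = "warm", k = 4, ratio = 2, scorer = oracle)
  expect_equal(nrow(ev$metrics), 4)
  expect_equal(ev$metrics$auroc, rep(1, 4))
  expect_equal(ev$metrics$aupr, rep(1, 4))
  expect_true(all(ev$metrics$auroc >= 0 & ev$metrics$auroc <= 1))

  ev2 <- cross_validate(b$positives, b$kg, dti_config(seed = 2),
                        scenario = "warm", k = 4, ratio = 2, scorer = oracle)
  expect_identical(tidy(ev), tidy(ev2))

  # summary is consistent with the per-fold table
  noisy <- function(fold, kg, config) {
    s <- seed_place <- sum(utf8ToInt(paste(fold$test$drug, collapse = "")))
    set.seed(s)
    fold$test$label * 0.5 + runif(nrow(fold$test))
  }
  ev3 <- cross_validate(b$positives, b$kg, dti_config(seed = 3),
                        scenario = "warm", k = 4, ratio = 2, scorer = noisy)
  s <- ev3$summary[ev3$summary$metric == "auroc", ]
  expect_equal(s$median, stats::median(ev3$metrics$auroc))
  expect_equal(s$min, min(ev3$metrics$auroc))
  expect_equal(s$max, max(ev3$metrics$auroc))
  g <- glance(ev3)
  expect_equal(g$median_aupr, stats::median(ev3$metrics$aupr))
})

test_that("fold plans and metric files round-trip through disk", {
  b <- tiny_bench(seed = 3)
  plan <- make_folds(b$positives, "cold_drug", k = 3, ratio = 2, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_fold_plan(plan, path)
  back <- read_fold_plan(path)
  expect_equal(back$scenario, plan$scenario)
  for (i in 1:3) {
    expect_equal(back$folds[[i]]$train, plan$folds[[i]]$train)
    expect_equal(back$folds[[i]]$test, plan$folds[[i]]$test)
  }

  ev <- cross_validate(b$positives, b$kg, dti_config(seed = 2),
                       scenario = "warm", k = 3, ratio = 2,
                       scorer = function(fold, kg, config) fold$test$label)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_eval(ev, tsv, js)
  tab <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$auroc, ev$metrics$auroc)
  expect_true(jsonlite::validate(paste(readLines(js), collapse = "")))
})
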