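test_that("min-max scaling maps features into [-1, 1] with stored parameters", {
  ft <- toy_feature_table(data.frame(f1 = c(0, 5, 10), f2 = c(3, 3, 3)))
  sc <- scale_features(ft)
  expect_equal(sc$f1, c(-1, 0, 1))
  expect_equal(sc$f2, c(0, 0, 0))          # constant-feature convention
  p <- attr(sc, "scaling")
  expect_equal(p$min[p$feature == "f1"], 0)
  expect_equal(p$max[p$feature == "f1"], 10)
  # idempotent on an already-scaled column
  sc2 <- scale_features(sc)
  expect_equal(sc2$f1, sc$f1)
  expect_equal(sc2$f2, sc$f2)
})

test_that("LOOCV separates well-separated classes perfectly for SVM and LDA", {
  ft <- separable_table(n_per = 10)
  scd <- scale_features(ft)
  # nearest-centroid oracle: every held-out point is nearer its own class
  x <- scd$f1
  y <- ft$habit
  oracle <- vapply(seq_along(x), function(i) {
    mus <- tapply(x[-i], y[-i], mean)
    names(mus)[which.min(abs(mus - x[i]))]
  }, character(1))
  expect_equal(oracle, y)                   # the geometry is separable
  for (fam in c("svm_rbf", "lda")) {
    spec <- if (fam == "svm_rbf") fixed_svm_spec() else
      classifier_spec("lda")
    ev <- loocv_evaluate(scd, "f1", spec, task = "habit")
    expect_equal(ev$overall, 100)
    expect_equal(as.character(ev$predicted), oracle)
    expect_equal(unname(colSums(ev$confusion)),
                 unname(table(y)[colnames(ev$confusion)]),
                 ignore_attr = TRUE)
  }
})

test_that("a singleton class has producer accuracy zero under LOOCV", {
  set.seed(104)
  ft <- toy_feature_table(
    data.frame(f1 = c(rnorm(8, 0), rnorm(8, 6), 3)),
    species = c(rep("a", 8), rep("b", 8), "c"))
  ev <- loocv_evaluate(scale_features(ft), "f1", fixed_svm_spec(),
                       task = "species")
  expect_equal(unname(ev$producer["c"]), 0)
  ev2 <- loocv_evaluate(scale_features(ft), "f1", classifier_spec("lda"),
                        task = "species")
  expect_equal(unname(ev2$producer["c"]), 0)
})

test_that("LOOCV confusion columns sum to class counts; overall is the weighted producer mean", {
  set.seed(105)
  ft <- toy_feature_table(
    data.frame(f1 = rnorm(30), f2 = rnorm(30)),
    species = sample(c("a", "b", "c"), 30, replace = TRUE, prob = c(.5, .3, .2)))
  ev <- loocv_evaluate(scale_features(ft), c("f1", "f2"), fixed_svm_spec(),
                       task = "species")
  counts <- table(ft$species)
  expect_equal(unname(colSums(ev$confusion)),
               unname(counts[colnames(ev$confusion)]), ignore_attr = TRUE)
  w <- counts[names(ev$producer)] / sum(counts)
  expect_equal(ev$overall, sum(ev$producer * w), tolerance = 1e-9)
})

test_that("evaluation errors on unknown columns and missing values", {
  ft <- toy_feature_table(data.frame(f1 = c(1, 2, NA, 4)),
                          habit = rep(c("coniferous", "deciduous"), 2))
  scd <- scale_features(ft)
  expect_error(loocv_evaluate(scd, "nope", fixed_svm_spec(), task = "habit"),
               "unknown feature")
  expect_error(loocv_evaluate(scd, "f1", fixed_svm_spec(), task = "habit"),
               "missing values")
})

test_that("RBF tuning returns the best grid point with the declared tie rule", {
  ft <- separable_table(n_per = 12)
  scd <- scale_features(ft)
  # grid of one: returned as-is
  spec1 <- fixed_svm_spec(C = 7, gamma = 0.3)
  expect_equal(tune_rbf(scd, "f1", spec1, task = "habit")[c("C", "gamma")],
               c(C = 7, gamma = 0.3))
  # separable data: chosen point achieves inner-CV accuracy 1
  spec <- classifier_spec("svm_rbf", C_grid = 2^c(0, 4),
                          gamma_grid = 2^c(-2, 1), seed = 3)
  tuned <- tune_rbf(scd, "f1", spec, task = "habit")
  expect_equal(unname(tuned["cv_accuracy"]), 1)
  # all grid points tie on separable data: smallest C, then smallest gamma
  expect_equal(unname(tuned["C"]), 1)
  expect_equal(unname(tuned["gamma"]), 0.25)
})

test_that("exhaustive search enumerates all combinations, order-independently", {
  set.seed(106)
  ft <- toy_feature_table(
    as.data.frame(matrix(rnorm(20 * 5), 20,
                         dimnames = list(NULL, paste0("f", 1:5)))),
    habit = rep(c("coniferous", "deciduous"), 10))
  scd <- scale_features(ft)
  spec <- fixed_svm_spec()
  sr <- exhaustive_search(scd, paste0("f", 1:5), 2L, spec, task = "habit")
  expect_equal(nrow(sr), choose(5, 2))
  expect_true(all(diff(sr$accuracy) <= 0))
  # pool permutation leaves the ranked table unchanged
  sr2 <- exhaustive_search(scd, paste0("f", c(4, 2, 5, 1, 3)), 2L, spec,
                           task = "habit")
  expect_equal(sr$subset, sr2$subset)
  expect_equal(sr$accuracy, sr2$accuracy)
  # arity 1 and the 2-of-2 degenerate case
  expect_equal(nrow(exhaustive_search(scd, paste0("f", 1:5), 1L, spec,
                                      task = "habit")), 5)
  expect_equal(nrow(exhaustive_search(scd, c("f1", "f2"), 2L, spec,
                                      task = "habit")), 1)
})

test_that("top-fraction selection keeps ties at the cutoff", {
  fake_result <- function(acc) {
    structure(data.frame(subset = paste0("s", seq_along(acc)),
                         accuracy = acc),
              class = c("search_result", "data.frame"),
              features = as.list(paste0("s", seq_along(acc))),
              n_evaluated = length(acc), arity = 1L, task = "habit")
  }
  sel <- select_top_fraction(fake_result(c(5, 4, 3, 3, 2)), 0.4)
  expect_equal(sel$accuracy, c(5, 4))
  sel2 <- select_top_fraction(fake_result(c(5, 4, 4, 4, 2)), 0.4)
  expect_equal(nrow(sel2), 4)               # ties at the cutoff included
  sel3 <- select_top_fraction(fake_result(c(5, 4, 3, 3, 2)), 1)
  expect_equal(nrow(sel3), 5)
  # monotone in the fraction
  accs <- c(9, 8, 8, 7, 6, 6, 6, 5, 4, 2)
  sizes <- vapply(seq(0.1, 1, 0.1), function(f)
    nrow(select_top_fraction(fake_result(accs), f)), integer(1))
  expect_true(all(diff(sizes) >= 0))
  # realized percentage, one decimal, half up
  expect_equal(attr(select_top_fraction(fake_result(c(5, 4, 4, 4, 2)), 0.4),
                    "fraction_realized_pct"), 80)
})

test_that("quadruples are the Cartesian product of the two pair sets", {
  a <- list(c("s1", "s2"), c("s3", "s4"))
  b <- list(c("c1", "c2"), c("c3", "c4"), c("c5", "c6"))
  q <- form_quadruples(a, b)
  expect_length(q, 6)
  expect_equal(q[[1]], c("s1", "s2", "c1", "c2"))
  expect_true(all(vapply(q, length, integer(1)) == 4))
  expect_equal(length(unique(lapply(q, sort))), 6)   # all unique
  expect_length(form_quadruples(list(), b), 0)
})

test_that("forward selection is greedy: locked features can miss the best pair", {
  # XOR-style geometry: f1, f2 jointly separate but are useless alone;
  # f3 is weakly informative alone and gets locked first
  set.seed(107)
  n <- 10
  cls <- rep(c("coniferous", "deciduous"), each = 2 * n)
  f1 <- c(rep(0, n), rep(1, n), rep(0, n), rep(1, n)) + rnorm(4 * n, 0, 0.05)
  f2 <- c(rep(0, n), rep(1, n), rep(1, n), rep(0, n)) + rnorm(4 * n, 0, 0.05)
  f3 <- ifelse(cls == "coniferous", 0, 0.35) + rnorm(4 * n, 0, 0.5)
  ft <- toy_feature_table(data.frame(f1, f2, f3), habit = cls)
  scd <- scale_features(ft)
  spec <- fixed_svm_spec(C = 32, gamma = 8)
  singles <- exhaustive_search(scd, c("f1", "f2", "f3"), 1L, spec,
                               task = "habit")
  expect_equal(singles$subset[1], "f3")     # f3 wins the first iteration
  pairs <- exhaustive_search(scd, c("f1", "f2", "f3"), 2L, spec,
                             task = "habit")
  expect_equal(pairs$subset[1], "f1 + f2")  # the XOR pair wins outright
  fw <- forward_select(scd, c("f1", "f2", "f3"), 2L, spec, task = "habit")
  expect_equal(fw$features[1], "f3")
  expect_lte(fw$accuracy, pairs$accuracy[1])
  # degenerate cases
  fw1 <- forward_select(scd, c("f1", "f2", "f3"), 1L, spec, task = "habit")
  expect_equal(fw1$features, singles$subset[1])
  expect_equal(fw1$accuracy, singles$accuracy[1])
  fw3 <- forward_select(scd, c("f1", "f2", "f3"), 3L, spec, task = "habit")
  expect_setequal(fw3$features, c("f1", "f2", "f3"))
  all3 <- loocv_evaluate(scd, c("f1", "f2", "f3"), spec, task = "habit")
  expect_equal(fw3$accuracy, all3$overall)
})

test_that("confusion summaries follow the user/producer definitions", {
  m <- diag(5)
  s <- confusion_summary(m)
  expect_equal(s$overall, 100)
  expect_true(all(s$user == 100) && all(s$producer == 100))
  m2 <- matrix(1, 2, 2)
  s2 <- confusion_summary(m2)
  expect_equal(s2$overall, 50)
  expect_true(all(s2$user == 50) && all(s2$producer == 50))
  # zero row/column: undefined accuracy reported as NA
  m3 <- matrix(c(2, 0, 1, 0), 2)
  s3 <- confusion_summary(m3)
  expect_true(is.na(s3$user[2]))
  expect_equal(unname(s3$user[1]), 2 / 3 * 100)
})

test_that("per-fold scaling mode refits scaling inside each fold", {
  ft <- separable_table(n_per = 8)
  scd_pf <- scale_features(ft, mode = "per_fold")
  expect_identical(attr(scd_pf, "scaling_mode"), "per_fold")
  expect_equal(scd_pf$f1, ft$f1)            # values deferred, not transformed
  ev <- loocv_evaluate(scd_pf, "f1", fixed_svm_spec(), task = "habit")
  expect_equal(ev$overall, 100)             # still separable per fold
})

test_that("null features never yield optimistically biased LOOCV accuracy", {
  # LOOCV with unweighted classifiers is pessimistic at chance (the held-out
  # specimen's class is always the training minority); the critical
  # direction is that accuracy never exceeds chance systematically
  accs <- vapply(1:40, function(s) {
    set.seed(s)
    ft <- toy_feature_table(data.frame(f1 = runif(40, -1, 1)),
                            habit = rep(c("coniferous", "deciduous"),
                                        each = 20))
    loocv_evaluate(scale_features(ft), "f1", fixed_svm_spec(),
                   task = "habit")$overall
  }, numeric(1))
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(mean(accs), 50 + 3 * se)
})
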