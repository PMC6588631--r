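# Study designs, balanced subsampling, top-5 scoring, confusion matrices,
# and the statistical tests against independent oracles.

test_that("canonical designs reproduce the study totals", {
  d <- canonical_designs()
  expect_equal(design_totals(d$organ_specific),
               c(database = 45000, query = 9000))
  expect_equal(design_totals(d$multi_organ),
               c(database = 87000, query = 14500))
  expect_equal(design_totals(d$gleason),
               c(database = 40000, query = 8000))
  expect_length(d$organ_specific$classes, 9)
  expect_length(d$multi_organ$classes, 29)
  expect_false("prostate/lymphocyte" %in% d$multi_organ$classes)
  expect_false("lymphocyte" %in% d$organ_specific$classes)
})

test_that("chance floor for the 9-category design rounds to 11%", {
  expect_equal(round(chance_floor(9)), 11)
  expect_equal(chance_floor(9), 100 / 9)
})

test_that("balanced_subsample returns exact per-class counts on disjoint slides", {
  set.seed(3)
  patches <- data.frame(
    slide_id = sample(sprintf("sl%02d", 1:8), 2000, replace = TRUE),
    class = sample(c("a", "b"), 2000, replace = TRUE),
    stringsAsFactors = FALSE)
  des <- study_design("toy", c("a", "b"), db_per_class = 100,
                      query_per_class = 30, n_db_slides = 6,
                      n_query_slides = 2, seed = 9)
  split <- balanced_subsample(patches, des)
  expect_equal(as.vector(table(split$database$class)), c(100L, 100L))
  expect_equal(as.vector(table(split$query$class)), c(30L, 30L))
  expect_length(intersect(split$database$slide_id, split$query$slide_id), 0)
  # deterministic given the design seed
  split2 <- balanced_subsample(patches, des)
  expect_identical(split, split2)
  # shortfall names the class
  des_big <- study_design("toy", c("a", "b"), 5000, 30, 6, 2, seed = 9)
  expect_error(balanced_subsample(patches, des_big), "class 'a'")
})

test_that("top-5 scoring matches hand enumeration", {
  q_labels <- rep(list("a"), 10)
  all_hit <- rep(list(list("a", "b", "b", "b", "b")), 10)
  expect_equal(top5_score(all_hit, q_labels), 100)
  none <- rep(list(list("b", "c")), 10)
  expect_equal(top5_score(none, q_labels), 0)
  # 7 of 10 queries contain >= 1 hit
  mixed <- c(rep(list(list("b", "a")), 7), rep(list(list("b", "b")), 3))
  expect_equal(top5_score(mixed, q_labels), 70)
  # empty result list counts as a miss
  expect_equal(top5_score(list(list(), list("a")), list("a", "a")), 50)
  expect_error(top5_score(list(as.list(rep("a", 6))), list("a")), "more than 5")
})

test_that("match predicates respect feature, organ, and grade axes", {
  q <- c("artery", "organ=prostate", "grade=GP3")
  expect_true(match_feature(q, c("artery", "fat", "organ=breast")))
  expect_false(match_feature(q, c("fat", "organ=prostate")))
  expect_true(match_feature_organ(q, c("artery", "organ=prostate")))
  expect_false(match_feature_organ(q, c("artery", "organ=breast")))
  expect_true(match_gleason(q, c("stroma", "grade=GP3")))
  expect_false(match_gleason(q, c("artery", "grade=GP4")))
  expect_true(match_gleason_feature(q, c("artery", "grade=GP3")))
  expect_false(match_gleason_feature(q, c("stroma", "grade=GP3")))
})

test_that("confusion matrix equals brute-force enumeration", {
  classes <- c("a", "b", "c")
  # results drawn only from the query's own class -> identity pattern
  rpq <- lapply(c("a", "b", "c"), function(cl) rep(list(cl), 5))
  m <- confusion_matrix_top5(rpq, c("a", "b", "c"), classes)
  expect_equal(unname(m), diag(3))

  # a single query whose results span {a, b}
  m2 <- confusion_matrix_top5(list(list("a", "b", "a", "a", "b")), "a",
                              classes)
  expect_equal(unname(m2["a", ]), c(1, 1, 0))

  # 3-class toy set vs hand count
  rpq3 <- list(list("a", "b"), list("c", "c"),   # two class-a queries
               list("b", "a"),                   # one class-b query
               list("c", "a"), list("b", "b"))   # two class-c queries
  qcl <- c("a", "a", "b", "c", "c")
  m3 <- confusion_matrix_top5(rpq3, qcl, classes)
  expect_equal(unname(m3["a", ]), c(0.5, 0.5, 0.5))
  expect_equal(unname(m3["b", ]), c(1, 1, 0))
  expect_equal(unname(m3["c", ]), c(0.5, 0.5, 0.5))
  # diagonal equals the per-class top-5 score
  for (cl in classes) {
    expect_equal(m3[cl, cl],
                 top5_score(rpq3[qcl == cl], as.list(qcl[qcl == cl])) / 100)
  }
})

test_that("mcnemar test matches exact and asymptotic oracles", {
  # symmetric discordance b = c = 10 -> p = 1 (exact, b + c < 25)
  a <- c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 5))
  b <- c(rep(FALSE, 10), rep(TRUE, 10), rep(TRUE, 5))
  r <- mcnemar_test(a, b)
  expect_equal(r$p.value, 1)
  expect_equal(r$method, "exact")
  # b = 5, c = 0 -> 2 * 0.5^5
  r2 <- mcnemar_test(c(rep(TRUE, 5), rep(TRUE, 3)),
                     c(rep(FALSE, 5), rep(TRUE, 3)))
  expect_equal(r2$p.value, 0.0625)
  # identical hit vectors -> p = 1
  expect_equal(mcnemar_test(a, a)$p.value, 1)
  # asymptotic branch agrees with stats::mcnemar.test
  set.seed(4)
  x <- c(rep(TRUE, 30), rep(FALSE, 12), rep(TRUE, 40), rep(FALSE, 40))
  y <- c(rep(FALSE, 30), rep(TRUE, 12), rep(TRUE, 40), rep(FALSE, 40))
  r3 <- mcnemar_test(x, y)
  expect_equal(r3$method, "chi-square")
  tab <- table(factor(x, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
  expect_equal(r3$p.value, stats::mcnemar.test(tab)$p.value)
})

test_that("mann-whitney agrees with enumeration and wilcox.test", {
  # U = 0 on fully separated samples of 3: exact two-sided p = 2/20
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 0.1)
  expect_equal(r$method, "exact")
  # identical groups -> degenerate p = 1
  expect_equal(mann_whitney_u(c(2, 2), c(2, 2, 2))$p.value, 1)
  # symmetry in the arguments
  set.seed(11)
  x <- rnorm(6); y <- rnorm(7)
  expect_equal(mann_whitney_u(x, y)$p.value, mann_whitney_u(y, x)$p.value)
  # exact path matches wilcox.test's exact p on untied data
  expect_equal(mann_whitney_u(x, y)$p.value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)
  # normal-approximation path matches wilcox.test with ties
  set.seed(12)
  a <- sample(1:6, 25, replace = TRUE)
  b <- sample(2:8, 30, replace = TRUE)
  expect_equal(mann_whitney_u(a, b)$p.value,
               suppressWarnings(stats::wilcox.test(a, b)$p.value),
               tolerance = 1e-12)
})

test_that("clopper-pearson interval matches binom.test and closed forms", {
  # x = 0: lower 0, upper 1 - (alpha/2)^(1/n)
  ci0 <- clopper_pearson_ci(0, 20)
  expect_equal(unname(ci0[1]), 0)
  expect_equal(unname(ci0[2]), 1 - 0.025^(1 / 20))
  # x = n: upper = 1
  expect_equal(unname(clopper_pearson_ci(15, 15)[2]), 1)
  # generic case against the binom.test oracle
  ci <- clopper_pearson_ci(50, 100)
  oracle <- stats::binom.test(50, 100)$conf.int
  expect_equal(unname(ci), as.numeric(oracle), tolerance = 1e-12)
  # the interval contains the point estimate
  for (x in c(1, 7, 13)) {
    ci <- clopper_pearson_ci(x, 13)
    expect_true(ci[1] <= x / 13 && x / 13 <= ci[2])
  }
})

test_that("normal_ci is mean +/- 1.96 SE", {
  expect_equal(unname(normal_ci(rep(50, 10))), c(50, 50))
  ci <- normal_ci(c(0, 100))
  # sd = 70.71, se = 50
  expect_equal(unname(ci), c(50 - 1.96 * 50, 50 + 1.96 * 50))
  expect_error(normal_ci(5), "at least 2")
  set.seed(2)
  v <- runif(30)
  ci2 <- normal_ci(v)
  expect_true(ci2[1] <= mean(v) && mean(v) <= ci2[2])
})

test_that("random engine score approaches the closed form", {
  # metadata-only database, 9 balanced classes
  per <- 50; n_class <- 4
  labs <- rep(paste0("c", seq_len(n_class)), each = per)
  meta <- data.frame(record_id = seq_along(labs), slide_id = "sdb",
                     x = 0, y = 0, w = 300, h = 300, magnification = "10x",
                     labels = labs, stringsAsFactors = FALSE)
  db <- structure(list(patches = meta, vectors = NULL, embedder = NULL,
                       params = kdtree_params(), index = NULL),
                  class = "embedding_db")
  queries <- lapply(1:400, function(i) {
    new_patch("sq", c(0, 0), "10x", labels = paste0("c", (i %% n_class) + 1))
  })
  rep_ <- run_study(list(db = db), queries, engines = "random", seed = 21)
  expected <- random_engine_expected_score(n_class)
  se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / 400)
  expect_lt(abs(rep_$scores$random$top5 - expected), 3 * se)
})

test_that("run_study rejects mismatched database patch sets", {
  db1 <- vector_db(4, 8, seed = 1)
  meta2 <- db1$patches
  meta2$x <- meta2$x + 1
  db2 <- db_from_vectors(db1$vectors, meta = meta2)
  expect_error(run_study(list(a = db1, b = db2), list(), engines = "random"),
               "share one database")
})
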