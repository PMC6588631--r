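# Blinded assignment, scoring rubrics, export/re-join, and aggregation.

toy_assignment_inputs <- function(nq = 40) {
  db <- db_from_vectors(matrix(rnorm(8 * 30 * 2), 240, 2), meta = {
    m <- collinear_meta(30, spacing = 5000)
    m$labels <- rep(c("artery", "fat", "stroma"), 10)
    m
  })
  queries <- lapply(seq_len(nq), function(i) {
    new_patch(paste0("q", i), c(0, 0), "10x",
              labels = c("artery", "organ=prostate", "grade=NT"))
  })
  fake_results <- lapply(seq_len(nq), function(i)
    random_retrieval(db, 4, seed = 10000 + i))
  list(db = db, queries = queries, fake = fake_results)
}

test_that("assignment sources follow the requested random fraction", {
  inp <- toy_assignment_inputs(1000)
  asg <- make_assignments(inp$queries, inp$db, random_fraction = 0.25,
                          seed = 31, engine_results = inp$fake)
  n_random <- sum(asg$queries$source == "random")
  expect_lt(abs(n_random - 250), 3 * sqrt(1000 * 0.25 * 0.75))
  # all-zero fraction: every query engine-sourced
  asg0 <- make_assignments(inp$queries[1:20], inp$db, random_fraction = 0,
                           seed = 31, engine_results = inp$fake[1:20])
  expect_true(all(asg0$queries$source == "smily"))
  # every query carries exactly 4 results from a single source
  expect_true(all(vapply(asg$results, nrow, 0L) == 4))
  # seeded determinism
  asg2 <- make_assignments(inp$queries, inp$db, random_fraction = 0.25,
                           seed = 31, engine_results = inp$fake)
  expect_identical(asg$queries, asg2$queries)
})

test_that("rater export is blinded and the key re-joins losslessly", {
  inp <- toy_assignment_inputs(30)
  asg <- make_assignments(inp$queries, inp$db, random_fraction = 0.25,
                          seed = 8, engine_results = inp$fake)
  dir <- withr::local_tempdir()
  sheet_path <- file.path(dir, "sheet.tsv")
  key_path <- file.path(dir, "key.tsv")
  export_rater_sheet(asg, sheet_path, key_path)

  sheet <- utils::read.table(sheet_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  # no source column, and no cell leaks the source strings
  expect_false("source" %in% names(sheet))
  expect_false(any(grepl("smily|random", unlist(sheet))))
  expect_equal(names(sheet)[1], "query_id")
  expect_length(grep("^result_", names(sheet)), 4)

  joined <- join_with_key(sheet_path, key_path)
  expect_equal(nrow(joined), 30)
  ord <- order(asg$queries$query_id)
  expect_equal(joined$source, asg$queries$source[ord])
})

test_that("binary feature rubric scores set overlap", {
  expect_equal(binary_feature_score(c("artery"), c("artery", "fat")), 100)
  expect_equal(binary_feature_score(c("artery"), c("fat")), 0)
  expect_equal(binary_feature_score(character(0), c("fat")), 0)
})

test_that("organ rubric passes through unclear and scores identity", {
  expect_equal(organ_match_score("prostate", "prostate"), 100)
  expect_equal(organ_match_score("prostate", "breast"), 0)
  expect_equal(organ_match_score("prostate", "breast", unclear = TRUE),
               "unclear")
})

test_that("match quality rubric reproduces the five anchor cases", {
  gp3_stroma <- list(tumor = TRUE, grade = "GP3", features = "stroma")
  gp4_nerve <- list(tumor = TRUE, grade = "GP4", features = "nerve")
  # tumor mismatch, visually different (no shared feature) -> 0
  expect_equal(match_quality_score(
    gp3_stroma, list(tumor = FALSE, grade = NA, features = "fat")), 0)
  # tumor mismatch but shared feature -> 25
  expect_equal(match_quality_score(
    gp3_stroma, list(tumor = FALSE, grade = NA, features = "stroma")), 25)
  # tumor status matches, grade differs -> 50
  expect_equal(match_quality_score(
    gp3_stroma, list(tumor = TRUE, grade = "GP4", features = "stroma")), 50)
  # grades match, no shared feature -> 75
  expect_equal(match_quality_score(
    gp4_nerve, list(tumor = TRUE, grade = "GP4", features = "fat")), 75)
  # grades match with a shared feature -> 100
  expect_equal(match_quality_score(
    gp4_nerve, list(tumor = TRUE, grade = "GP4",
                    features = c("nerve", "fat"))), 100)
  # both non-tumor counts as grade agreement
  expect_equal(match_quality_score(
    list(tumor = FALSE, features = "fat"),
    list(tumor = FALSE, features = "fat")), 100)
  expect_error(match_quality_score(
    list(tumor = TRUE, features = "fat"),
    list(tumor = FALSE, features = "fat")), "grade")
})

test_that("match quality rubric is exhaustive and consistent over a small vocabulary", {
  vocab <- list(character(0), "f1", "f2", c("f1", "f2"))
  grades <- c("GP3", "GP4")
  sides <- list()
  for (tumor in c(TRUE, FALSE)) {
    for (g in if (tumor) grades else NA) {
      for (f in vocab) {
        sides[[length(sides) + 1]] <- list(tumor = tumor, grade = g,
                                           features = f)
      }
    }
  }
  for (q in sides) {
    for (r in sides) {
      s <- match_quality_score(q, r)
      expect_true(s %in% c(0, 25, 50, 75, 100))
      overlap <- length(intersect(q$features, r$features)) > 0
      # tumor agreement decides the 50+ band; overlap decides 25/100
      if (q$tumor != r$tumor) {
        expect_equal(s, if (overlap) 25 else 0)
      } else {
        expect_gte(s, 50)
        if (s == 100) expect_true(overlap)
        if (s == 75) expect_false(overlap)
      }
    }
  }
})

test_that("aggregation averages flat over results and handles unclear", {
  # two queries scoring {100,0,0,0} and {100,100,0,0} -> mean 37.5
  sc <- data.frame(query_id = rep(c("q1", "q2"), each = 4),
                   source = "smily",
                   score = c(100, 0, 0, 0, 100, 100, 0, 0),
                   stringsAsFactors = FALSE)
  agg <- aggregate_scores(sc)
  expect_equal(agg$smily$mean, 37.5)
  expect_equal(agg$smily$n, 8)
  # all results scored 100 -> mean 100
  sc2 <- sc; sc2$score <- 100
  expect_equal(aggregate_scores(sc2)$smily$mean, 100)
  # half unclear: denominator halves, unclear fraction reported
  sc3 <- data.frame(query_id = "q1", source = "smily",
                    score = c("100", "0", "unclear", "unclear"),
                    stringsAsFactors = FALSE)
  agg3 <- aggregate_scores(sc3)
  expect_equal(agg3$smily$n, 2)
  expect_equal(agg3$smily$mean, 50)
  expect_equal(agg3$smily$unclear_fraction, 0.5)
  # unscored results are reported by query
  sc4 <- sc; sc4$score[3] <- NA
  expect_error(aggregate_scores(sc4), "q1")
})

test_that("separable retrieval outscores the random arm end to end", {
  set <- separable_set()
  db <- separable_db()
  # queries: reuse patches but treat them as fresh queries on other slides
  queries <- set$patches[set$meta$slide_id %in% c("slide005", "slide006")]
  asg <- make_assignments(queries, db, random_fraction = 0.5, seed = 2,
                          options = query_options(exclude_query_slide = TRUE))
  rows <- list()
  for (i in seq_along(queries)) {
    res <- asg$results[[i]]
    for (j in seq_len(nrow(res))) {
      rows[[length(rows) + 1]] <- data.frame(
        query_id = asg$queries$query_id[i],
        source = asg$queries$source[i],
        score = binary_feature_score(
          histoquery:::feature_labels(queries[[i]]$labels),
          histoquery:::feature_labels(strsplit(res$labels[j], ";")[[1]])),
        stringsAsFactors = FALSE)
    }
  }
  agg <- aggregate_scores(do.call(rbind, rows))
  expect_gt(agg$smily$mean, agg$random$mean)
})
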