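# Large-scale quantitative study harness: balanced subsampling, top-5
# scoring, confusion matrices, engine comparison, and the associated
# statistics (exact McNemar, Mann-Whitney U, Clopper-Pearson intervals,
# normal-approximation intervals).

#' Define a retrieval study design
#'
#' A design names the classes (optionally feature x organ combinations), the
#' balanced per-class database and query counts, and the slide split.
#'
#' @param name Design name.
#' @param classes Character vector of class keys.
#' @param db_per_class,query_per_class Patches sampled per class into the
#'   database and query sets.
#' @param n_db_slides,n_query_slides Disjoint slide counts for the two sets.
#' @param seed Sampling seed.
#' @export
study_design <- function(name, classes, db_per_class, query_per_class,
                         n_db_slides, n_query_slides, seed = 1) {
  stopifnot(length(classes) >= 1, db_per_class > 0, query_per_class > 0)
  structure(list(name = name, classes = classes,
                 db_per_class = as.integer(db_per_class),
                 query_per_class = as.integer(query_per_class),
                 n_db_slides = as.integer(n_db_slides),
                 n_query_slides = as.integer(n_query_slides),
                 seed = seed),
            class = "study_design")
}

HISTOLOGIC_FEATURES <- c("artery", "capillary", "fat", "lymphatic vessel",
                         "lymphocyte", "nerve", "normal epithelium",
                         "smooth muscle", "stroma", "vein")
GLEASON_CATEGORIES <- c("NT", "GP3", "GP4", "GP5")

#' The three canonical study designs
#'
#' Organ-specific (prostate; 9 histologic features, lymphocyte absent from
#' the prostate specimens), multi-organ (prostate/breast/colon x 10 features
#' with the prostate-lymphocyte cell excluded, 29 classes), and Gleason
#' grading (non-tumor plus Gleason patterns 3-5). Per-class counts are
#' 5000/1000, 3000/500 and 10000/2000, giving database/query totals of
#' 45,000/9,000, 87,000/14,500 and 40,000/8,000.
#'
#' @param seed Sampling seed stored on each design.
#' @return Named list of [study_design()] objects.
#' @export
canonical_designs <- function(seed = 1) {
  prostate9 <- setdiff(HISTOLOGIC_FEATURES, "lymphocyte")
  multi <- as.vector(outer(c("prostate", "breast", "colon"),
                           HISTOLOGIC_FEATURES, paste, sep = "/"))
  multi <- setdiff(multi, "prostate/lymphocyte")
  list(
    organ_specific = study_design("organ_specific", prostate9,
                                  5000, 1000, 15, 5, seed),
    multi_organ = study_design("multi_organ", multi, 3000, 500, 45, 15, seed),
    gleason = study_design("gleason", GLEASON_CATEGORIES,
                           10000, 2000, 20, 5, seed))
}

#' Database and query totals implied by a design
#'
#' @param design A [study_design()].
#' @return Named vector `c(database, query)`.
#' @export
design_totals <- function(design) {
  c(database = length(design$classes) * design$db_per_class,
    query = length(design$classes) * design$query_per_class)
}

#' Chance floor of a balanced single-label design
#'
#' The probability that one retrieved patch matches the query class under
#' uniform class assignment, as a percentage: 100/C (11% for the 9-category
#' prostate design).
#'
#' @param n_classes Number of balanced classes.
#' @export
chance_floor <- function(n_classes) 100 / n_classes

#' Expected top-5 score of uniform random retrieval
#'
#' For balanced single-label data, the chance that at least one of `k`
#' uniform draws matches the query class: `100 * (1 - ((C-1)/C)^k)`.
#'
#' @param n_classes Number of balanced classes.
#' @param k Results per query (default 5).
#' @export
random_engine_expected_score <- function(n_classes, k = 5) {
  100 * (1 - ((n_classes - 1) / n_classes)^k)
}

#' Balanced subsampling into disjoint database and query sets
#'
#' Slides are first split (seeded) into disjoint database and query slide
#' sets; then exactly `db_per_class` and `query_per_class` patches per class
#' are sampled without replacement from the respective side. A class with
#' too few patches on either side raises an error naming the class and the
#' shortfall.
#'
#' @param patches data.frame with at least `slide_id` and `class` columns
#'   (one row per patch).
#' @param design A [study_design()].
#' @return List with data.frames `database` and `query`.
#' @export
balanced_subsample <- function(patches, design) {
  stopifnot(all(c("slide_id", "class") %in% names(patches)))
  slides <- sort(unique(patches$slide_id))
  if (length(slides) < design$n_db_slides + design$n_query_slides) {
    stop("need ", design$n_db_slides + design$n_query_slides,
         " distinct slides, found ", length(slides))
  }
  sp <- split_slides(patches, design)
  q_slides <- sp$query
  d_slides <- sp$db
  sample_side <- function(side_patches, per_class, side, seed_offset) {
    out <- lapply(seq_along(design$classes), function(ci) {
      cl <- design$classes[ci]
      rows <- which(side_patches$class == cl)
      if (length(rows) < per_class) {
        stop("insufficient patches for class '", cl, "' in the ", side,
             " set: need ", per_class, ", have ", length(rows),
             " (shortfall ", per_class - length(rows), ")")
      }
      take <- with_seed(derive_seed(design$seed, seed_offset + ci),
                        sample(rows, per_class))
      side_patches[take, , drop = FALSE]
    })
    do.call(rbind, out)
  }
  list(database = sample_side(patches[patches$slide_id %in% d_slides, ],
                              design$db_per_class, "database", 0),
       query = sample_side(patches[patches$slide_id %in% q_slides, ],
                           design$query_per_class, "query", 1000))
}

# Seeded slide split, stratified by organ when the patch table carries an
# organ column (each organ's classes live only on that organ's slides, so a
# plain split could starve an organ's query set).
split_slides <- function(patches, design) {
  cols <- c("slide_id", if ("organ" %in% names(patches)) "organ")
  info <- unique(patches[cols])
  if (!"organ" %in% names(info)) info$organ <- "all"
  info <- info[order(info$slide_id), , drop = FALSE]
  total <- nrow(info)
  groups <- sort(unique(info$organ))
  nq_g <- round(design$n_query_slides * table(info$organ)[groups] / total)
  nd_g <- round(design$n_db_slides * table(info$organ)[groups] / total)
  # largest-remainder style fix-up so totals match the design exactly
  nq_g[1] <- nq_g[1] + design$n_query_slides - sum(nq_g)
  nd_g[1] <- nd_g[1] + design$n_db_slides - sum(nd_g)
  q_sl <- character(0); d_sl <- character(0)
  for (gi in seq_along(groups)) {
    sl <- info$slide_id[info$organ == groups[gi]]
    perm <- with_seed(derive_seed(design$seed, 5000 + gi), sample(sl))
    nq <- nq_g[gi]; nd <- min(nd_g[gi], length(sl) - nq)
    q_sl <- c(q_sl, perm[seq_len(nq)])
    d_sl <- c(d_sl, perm[nq + seq_len(nd)])
  }
  list(query = q_sl, db = d_sl)
}

# ---- label helpers ---------------------------------------------------------
# A patch's label set is a character vector; plain entries are histologic
# features, "organ=..." and "grade=..." entries carry the other axes.

split_labels <- function(x) {
  if (length(x) == 1 && is.character(x)) x <- strsplit(x, ";", fixed = TRUE)[[1]]
  x[nzchar(x)]
}

feature_labels <- function(labels) {
  l <- split_labels(labels)
  l[!grepl("^(organ|grade)=", l)]
}

organ_label <- function(labels) {
  l <- grep("^organ=", split_labels(labels), value = TRUE)
  if (length(l) == 0) NA_character_ else sub("^organ=", "", l[1])
}

grade_label <- function(labels) {
  l <- grep("^grade=", split_labels(labels), value = TRUE)
  if (length(l) == 0) NA_character_ else sub("^grade=", "", l[1])
}

#' Match predicates for top-5 scoring
#'
#' Each predicate takes the query's and one result's label sets and reports
#' whether the result is a hit: shared histologic feature
#' (`match_feature`), shared feature and same organ (`match_feature_organ`),
#' same Gleason category (`match_gleason`), or both Gleason category and a
#' shared feature (`match_gleason_feature`). Multi-label patches hit on any
#' intersection, so non-exhaustive annotations are not penalized.
#'
#' @param query_labels,result_labels Character label vectors (or
#'   ";"-joined strings).
#' @return Logical scalar.
#' @export
match_feature <- function(query_labels, result_labels) {
  length(intersect(feature_labels(query_labels),
                   feature_labels(result_labels))) > 0
}

#' @rdname match_feature
#' @export
match_feature_organ <- function(query_labels, result_labels) {
  match_feature(query_labels, result_labels) &&
    identical(organ_label(query_labels), organ_label(result_labels))
}

#' @rdname match_feature
#' @export
match_gleason <- function(query_labels, result_labels) {
  q <- grade_label(query_labels); r <- grade_label(result_labels)
  !is.na(q) && !is.na(r) && q == r
}

#' @rdname match_feature
#' @export
match_gleason_feature <- function(query_labels, result_labels) {
  match_gleason(query_labels, result_labels) &&
    match_feature(query_labels, result_labels)
}

#' Per-query top-5 hit indicators
#'
#' @param results_per_query List (one element per query) of lists of result
#'   label sets, each outer element holding at most 5 results. An empty list
#'   is a miss.
#' @param query_labels List of query label sets, same length.
#' @param match_predicate One of the `match_*` predicates (default
#'   [match_feature()]).
#' @return Logical vector of hits.
#' @export
top5_hits <- function(results_per_query, query_labels,
                      match_predicate = match_feature) {
  stopifnot(length(results_per_query) == length(query_labels))
  vapply(seq_along(query_labels), function(i) {
    res <- results_per_query[[i]]
    if (length(res) > 5) stop("query ", i, " has more than 5 results")
    any(vapply(res, function(r) match_predicate(query_labels[[i]], r), TRUE))
  }, TRUE)
}

#' Top-5 score
#'
#' Percentage of queries whose five (or fewer) results contain at least one
#' hit under the match predicate — the headline retrieval metric, chosen to
#' mimic a user scanning a handful of search results.
#'
#' @inheritParams top5_hits
#' @return Percentage in `[0, 100]`.
#' @export
top5_score <- function(results_per_query, query_labels,
                       match_predicate = match_feature) {
  100 * mean(top5_hits(results_per_query, query_labels, match_predicate))
}

#' Top-5 confusion matrix
#'
#' Entry (i, j) is the fraction of class-i queries whose top-5 results
#' contain at least one class-j result. The diagonal equals the per-class
#' top-5 score; rows need not sum to 1 since one query can hit several
#' classes.
#'
#' @param results_per_query List of lists of result label sets.
#' @param query_classes Character vector: each query's class key.
#' @param classes Class keys defining rows/columns.
#' @param class_member Function(labels, class) deciding membership; the
#'   default tests whether the class key appears among the labels (features
#'   or "organ/feature" keys).
#' @return `length(classes)` square matrix.
#' @export
confusion_matrix_top5 <- function(results_per_query, query_classes, classes,
                                  class_member = NULL) {
  if (is.null(class_member)) {
    class_member <- function(labels, cl) {
      l <- split_labels(labels)
      f <- feature_labels(l)
      o <- organ_label(l); g <- grade_label(l)
      cl %in% c(l, f, if (!is.na(g)) g, if (!is.na(o) && length(f))
        paste0(o, "/", f))
    }
  }
  m <- matrix(0, length(classes), length(classes),
              dimnames = list(query = classes, result = classes))
  for (i in seq_along(classes)) {
    qi <- which(query_classes == classes[i])
    if (length(qi) == 0) next
    for (j in seq_along(classes)) {
      hits <- vapply(qi, function(q) {
        any(vapply(results_per_query[[q]],
                   function(r) class_member(r, classes[j]), TRUE))
      }, TRUE)
      m[i, j] <- mean(hits)
    }
  }
  m
}

#' Run a retrieval study across engines
#'
#' Executes every query against each engine over the same database patch
#' set, scores hits under the match predicate, and assembles per-engine
#' top-5 scores with Clopper-Pearson intervals, per-class scores, confusion
#' matrices, and pairwise McNemar tests on the shared query set.
#'
#' @param dbs Named list of `embedding_db` objects, one per
#'   embedding-based engine (e.g. `list(smily = ..., sift = ...)`); all must
#'   index the same patch set. A `"random"` engine needs no vectors and uses
#'   the first database's patch table.
#' @param query_patches List of labeled [new_patch()] objects.
#' @param engines Character vector naming engines to run; `"random"` plus
#'   the names of `dbs`.
#' @param options [query_options()]; evaluation keeps
#'   `exclude_query_slide = TRUE` since query slides are disjoint.
#' @param match_predicate Hit predicate (default [match_feature()]).
#' @param classes Optional class keys for confusion matrices.
#' @param query_classes Optional per-query class keys (required with
#'   `classes`).
#' @param seed Seed for the random engine.
#' @return An `evaluation_report` list: `scores`, `hits`, `confusion`,
#'   `pairwise`, `n`.
#' @export
run_study <- function(dbs, query_patches, engines = c(names(dbs), "random"),
                      options = query_options(exclude_query_slide = TRUE),
                      match_predicate = match_feature, classes = NULL,
                      query_classes = NULL, seed = 1) {
  stopifnot(length(dbs) >= 1)
  base_meta <- dbs[[1]]$patches[c("slide_id", "x", "y")]
  for (d in dbs) {
    if (!identical(d$patches[c("slide_id", "x", "y")], base_meta)) {
      stop("all engines must share one database patch set")
    }
  }
  query_labels <- lapply(query_patches, function(p) p$labels)
  results <- list(); hits <- list()
  for (eng in engines) {
    rpq <- vector("list", length(query_patches))
    for (i in seq_along(query_patches)) {
      res <- if (eng == "random") {
        random_retrieval(dbs[[1]], options$k, derive_seed(seed, i))
      } else {
        query_database(dbs[[eng]], query_patches[[i]], options)
      }
      rpq[[i]] <- lapply(res$labels, split_labels)
    }
    results[[eng]] <- rpq
    hits[[eng]] <- top5_hits(rpq, query_labels, match_predicate)
  }
  nq <- length(query_patches)
  scores <- lapply(hits, function(h) {
    ci <- clopper_pearson_ci(sum(h), nq)
    list(top5 = 100 * mean(h), ci_lower = 100 * ci[1], ci_upper = 100 * ci[2],
         n = nq)
  })
  confusion <- NULL
  if (!is.null(classes)) {
    stopifnot(length(query_classes) == nq)
    confusion <- lapply(results, confusion_matrix_top5,
                        query_classes = query_classes, classes = classes)
  }
  pairwise <- list()
  engs <- names(hits)
  if (length(engs) >= 2) {
    for (a in seq_along(engs)) {
      for (b in seq_along(engs)) {
        if (a < b) {
          key <- paste(engs[a], engs[b], sep = "_vs_")
          pairwise[[key]] <- mcnemar_test(hits[[engs[a]]], hits[[engs[b]]])
        }
      }
    }
  }
  structure(list(scores = scores, hits = hits, confusion = confusion,
                 pairwise = pairwise, n = nq),
            class = "evaluation_report")
}

# ---- statistics ------------------------------------------------------------

#' McNemar test on paired binary outcomes
#'
#' Exact binomial McNemar on the discordant pairs (b, c) when b + c < 25,
#' chi-square with continuity correction otherwise. Zero discordant pairs
#' give p = 1.
#'
#' @param hits_a,hits_b Logical/0-1 vectors of equal length, paired by
#'   query.
#' @return List with `p.value`, `b`, `c`, `method`.
#' @export
mcnemar_test <- function(hits_a, hits_b) {
  stopifnot(length(hits_a) == length(hits_b))
  a <- as.logical(hits_a); b_ <- as.logical(hits_b)
  b <- sum(a & !b_)  # a hit, b miss
  cc <- sum(!a & b_)
  n <- b + cc
  if (n == 0) {
    return(list(p.value = 1, b = b, c = cc, method = "exact"))
  }
  if (n < 25) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
    method <- "exact"
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square"
  }
  list(p.value = p, b = b, c = cc, method = method)
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact by full enumeration of rank splits when the pooled sample has at
#' most 20 values; otherwise the normal approximation with tie correction
#' and continuity correction. Identical values across both groups give
#' p = 1.
#'
#' @param x,y Numeric vectors.
#' @return List with `p.value`, `U`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (length(unique(pooled)) == 1) {
    return(list(p.value = 1, U = U, method = "degenerate"))
  }
  mu <- m * n / 2
  if (m + n <= 20) {
    combs <- utils::combn(m + n, m)
    dev_obs <- abs(U - mu)
    devs <- apply(combs, 2, function(ix) {
      abs(sum(r[ix]) - m * (m + 1) / 2 - mu)
    })
    p <- mean(devs >= dev_obs - 1e-9)
    method <- "exact"
  } else {
    ties <- table(pooled)
    N <- m + n
    sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(z, lower.tail = FALSE)
    p <- min(1, max(0, p))
    method <- "normal"
  }
  list(p.value = p, U = U, method = method)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile interval; always contains the point estimate
#' `successes / n`. At `successes = 0` the upper bound has the closed form
#' `1 - (alpha/2)^(1/n)`.
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param alpha Two-sided error rate (default 0.05).
#' @return Numeric `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson_ci <- function(successes, n, alpha = 0.05) {
  stopifnot(n >= 1, successes >= 0, successes <= n)
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Normal-approximation confidence interval for a mean
#'
#' Mean plus/minus 1.96 standard errors — the interval used for non-binary
#' (averaged) accuracy metrics.
#'
#' @param values Numeric vector, length >= 2.
#' @return Numeric `c(lower, upper)`.
#' @export
normal_ci <- function(values) {
  if (length(values) < 2) stop("normal_ci needs at least 2 values")
  m <- mean(values)
  se <- stats::sd(values) / sqrt(length(values))
  c(lower = m - 1.96 * se, upper = m + 1.96 * se)
}
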