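# Blinded prospective-study machinery: randomized engine assignment per
# query (all four results of a query come from one source), scoring rubrics,
# blinded export / keyed re-join, and aggregation.

#' Randomize queries between retrieval and the random control
#'
#' Each query is independently assigned, with probability `random_fraction`,
#' to the random-control arm; otherwise it receives the search engine's
#' top-`k`. All `k` results of a query share one source, and the
#' rater-facing export hides the source — raters stay blinded.
#'
#' @param query_patches List of labeled [new_patch()] objects.
#' @param db An `embedding_db`.
#' @param random_fraction Probability of the random arm (default 0.25).
#' @param seed Assignment seed.
#' @param k Results per query (default 4, the prospective-study setting).
#' @param options [query_options()] for the engine arm; `k` is overridden.
#' @param engine_results Optional list of precomputed top-`k` result
#'   data.frames (one per query, as returned by [query_database()]), reused
#'   for engine-arm queries instead of searching again.
#' @return A `rater_assignments` object: list with `queries` (data.frame of
#'   query_id, source) and `results` (list of result data.frames).
#' @export
make_assignments <- function(query_patches, db, random_fraction = 0.25,
                             seed = 1, k = 4,
                             options = query_options(
                               exclude_query_slide = TRUE),
                             engine_results = NULL) {
  stopifnot(random_fraction >= 0, random_fraction <= 1)
  options$k <- as.integer(k)
  options$pool <- max(options$pool, 10L * options$k)
  nq <- length(query_patches)
  src <- with_seed(seed, ifelse(stats::runif(nq) < random_fraction,
                                "random", "smily"))
  results <- vector("list", nq)
  for (i in seq_len(nq)) {
    results[[i]] <- if (src[i] == "random") {
      random_retrieval(db, k, derive_seed(seed, i))
    } else if (!is.null(engine_results)) {
      utils::head(engine_results[[i]], k)
    } else {
      query_database(db, query_patches[[i]], options)
    }
  }
  structure(list(
    queries = data.frame(query_id = sprintf("q%04d", seq_len(nq)),
                         source = src, stringsAsFactors = FALSE),
    results = results,
    query_labels = lapply(query_patches, function(p) p$labels),
    k = as.integer(k)),
    class = "rater_assignments")
}

result_key <- function(res) {
  paste(res$slide_id, res$x, res$y, sep = ":")
}

#' Export the blinded rater sheet and the answer key
#'
#' The rater-facing TSV lists the query and its result identifiers with
#' blank score columns and carries no source information; the keyed answer
#' TSV holds the source and re-joins losslessly on `query_id`.
#'
#' @param assignments A [make_assignments()] object.
#' @param sheet_path Path of the blinded TSV.
#' @param key_path Path of the answer-key TSV.
#' @export
export_rater_sheet <- function(assignments, sheet_path, key_path) {
  k <- assignments$k
  rows <- lapply(seq_len(nrow(assignments$queries)), function(i) {
    res <- assignments$results[[i]]
    ids <- c(result_key(res), rep("", k))[seq_len(k)]
    c(query_id = assignments$queries$query_id[i],
      stats::setNames(ids, paste0("result_", seq_len(k))),
      stats::setNames(rep("", k), paste0("score_", seq_len(k))))
  })
  sheet <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(assignments$queries, key_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(sheet)
}

#' Re-join a scored sheet with the answer key
#'
#' @param sheet data.frame (or TSV path) of the scored rater sheet.
#' @param key data.frame (or TSV path) of the answer key.
#' @return The sheet with the `source` column restored.
#' @export
join_with_key <- function(sheet, key) {
  if (is.character(sheet)) {
    sheet <- utils::read.table(sheet, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE,
                               colClasses = "character")
  }
  if (is.character(key)) {
    key <- utils::read.table(key, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  }
  merge(sheet, key, by = "query_id", sort = TRUE)
}

#' Binary histologic-feature rubric
#'
#' 100 when the query and result share at least one histologic feature,
#' else 0.
#'
#' @param query_features,result_features Character feature sets.
#' @return 0 or 100.
#' @export
binary_feature_score <- function(query_features, result_features) {
  if (length(intersect(query_features, result_features)) > 0) 100 else 0
}

#' Three-way organ rubric
#'
#' 100 when organs match, 0 when they differ, `"unclear"` when the rater
#' could not judge (passed through; excluded from the aggregate denominator
#' by [aggregate_scores()]).
#'
#' @param query_organ,result_organ Organ labels.
#' @param unclear TRUE when the rater marked the comparison unclear.
#' @return 0, 100, or the string `"unclear"`.
#' @export
organ_match_score <- function(query_organ, result_organ, unclear = FALSE) {
  if (isTRUE(unclear)) return("unclear")
  if (identical(query_organ, result_organ)) 100 else 0
}

#' Overall match-quality rubric (0/25/50/75/100)
#'
#' The multi-aspect similarity score for tumor-bearing organ queries:
#' \itemize{
#'   \item 0 — tumor presence differs and no histologic feature is shared
#'     (the patches "look different"; the automated surrogate for visual
#'     difference is an empty feature intersection);
#'   \item 25 — tumor presence differs but at least one feature is shared;
#'   \item 50 — tumor presence matches but the grade differs;
#'   \item 75 — grades match (or both patches are non-tumor) with no shared
#'     feature;
#'   \item 100 — grades match (or both non-tumor) and at least one feature
#'     is shared.
#' }
#'
#' @param query,result Lists with `tumor` (logical), `grade` (category,
#'   required when tumor), `features` (character set).
#' @return One of 0, 25, 50, 75, 100.
#' @export
match_quality_score <- function(query, result) {
  for (side in list(query, result)) {
    if (!is.logical(side$tumor)) stop("tumor flag must be logical")
    if (isTRUE(side$tumor) && (is.null(side$grade) || is.na(side$grade))) {
      stop("tumor patch is missing its grade")
    }
  }
  feat_overlap <- length(intersect(query$features, result$features)) > 0
  if (query$tumor != result$tumor) {
    return(if (feat_overlap) 25 else 0)
  }
  grades_agree <- if (!query$tumor) TRUE else
    identical(query$grade, result$grade)
  if (!grades_agree) return(50)
  if (feat_overlap) 100 else 75
}

#' Aggregate rater scores by source
#'
#' The study score is the flat mean over all individual result scores within
#' each source group, with a plus/minus 1.96 SE interval. `"unclear"` values
#' (three-way organ rubric) are excluded from the denominator and their
#' fraction reported separately. Unscored results raise an error listing
#' them.
#'
#' @param scores data.frame with columns `query_id`, `source`, `score`
#'   (numeric, or the string "unclear").
#' @return Named list per source: `mean`, `ci`, `n`, `unclear_fraction`.
#' @export
aggregate_scores <- function(scores) {
  stopifnot(all(c("query_id", "source", "score") %in% names(scores)))
  missing <- is.na(scores$score) | scores$score == ""
  if (any(missing)) {
    stop("unscored results for queries: ",
         paste(unique(scores$query_id[missing]), collapse = ", "))
  }
  out <- list()
  for (src in unique(scores$source)) {
    s <- scores$score[scores$source == src]
    unclear <- s == "unclear"
    v <- suppressWarnings(as.numeric(s[!unclear]))
    out[[src]] <- list(
      mean = mean(v),
      ci = if (length(v) >= 2) normal_ci(v) else c(lower = NA, upper = NA),
      n = length(v),
      unclear_fraction = mean(unclear))
  }
  out
}
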