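# User-facing query pipeline: embed the query, retrieve an enlarged
# candidate pool, keep each patch's best orientation, enforce spatial
# diversity, apply exclusions, return the top k.

#' Query options
#'
#' @param k Number of results to return (default 5, the top-5 evaluation
#'   setting).
#' @param diversity_radius Minimum base-frame Euclidean distance, in pixels,
#'   between centers of two returned results on the same slide (default
#'   1000). Zero disables the filter.
#' @param exclude_query_slide Drop results from the query's slide; the
#'   evaluation studies keep database and query slides disjoint.
#' @param exclude_self Drop the stored patch with the query's exact
#'   footprint.
#' @param pool Initial candidate pool size; defaults to `10 * k` and grows
#'   on shortfall.
#' @export
query_options <- function(k = 5, diversity_radius = 1000,
                          exclude_query_slide = FALSE, exclude_self = FALSE,
                          pool = NULL) {
  stopifnot(k >= 1, diversity_radius >= 0)
  list(k = as.integer(k), diversity_radius = diversity_radius,
       exclude_query_slide = exclude_query_slide,
       exclude_self = exclude_self, pool = pool %||% (10L * as.integer(k)))
}

#' Search the database with a query patch
#'
#' Pipeline: embed orientation 0 of the resized query (the database's eight
#' stored orientations already span the dihedral group, so embedding further
#' query orientations would be redundant); retrieve a candidate pool by
#' exact nearest-neighbour search over all stored orientation vectors; keep
#' only each distinct patch's minimum-distance orientation; apply
#' exclusions; then greedily accept candidates in rank order, dropping any
#' whose base-frame center lies within `diversity_radius` pixels of an
#' already-accepted result on the same slide. The pool doubles on shortfall
#' until the database is exhausted.
#'
#' @param db An `embedding_db` (k-d tree used when present, exact either
#'   way).
#' @param query_patch A [new_patch()] with square pixels between 200 and 400
#'   px per side.
#' @param options [query_options()].
#' @return data.frame with columns `rank`, `record`, `slide_id`, `x`, `y`,
#'   `w`, `h`, `magnification`, `labels`, `best_orientation`, `distance`.
#'   Attribute `shortfall` is TRUE when fewer than `k` survivors exist.
#' @export
query_database <- function(db, query_patch, options = query_options()) {
  stopifnot(inherits(db, "embedding_db"), inherits(query_patch, "hq_patch"))
  if (!identical(db$embedder$name, "external")) {
    q <- as_float32(embed_pixels(db$embedder,
                                 resize_for_embedding(query_patch$pixels)))
  } else {
    stop("database has an external embedder; use query_vector()")
  }
  query_vector(db, q, options, query_patch = query_patch)
}

#' Search the database with a raw embedding vector
#'
#' Same pipeline as [query_database()] but starting from an already-computed
#' query embedding; used when the query was embedded elsewhere.
#'
#' @inheritParams query_database
#' @param q Numeric query embedding.
#' @param query_patch Optional patch supplying slide/footprint for the
#'   exclusion rules.
#' @export
query_vector <- function(db, q, options = query_options(),
                         query_patch = NULL) {
  total <- nrow(db$vectors)
  pool <- min(options$pool, total)
  repeat {
    res <- if (inherits(db$index, "hq_kdtree")) {
      kdtree_knn(db, q, pool)
    } else {
      brute_force_knn(db, q, pool)
    }
    out <- filter_results(db, res, options, query_patch)
    if (nrow(out) >= options$k || pool >= total) break
    pool <- min(2L * pool, total)
  }
  shortfall <- nrow(out) < options$k
  out <- utils::head(out, options$k)
  if (nrow(out) > 0) out$rank <- seq_len(nrow(out))
  attr(out, "shortfall") <- shortfall
  out
}

filter_results <- function(db, res, options, query_patch) {
  # dedup: results arrive distance-ascending, keep first (= best) orientation
  res <- res[!duplicated(res$record), , drop = FALSE]
  meta <- db$patches[match(res$record, db$patches$record_id), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  if (!is.null(query_patch)) {
    if (options$exclude_query_slide) {
      keep <- keep & meta$slide_id != query_patch$slide_id
    }
    if (options$exclude_self) {
      keep <- keep & !(meta$slide_id == query_patch$slide_id &
                         meta$x == query_patch$origin[1] &
                         meta$y == query_patch$origin[2] &
                         meta$magnification == query_patch$magnification)
    }
  }
  res <- res[keep, , drop = FALSE]; meta <- meta[keep, , drop = FALSE]
  cx <- meta$x + meta$w / 2; cy <- meta$y + meta$h / 2
  ax <- numeric(0); ay <- numeric(0); aslide <- character(0)
  take <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    ok <- TRUE
    if (options$diversity_radius > 0 && length(ax) > 0) {
      same <- aslide == meta$slide_id[i]
      if (any(same)) {
        dd <- sqrt((ax[same] - cx[i])^2 + (ay[same] - cy[i])^2)
        ok <- all(dd >= options$diversity_radius)
      }
    }
    if (ok) {
      take[i] <- TRUE
      ax <- c(ax, cx[i]); ay <- c(ay, cy[i])
      aslide <- c(aslide, meta$slide_id[i])
    }
  }
  res <- res[take, , drop = FALSE]; meta <- meta[take, , drop = FALSE]
  data.frame(rank = seq_len(nrow(res)), record = res$record,
             slide_id = meta$slide_id, x = meta$x, y = meta$y,
             w = meta$w, h = meta$h, magnification = meta$magnification,
             labels = meta$labels, best_orientation = res$orientation,
             distance = res$distance, stringsAsFactors = FALSE)
}

#' Random retrieval baseline
#'
#' Samples `k` distinct patches uniformly without replacement — the negative
#' control used both in the quantitative studies and as the blinded
#' rater-study control arm. Distances are unset.
#'
#' @param db An `embedding_db` (vectors not required).
#' @param k Number of patches.
#' @param seed Seed; identical seeds give identical draws.
#' @return data.frame shaped like [query_database()] output with `distance`
#'   and `best_orientation` NA.
#' @export
random_retrieval <- function(db, k, seed) {
  n <- nrow(db$patches)
  stopifnot(n >= k)
  ids <- with_seed(seed, sample.int(n, k))
  meta <- db$patches[ids, , drop = FALSE]
  data.frame(rank = seq_len(k), record = meta$record_id,
             slide_id = meta$slide_id, x = meta$x, y = meta$y,
             w = meta$w, h = meta$h, magnification = meta$magnification,
             labels = meta$labels, best_orientation = NA_integer_,
             distance = NA_real_, stringsAsFactors = FALSE)
}
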