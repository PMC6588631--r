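# Embedding database: persistence, exact brute-force search oracle, and a
# k-d tree accelerated search that is contractually identical to brute force
# (branch-and-bound with ball-overlap pruning, no approximation).
#
# All 8N orientation vectors live in one row matrix; row r is orientation
# row_orient[r] of record row_record[r], and rows are ordered record-major
# (record 1 orientations 0..7, record 2, ...). Ties in distance are broken
# by (record id, orientation) ascending so results are reproducible.

#' k-d tree stopping parameters
#'
#' Splitting stops when a node holds at most `leaf_size` points or reaches
#' `max_depth`. Exactness of the search never depends on these; they only
#' trade tree build time against per-query pruning.
#'
#' @param leaf_size Maximum leaf occupancy before depth cutoff (default 40).
#' @param max_depth Maximum node depth, root at 0 (default 6).
#' @export
kdtree_params <- function(leaf_size = 40, max_depth = 6) {
  stopifnot(leaf_size >= 1, max_depth >= 1)
  list(leaf_size = as.integer(leaf_size), max_depth = as.integer(max_depth))
}

#' Build an embedding database from patches
#'
#' Embeds every patch in all eight orientations and assembles the searchable
#' database. Pixel data is not retained; the database stores patch metadata
#' (base-frame footprint, labels) plus the vectors.
#'
#' @param patches List of [new_patch()] objects.
#' @param embedder An `embedder` object.
#' @param params [kdtree_params()] recorded for index construction.
#' @param build_index Build the k-d tree immediately (default TRUE).
#' @return An object of class `embedding_db`.
#' @export
build_database <- function(patches, embedder, params = kdtree_params(),
                           build_index = TRUE) {
  stopifnot(length(patches) >= 1)
  recs <- lapply(patches, function(p) embed_patch(embedder, p))
  vectors <- do.call(rbind, lapply(recs, function(r) r$vectors))
  meta <- patch_meta_table(patches)
  db <- new_embedding_db(meta, vectors, embedder, params)
  if (build_index) db$index <- build_kdtree(db, params)
  db
}

patch_meta_table <- function(patches) {
  data.frame(
    record_id = seq_along(patches),
    slide_id = vapply(patches, function(p) p$slide_id, ""),
    x = vapply(patches, function(p) p$origin[1], 0),
    y = vapply(patches, function(p) p$origin[2], 0),
    w = vapply(patches, function(p) p$size[1] * p$base_scale, 0),
    h = vapply(patches, function(p) p$size[2] * p$base_scale, 0),
    magnification = vapply(patches, function(p) p$magnification, ""),
    labels = vapply(patches, function(p) paste(p$labels, collapse = ";"), ""),
    stringsAsFactors = FALSE)
}

new_embedding_db <- function(meta, vectors, embedder, params) {
  n <- nrow(meta)
  if (!is.null(vectors)) {
    stopifnot(nrow(vectors) == 8 * n)
    row_record <- rep(meta$record_id, each = 8)
    row_orient <- rep.int(0:7, n)
  } else {
    row_record <- row_orient <- integer(0)
  }
  structure(list(patches = meta, vectors = vectors,
                 row_record = row_record, row_orient = row_orient,
                 embedder = embedder, params = params, index = NULL),
            class = "embedding_db")
}

#' Assemble a database directly from orientation vectors
#'
#' Bypasses embedding: `vectors` supplies the 8N x dim matrix in
#' record-major orientation order. Used for index experiments and by
#' [load_database()].
#'
#' @param meta Patch metadata data.frame (as in `db$patches`); a minimal
#'   frame is synthesized when NULL.
#' @param vectors 8N x dim numeric matrix.
#' @param embedder Embedder spec associated with the vectors.
#' @param params [kdtree_params()].
#' @export
db_from_vectors <- function(vectors, meta = NULL, embedder = NULL,
                            params = kdtree_params()) {
  stopifnot(is.matrix(vectors), nrow(vectors) %% 8 == 0)
  n <- nrow(vectors) / 8
  if (is.null(meta)) {
    meta <- data.frame(record_id = seq_len(n),
                       slide_id = sprintf("s%04d", seq_len(n)),
                       x = 0, y = 0, w = 300, h = 300,
                       magnification = "10x", labels = "",
                       stringsAsFactors = FALSE)
  }
  if (is.null(embedder)) {
    embedder <- structure(list(name = "external",
                               output_dim = ncol(vectors),
                               deterministic = TRUE, parameters = list()),
                          class = "embedder")
  }
  new_embedding_db(meta, as_float32(vectors), embedder, params)
}

#' Euclidean (L2) distance between two embedding vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar; zero iff `a == b`.
#' @export
l2_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("dimension mismatch: ", length(a), " vs ", length(b))
  }
  sqrt(sum((a - b)^2))
}

# Distances from query q to a set of vector rows, numerically identical
# to the per-leaf computation used by the k-d tree search.
row_distances <- function(V, rows, q) {
  X <- V[rows, , drop = FALSE]
  d2 <- rowSums(X * X) - 2 * as.vector(X %*% q) + sum(q * q)
  sqrt(pmax(d2, 0))
}

#' Exact k nearest neighbours by brute force
#'
#' The oracle the accelerated index is held to: the k globally smallest L2
#' distances over all 8N orientation vectors, ascending, ties broken by
#' (record id, orientation).
#'
#' @param db An `embedding_db` with vectors.
#' @param query_vector Numeric vector of the database's dimension.
#' @param k Number of neighbours.
#' @return data.frame with columns `record`, `orientation`, `distance`;
#'   attribute `truncated` is TRUE when `k` exceeds the vector count.
#' @export
brute_force_knn <- function(db, query_vector, k) {
  stopifnot(k >= 1, nrow(db$patches) >= 1)
  check_dim(db, query_vector)
  d <- row_distances(db$vectors, seq_len(nrow(db$vectors)), query_vector)
  ord <- order(d, db$row_record, db$row_orient)
  take <- utils::head(ord, k)
  out <- data.frame(record = db$row_record[take],
                    orientation = db$row_orient[take],
                    distance = d[take])
  attr(out, "truncated") <- k > length(d)
  out
}

check_dim <- function(db, q) {
  if (length(q) != ncol(db$vectors)) {
    stop("dimension mismatch: query has ", length(q),
         ", database has ", ncol(db$vectors))
  }
}

#' Build the k-d tree index
#'
#' Axis-aligned median splits on the widest-spread dimension; a node stops
#' splitting when it holds at most `leaf_size` points or sits at
#' `max_depth`. Every vector lands in exactly one leaf. Nodes carry their
#' bounding boxes for ball-overlap pruning at query time.
#'
#' @param db An `embedding_db`.
#' @param params [kdtree_params()].
#' @return Index object (assign to `db$index`).
#' @export
build_kdtree <- function(db, params = db$params) {
  V <- db$vectors
  stopifnot(!is.null(V), nrow(V) >= 1)
  build_node <- function(idx, depth) {
    X <- V[idx, , drop = FALSE]
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    node <- list(idx = idx, depth = depth, lo = lo, hi = hi, leaf = TRUE)
    if (length(idx) <= params$leaf_size || depth >= params$max_depth) {
      return(node)
    }
    spread <- hi - lo
    sd_ <- which.max(spread)
    if (spread[sd_] == 0) return(node)  # all points identical
    v <- X[, sd_]
    med <- stats::median(v)
    left <- v <= med
    if (all(left)) left <- v < med
    if (!any(left) || all(left)) return(node)
    node$leaf <- FALSE
    node$split_dim <- sd_
    node$split_val <- med
    node$left <- build_node(idx[left], depth + 1)
    node$right <- build_node(idx[!left], depth + 1)
    node$idx <- NULL
    node
  }
  structure(list(root = build_node(seq_len(nrow(V)), 0L),
                 params = params, n_vectors = nrow(V)),
            class = "hq_kdtree")
}

# Minimum possible distance from q to any point in the node's bounding box.
bbox_min_dist <- function(node, q) {
  d <- pmax(0, node$lo - q, q - node$hi)
  sqrt(sum(d * d))
}

#' Exact k nearest neighbours via the k-d tree
#'
#' Branch-and-bound descent: children nearer the query are visited first and
#' a subtree is pruned only when its bounding box lies strictly farther than
#' the current k-th best distance, so the output — including tie order — is
#' identical to [brute_force_knn()].
#'
#' @param db An `embedding_db` whose `index` was built by [build_kdtree()].
#' @param query_vector Query embedding.
#' @param k Number of neighbours.
#' @return Same shape as [brute_force_knn()].
#' @export
kdtree_knn <- function(db, query_vector, k) {
  stopifnot(k >= 1, inherits(db$index, "hq_kdtree"))
  check_dim(db, query_vector)
  q <- query_vector
  env <- new.env(parent = emptyenv())
  env$rows <- list(); env$dists <- list()
  env$n <- 0L
  env$bestd <- numeric(0)  # k smallest distances seen so far
  visit <- function(node) {
    # strict > (plus an ulp-scale guard) so equal-distance ties at the k-th
    # rank are never pruned away, even under floating-point cancellation
    if (length(env$bestd) >= k &&
        bbox_min_dist(node, q) > env$bestd[k] + 1e-9 * (1 + env$bestd[k])) {
      return(invisible())
    }
    if (node$leaf) {
      d <- row_distances(db$vectors, node$idx, q)
      env$n <- env$n + 1L
      env$rows[[env$n]] <- node$idx
      env$dists[[env$n]] <- d
      env$bestd <- utils::head(sort(c(env$bestd, d)), k)
      return(invisible())
    }
    kids <- list(node$left, node$right)
    md <- c(bbox_min_dist(node$left, q), bbox_min_dist(node$right, q))
    for (j in order(md)) visit(kids[[j]])
    invisible()
  }
  visit(db$index$root)
  rows <- unlist(env$rows[seq_len(env$n)])
  d <- unlist(env$dists[seq_len(env$n)])
  rec <- db$row_record[rows]; ori <- db$row_orient[rows]
  ord <- order(d, rec, ori)
  take <- utils::head(ord, k)
  out <- data.frame(record = rec[take], orientation = ori[take],
                    distance = d[take])
  attr(out, "truncated") <- k > db$index$n_vectors
  out
}

# Leaf occupancy and depth audit, used by tests.
kdtree_leaves <- function(index) {
  out <- list()
  walk <- function(node) {
    if (node$leaf) {
      out[[length(out) + 1L]] <<- list(n = length(node$idx),
                                       depth = node$depth, idx = node$idx)
    } else {
      walk(node$left); walk(node$right)
    }
  }
  walk(index$root)
  out
}

#' Persist a database to a directory
#'
#' On-disk layout: `manifest.json` (format version, embedder spec including
#' any projection/codebook so queries reuse the identical vocabulary, k-d
#' parameters, dimensions), `patches.tsv` (record metadata), and
#' `embeddings.f32` (row-major little-endian 32-bit floats, shape
#' (8N, output_dim)).
#'
#' @param db An `embedding_db`.
#' @param path Directory to create/overwrite.
#' @export
save_database <- function(db, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format_version = 1L,
    n_records = nrow(db$patches),
    output_dim = ncol(db$vectors),
    embedder = serialize_embedder(db$embedder),
    kdtree = db$params)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(db$patches, file.path(path, "patches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(file.path(path, "embeddings.f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(db$vectors)), con, size = 4, endian = "little")
  invisible(path)
}

# The default embedder's projection is a pure function of (dim, seed), so
# only those persist; the SIFT codebook is the fitted vocabulary and is
# stored in full so queries reuse it verbatim.
serialize_embedder <- function(e) {
  pars <- list(seed = e$parameters$seed)
  if (!is.null(e$parameters$centers)) {
    pars$centers_dim <- dim(e$parameters$centers)
    pars$centers <- as.vector(e$parameters$centers)
  }
  list(name = e$name, output_dim = e$output_dim,
       deterministic = e$deterministic, class = class(e), parameters = pars)
}

deserialize_embedder <- function(s) {
  dim_ <- as.integer(s$output_dim)
  seed <- as.numeric(s$parameters$seed %||% 17)
  if (identical(s$name, "default")) {
    return(default_embedder(dim = dim_, seed = seed))
  }
  if (identical(s$name, "sift_bovw")) {
    e <- sift_bovw_embedder(NULL, codebook_size = dim_, seed = seed)
    if (!is.null(s$parameters$centers)) {
      cd <- unlist(s$parameters$centers_dim)
      e$parameters$centers <- matrix(unlist(s$parameters$centers),
                                     cd[1], cd[2])
    }
    return(e)
  }
  structure(list(name = s$name, output_dim = dim_,
                 deterministic = isTRUE(s$deterministic),
                 parameters = s$parameters),
            class = unlist(s$class))
}

#' Load a persisted database
#'
#' Verifies the manifest's format version and that the embedding matrix has
#' exactly the declared number of values; truncation or mismatch raises an
#' integrity error. The round trip through [save_database()] is lossless.
#'
#' @param path Directory written by [save_database()].
#' @param build_index Rebuild the k-d tree after loading (default TRUE).
#' @return An `embedding_db`.
#' @export
load_database <- function(path, build_index = TRUE) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf)
  if (!identical(as.integer(manifest$format_version), 1L)) {
    stop("unsupported database format version: ", manifest$format_version)
  }
  meta <- utils::read.table(file.path(path, "patches.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c(labels = "character",
                                           slide_id = "character"))
  n <- as.integer(manifest$n_records)
  dim_ <- as.integer(manifest$output_dim)
  fpath <- file.path(path, "embeddings.f32")
  expected <- 8 * n * dim_
  actual <- file.info(fpath)$size / 4
  if (!isTRUE(actual == expected)) {
    stop("embedding matrix integrity error: expected ", expected,
         " float32 values, found ", actual)
  }
  con <- file(fpath, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = expected, size = 4, endian = "little")
  vectors <- matrix(vals, nrow = 8 * n, ncol = dim_, byrow = TRUE)
  embedder <- deserialize_embedder(manifest$embedder)
  params <- kdtree_params(manifest$kdtree$leaf_size, manifest$kdtree$max_depth)
  db <- new_embedding_db(meta, vectors, embedder, params)
  if (build_index) db$index <- build_kdtree(db, params)
  db
}
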