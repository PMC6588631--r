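# Pluggable embedder contract plus two concrete embedders:
#   * default_embedder(): deterministic handcrafted descriptor (intensity,
#     gradient-orientation and gradient-magnitude histograms, seeded linear
#     projection, L2-normalized);
#   * sift_bovw_embedder(): dense SIFT-style local descriptors aggregated by
#     a seeded bag-of-visual-words codebook.
# Any object of class "embedder" with an embed_pixels() method plugs into the
# database, so a learned network can substitute without touching downstream
# code.

#' Compute the embedding vector of pre-resized pixels
#'
#' Generic behind the embedder contract. `pixels` has already been oriented
#' and passed through [resize_for_embedding()].
#'
#' @param embedder An `embedder` object.
#' @param pixels 224 x 224 x 3 array in `[0, 255]`.
#' @return Numeric vector of length `embedder$output_dim`.
#' @export
embed_pixels <- function(embedder, pixels) UseMethod("embed_pixels")

#' @export
embed_pixels.default <- function(embedder, pixels) {
  stop("no embed_pixels() method for class ", paste(class(embedder),
                                                    collapse = "/"))
}

#' Default deterministic embedder
#'
#' A handcrafted, fully deterministic image descriptor: per-channel 16-bin
#' intensity histograms, an 8-bin gradient-orientation histogram over a 4x4
#' spatial grid (128 bins), and a 16-bin gradient-magnitude histogram,
#' linearly projected to `dim` values by a fixed seeded projection and
#' L2-normalized.
#'
#' The projection is built to respect the square's symmetry group: a
#' dihedral transform of the input permutes the 128 orientation-spatial bins
#' and leaves the intensity/magnitude histograms unchanged, so the
#' projection applies a seeded random matrix that commutes with those bin
#' permutations (its texture part) and maps the invariant histograms into
#' the permutation-invariant subspace (its colour part). Consequently
#' `emb(T(x)) = rho(T) emb(x)` with `rho(T)` orthogonal: rotating or
#' mirroring both query and database patches leaves every pairwise L2
#' distance unchanged, which is what makes the orientation-augmented
#' database exactly orientation-invariant at `dim = 128`. For other `dim` a
#' final seeded Gaussian stage is applied and the isometry becomes
#' approximate.
#'
#' @param dim Output dimension, >= 8 (default 128).
#' @param seed Seed for the fixed projection matrices.
#' @return An object of classes `default_embedder`, `embedder`.
#' @export
default_embedder <- function(dim = 128, seed = 17) {
  stopifnot(dim >= 8)
  perms <- d4_bin_permutations()
  W <- with_seed(seed, {
    M <- matrix(stats::rnorm(128 * 128), 128, 128) / sqrt(128)
    acc <- matrix(0, 128, 128)
    for (p in perms) {
      P <- matrix(0, 128, 128); P[cbind(p, 1:128)] <- 1
      acc <- acc + P %*% M %*% t(P)
    }
    acc / 8
  })
  orbit <- d4_bin_orbits(perms)  # 128 x n_orbits indicator basis
  C <- with_seed(seed + 1, matrix(stats::rnorm(ncol(orbit) * 64),
                                  ncol(orbit), 64) / sqrt(64))
  B <- orbit %*% C
  final <- NULL
  if (dim != 128) {
    final <- with_seed(seed + 2,
                       matrix(stats::rnorm(dim * 128), dim, 128) / sqrt(128))
  }
  structure(list(name = "default", output_dim = as.integer(dim),
                 deterministic = TRUE,
                 parameters = list(seed = seed, W = W, B = B, final = final)),
            class = c("default_embedder", "embedder"))
}

# The eight D4 bin permutations of the (4x4 cell) x (8 orientation) grid:
# element k of the result maps descriptor bin i of x to bin p[i] of the
# k-th oriented copy of x (mirror first for k >= 4, then k %% 4 CCW
# rotations, matching apply_orientation()).
d4_bin_permutations <- function() {
  cell_rot <- function(cells) {
    ry <- cells %/% 4L; rx <- cells %% 4L
    (3L - rx) * 4L + ry
  }
  cell_mir <- function(cells) {
    ry <- cells %/% 4L; rx <- cells %% 4L
    ry * 4L + (3L - rx)
  }
  base_cell <- rep(0:15, each = 8L)
  base_ob <- rep.int(0:7, 16L)
  lapply(0:7, function(k) {
    cell <- base_cell; ob <- base_ob
    if (k >= 4) {
      cell <- cell_mir(cell)
      ob <- (3L - ob) %% 8L         # gradient angle theta -> pi - theta
    }
    for (r in seq_len(k %% 4)) {
      cell <- cell_rot(cell)
      ob <- (ob - 2L) %% 8L         # gradient angle theta -> theta - pi/2
    }
    cell * 8L + ob + 1L
  })
}

# Orbits of the 128 bins under the permutation group, as a normalized
# indicator basis of the invariant subspace.
d4_bin_orbits <- function(perms) {
  orbit_id <- integer(128)
  nid <- 0L
  for (i in 1:128) {
    if (orbit_id[i] == 0L) {
      nid <- nid + 1L
      members <- unique(vapply(perms, function(p) p[i], 0L))
      # close under the group (the 8 images already form the orbit for D4)
      orbit_id[members] <- nid
    }
  }
  basis <- matrix(0, 128, nid)
  for (i in 1:128) {
    basis[i, orbit_id[i]] <- 1
  }
  sweep(basis, 2, sqrt(colSums(basis^2)), "/")
}

#' @export
embed_pixels.default_embedder <- function(embedder, pixels) {
  f <- patch_descriptor(pixels)
  h <- f[c(1:48, 177:192)]   # dihedral-invariant: colour + magnitude
  g <- f[49:176]             # equivariant: orientation x spatial grid
  h <- h / (sqrt(sum(h^2)) + 1e-12)
  g <- g / (sqrt(sum(g^2)) + 1e-12)
  v <- as.vector(embedder$parameters$W %*% g + embedder$parameters$B %*% h)
  if (!is.null(embedder$parameters$final)) {
    v <- as.vector(embedder$parameters$final %*% v)
  }
  n <- sqrt(sum(v^2))
  if (n > 0) v <- v / n
  v
}

# Spatial 4x4 cell index is a pure function of the image dims; cache it.
.descriptor_cache <- new.env(parent = emptyenv())

spatial_cell_index <- function(h, w) {
  key <- paste(h, w)
  cached <- .descriptor_cache[[key]]
  if (!is.null(cached)) return(cached)
  ry <- pmin.int(floor((seq_len(h) - 1) / h * 4), 3)
  rx <- pmin.int(floor((seq_len(w) - 1) / w * 4), 3)
  idx <- (outer(ry, rx, function(r, c) r * 4 + c)) * 8L
  .descriptor_cache[[key]] <- idx
  idx
}

# Raw 192-value descriptor: 48 intensity + 128 orientation + 16 magnitude.
patch_descriptor <- function(px) {
  h <- dim(px)[1]; w <- dim(px)[2]
  npix <- h * w
  ch_hist <- c(tabulate(as.integer(px[, , 1] / 16) + 1L, 16),
               tabulate(as.integer(px[, , 2] / 16) + 1L, 16),
               tabulate(as.integer(px[, , 3] / 16) + 1L, 16)) / npix
  g <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  gr <- image_gradients(g)
  obin <- pmin.int(as.integer((gr$ang + pi) * (8 / (2 * pi))), 7L)
  idx <- spatial_cell_index(h, w) + obin + 1L
  ohist <- numeric(128)
  agg <- rowsum(as.vector(gr$mag), as.vector(idx))
  ohist[as.integer(rownames(agg))] <- agg
  ohist <- ohist / (sum(ohist) + 1e-12)
  mhist <- tabulate(as.integer(gr$mag * (16 / 181)) + 1L, 16) / npix
  c(ch_hist, ohist, mhist)
}

# Central-difference gradients (replicated borders) of a grayscale matrix.
image_gradients <- function(g) {
  h <- nrow(g); w <- ncol(g)
  gx <- (g[, c(2:w, w)] - g[, c(1, 1:(w - 1))]) / 2
  gy <- (g[c(2:h, h), ] - g[c(1, 1:(h - 1)), ]) / 2
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2), ang = atan2(gy, gx))
}

#' SIFT-style bag-of-visual-words embedder
#'
#' Dense SIFT-style descriptors (4x4 cells x 8 orientation bins over 16x16
#' windows on a regular grid; windows with negligible gradient energy are
#' skipped, so flat patches yield no keypoints) are clustered with seeded
#' k-means into a visual-word codebook. A patch's embedding is its
#' L2-normalized codeword histogram; a patch with zero keypoints maps to the
#' all-zero vector.
#'
#' @param training_patches List of [new_patch()] objects used to fit the
#'   codebook, or NULL for an unfitted spec (which [embed_patch()] rejects).
#' @param codebook_size Number of visual words (default 128, matching the
#'   embedding dimension of the default embedder).
#' @param seed Seed controlling k-means; the embedder is deterministic given
#'   the seed and training set.
#' @return An object of classes `sift_bovw_embedder`, `embedder`.
#' @export
sift_bovw_embedder <- function(training_patches = NULL, codebook_size = 128,
                               seed = 1) {
  spec <- structure(list(name = "sift_bovw",
                         output_dim = as.integer(codebook_size),
                         deterministic = TRUE,
                         parameters = list(seed = seed, centers = NULL,
                                           step = 16L, win = 16L,
                                           energy_threshold = 2)),
                    class = c("sift_bovw_embedder", "embedder"))
  if (is.null(training_patches)) return(spec)
  descs <- do.call(rbind, lapply(training_patches, function(p) {
    sift_descriptors(resize_for_embedding(p$pixels), spec$parameters)
  }))
  if (is.null(descs) || nrow(descs) < codebook_size) {
    stop("too few keypoint descriptors to fit the codebook: need at least ",
         codebook_size, ", got ", if (is.null(descs)) 0 else nrow(descs))
  }
  km <- with_seed(seed, stats::kmeans(descs, centers = codebook_size,
                                      iter.max = 30, nstart = 1))
  spec$parameters$centers <- km$centers
  spec
}

#' @export
embed_pixels.sift_bovw_embedder <- function(embedder, pixels) {
  counts <- bovw_counts(embedder, pixels)
  n <- sqrt(sum(counts^2))
  if (n > 0) counts / n else counts
}

#' Raw visual-word counts for a pixel array
#'
#' The pre-normalization codeword histogram; its entries sum to the number
#' of detected keypoints.
#'
#' @param embedder A fitted [sift_bovw_embedder()].
#' @param pixels 224 x 224 x 3 array.
#' @return Integer-valued numeric vector of length `codebook_size`.
#' @export
bovw_counts <- function(embedder, pixels) {
  centers <- embedder$parameters$centers
  if (is.null(centers)) {
    stop("embedder not fitted: supply training_patches to sift_bovw_embedder()")
  }
  d <- sift_descriptors(pixels, embedder$parameters)
  counts <- numeric(nrow(centers))
  if (is.null(d) || nrow(d) == 0) return(counts)
  # nearest codeword per descriptor
  d2 <- outer(rowSums(d^2), rowSums(centers^2), "+") - 2 * d %*% t(centers)
  nn <- max.col(-d2, ties.method = "first")
  tab <- tabulate(nn, nbins = nrow(centers))
  as.numeric(tab)
}

# Dense SIFT-style descriptors: one 128-vector per grid window whose mean
# gradient magnitude exceeds the energy threshold.
sift_descriptors <- function(pixels, pars) {
  g <- (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3
  gr <- image_gradients(g)
  win <- pars$win; step <- pars$step
  h <- nrow(g); w <- ncol(g)
  ys <- seq.int(0L, h - win, by = step)
  xs <- seq.int(0L, w - win, by = step)
  obin <- pmin(floor((gr$ang + pi) / (2 * pi) * 8), 7)
  cell_of <- floor((seq_len(win) - 1) / (win / 4))  # 0..3 per axis
  out <- list()
  for (y0 in ys) {
    for (x0 in xs) {
      rows <- (y0 + 1):(y0 + win); cols <- (x0 + 1):(x0 + win)
      m <- gr$mag[rows, cols]
      if (mean(m) <= pars$energy_threshold) next
      ob <- obin[rows, cols]
      idx <- (outer(cell_of, cell_of, function(r, c) r * 4 + c)) * 8 + ob + 1
      v <- numeric(128)
      agg <- rowsum(as.vector(m), as.vector(idx))
      v[as.integer(rownames(agg))] <- agg
      n <- sqrt(sum(v^2))
      if (n > 0) v <- v / n
      out[[length(out) + 1L]] <- v
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Embed a patch in all eight orientations
#'
#' Each orientation of the square patch is resized through
#' [resize_for_embedding()] and embedded separately, yielding the
#' orientation-augmented record stored in the database (eight vectors per
#' patch). Vectors are quantized to 32-bit floats, the database's storage
#' precision.
#'
#' @param embedder An `embedder` object.
#' @param patch A [new_patch()] with square pixels.
#' @return An `embedding_record`: `patch_ref` plus an 8 x `output_dim` matrix
#'   `vectors`, row k holding orientation k-1.
#' @export
embed_patch <- function(embedder, patch) {
  stopifnot(inherits(embedder, "embedder"), inherits(patch, "hq_patch"))
  if (inherits(embedder, "sift_bovw_embedder") &&
      is.null(embedder$parameters$centers)) {
    stop("embedder not fitted: supply training_patches to sift_bovw_embedder()")
  }
  vecs <- matrix(0, 8, embedder$output_dim)
  for (k in 0:7) {
    px <- resize_for_embedding(apply_orientation(patch$pixels, k))
    v <- embed_pixels(embedder, px)
    if (length(v) != embedder$output_dim || any(!is.finite(v))) {
      stop("embedder returned an invalid vector")
    }
    vecs[k + 1, ] <- v
  }
  structure(list(patch_ref = list(slide_id = patch$slide_id,
                                  origin = patch$origin,
                                  magnification = patch$magnification),
                 vectors = as_float32(vecs)),
            class = "embedding_record")
}

#' Storage-reduction factor of the embedding representation
#'
#' Raw patch values divided by stored embedding values: a 300 x 300 x 3 patch
#' kept as eight 128-vectors is a roughly 260-fold reduction.
#'
#' @param patch_size Patch side length in pixels (default 300).
#' @param channels Number of channels (default 3).
#' @param n_orientations Stored orientations per patch (default 8).
#' @param dim Embedding dimension (default 128).
#' @return The reduction factor as a plain number.
#' @export
storage_reduction_fold <- function(patch_size = 300, channels = 3,
                                   n_orientations = 8, dim = 128) {
  (patch_size^2 * channels) / (n_orientations * dim)
}
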