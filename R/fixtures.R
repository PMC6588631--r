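# Seeded generator of classed texture patches, pyramidal slides, and noisy
# annotations, emulating the structure of an annotated whole-slide corpus:
# multi-class, multi-"organ", graded textures with imperfect (~70% pure)
# recorded labels.
#
# Texture model: each patch is a grayscale field
#   128 + a_bg * lowpass-noise + separability * a_cl * bandpass-noise(class)
# where the class-specific component is isotropic band-pass noise whose
# radial frequency band identifies the class. Isotropic bands make the
# textures dihedral-covariant — rotating or mirroring a patch keeps its
# class — which is what makes orientation-invariance tests meaningful
# (histology has no canonical orientation either). "Organ" tints the hue,
# "grade" adds an ordered density of dark blobs. At separability 0 the
# class component vanishes and classes are exchangeable by construction.

#' Specify a synthetic patch corpus
#'
#' @param n_classes Number of texture families ("histologic features").
#' @param n_organs Number of hue families (default 1).
#' @param n_grades Number of ordered blob-density grades (default 1).
#' @param patches_per_cell Patches per class x organ x grade cell.
#' @param separability Class-signal amplitude, >= 0; 0 makes classes
#'   exchangeable (default 1).
#' @param label_purity Probability a patch's recorded label equals its true
#'   class; with probability `1 - label_purity` the recorded label is a
#'   uniformly random other class (default 0.7, mirroring real annotation
#'   purity). Ground truth is always retained.
#' @param patch_size Patch side length in pixels (default 300).
#' @param n_slides Number of synthetic slides the patches are spread over
#'   (default 20; slides are nested within organs when `n_organs > 1`).
#' @param seed Seed; output is bit-identical for identical seeds.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_classes = 9, n_organs = 1, n_grades = 1,
                         patches_per_cell = 50, separability = 1,
                         label_purity = 0.7, patch_size = 300,
                         n_slides = 20, seed = 1) {
  stopifnot(n_classes >= 1, n_organs >= 1, n_grades >= 1,
            patches_per_cell >= 1, separability >= 0,
            label_purity > 0, label_purity <= 1, patch_size >= 8)
  structure(list(n_classes = as.integer(n_classes),
                 n_organs = as.integer(n_organs),
                 n_grades = as.integer(n_grades),
                 patches_per_cell = as.integer(patches_per_cell),
                 separability = separability, label_purity = label_purity,
                 patch_size = as.integer(patch_size),
                 n_slides = as.integer(n_slides), seed = seed),
            class = "fixture_spec")
}

fixture_class_names <- function(n) sprintf("class%02d", seq_len(n))
fixture_organ_names <- function(n) sprintf("organ%d", seq_len(n))
fixture_grade_names <- function(n) {
  if (n == 1) "NT" else c("NT", sprintf("GP%d", 2 + seq_len(n - 1)))
}

#' Generate a labeled synthetic patch set
#'
#' Returns one metadata row per patch: true class, recorded (possibly
#' mislabeled) class, organ, grade, slide assignment and non-overlapping
#' base-frame coordinates. Pixel content is generated per patch from a
#' derived seed, either eagerly (`pixels = TRUE`) or later via
#' [fixture_patch()], so large study-design corpora can be laid out without
#' synthesizing images.
#'
#' @param spec A [fixture_spec()].
#' @param pixels Attach pixel arrays and return patch objects (default
#'   TRUE).
#' @return List with `meta` (data.frame) and, when `pixels`, `patches`
#'   (list of [new_patch()], labels = recorded class plus `organ=`/`grade=`
#'   tags).
#' @export
generate_patch_set <- function(spec, pixels = TRUE) {
  cls <- fixture_class_names(spec$n_classes)
  orgs <- fixture_organ_names(spec$n_organs)
  grds <- fixture_grade_names(spec$n_grades)
  cells <- expand.grid(class_true = cls, organ = orgs, grade = grds,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- cells[rep(seq_len(nrow(cells)), each = spec$patches_per_cell), ,
                drop = FALSE]
  n <- nrow(meta)
  meta$patch_id <- seq_len(n)
  # slides nested within organs; patches round-robin over their organ's slides
  spo <- max(1L, spec$n_slides %/% spec$n_organs)
  oi <- match(meta$organ, orgs) - 1L
  within <- stats::ave(seq_len(n), meta$organ, FUN = seq_along) - 1L
  slide_no <- oi * spo + (within %% spo) + 1L
  meta$slide_id <- sprintf("slide%03d", slide_no)
  # non-overlapping grid coordinates per slide; whole-slide images are
  # gigapixel-sized, so distinct annotated patches sit far apart — keep them
  # outside the default 1,000 px diversity radius of each other
  slot <- stats::ave(seq_len(n), meta$slide_id, FUN = seq_along) - 1L
  pitch <- max(2L * spec$patch_size, 2000L)
  meta$x <- (slot %% 100L) * pitch
  meta$y <- (slot %/% 100L) * pitch
  # symmetric label noise: flipped patches take a uniformly random other class
  flip <- with_seed(derive_seed(spec$seed, 777),
                    stats::runif(n) > spec$label_purity)
  off <- with_seed(derive_seed(spec$seed, 778),
                   sample.int(max(spec$n_classes - 1L, 1L), n, replace = TRUE))
  ci <- match(meta$class_true, cls)
  meta$class <- ifelse(flip & spec$n_classes > 1,
                       cls[((ci - 1L + off) %% spec$n_classes) + 1L],
                       meta$class_true)
  rownames(meta) <- NULL
  out <- list(meta = meta, spec = spec)
  if (pixels) {
    out$patches <- lapply(seq_len(n), function(i) fixture_patch(spec, meta[i, ]))
  }
  class(out) <- "fixture_set"
  out
}

#' Synthesize one fixture patch from its metadata row
#'
#' Deterministic given the spec seed and `row$patch_id`.
#'
#' @param spec The [fixture_spec()] the row came from.
#' @param row One row of `generate_patch_set(spec, pixels = FALSE)$meta`.
#' @return A labeled [new_patch()].
#' @export
fixture_patch <- function(spec, row) {
  s <- spec$patch_size
  ci <- match(row$class_true, fixture_class_names(spec$n_classes))
  oi <- match(row$organ, fixture_organ_names(spec$n_organs))
  gi <- match(row$grade, fixture_grade_names(spec$n_grades))
  px <- with_seed(derive_seed(spec$seed, row$patch_id), {
    fixture_texture(s, ci, spec$n_classes, oi, spec$n_organs, gi,
                    spec$separability)
  })
  labels <- c(row$class, paste0("organ=", row$organ),
              paste0("grade=", row$grade))
  new_patch(row$slide_id, origin = c(row$x, row$y), magnification = "10x",
            size = c(s, s), pixels = px, labels = labels)
}

# Class-specific radial frequency band (cycles/pixel), spread over
# [0.05, 0.32] so families are distinct but all resolvable at 224px.
class_band <- function(ci, n_classes) {
  lo <- 0.05; hi <- 0.32
  f <- if (n_classes == 1) (lo + hi) / 2 else
    lo + (ci - 1) / (n_classes - 1) * (hi - lo)
  c(f - 0.025, f + 0.025)
}

# Isotropic band-pass filter of white noise, unit variance.
bandpass_noise <- function(s, band) {
  z <- matrix(stats::rnorm(s * s), s, s)
  f <- c(0:(s %/% 2), -((s - s %/% 2 - 1):1)) / s
  r <- sqrt(outer(f^2, f^2, "+"))
  mask <- r >= band[1] & r < band[2]
  if (!any(mask)) mask[2, 1] <- TRUE
  out <- Re(stats::fft(stats::fft(z) * mask, inverse = TRUE)) / (s * s)
  sdv <- stats::sd(out)
  if (sdv > 0) out / sdv else out
}

fixture_texture <- function(s, ci, n_classes, oi, n_organs, gi, separability) {
  bg <- bandpass_noise(s, c(0.0, 0.06))
  g <- 128 + 16 * bg
  if (separability > 0) {
    g <- g + 16 * separability * bandpass_noise(s, class_band(ci, n_classes))
  }
  # grade: ordered density of dark blobs
  if (gi > 1) {
    nb <- 8 * (gi - 1)
    rad <- max(2, s / 25)
    bx <- stats::runif(nb, 1, s); by <- stats::runif(nb, 1, s)
    rr <- row(g); cc <- col(g)
    for (b in seq_len(nb)) {
      m <- (rr - by[b])^2 + (cc - bx[b])^2 <= rad^2
      g[m] <- g[m] - 45
    }
  }
  # organ: hue tint via per-channel gains
  phase <- 2 * pi * (oi - 1) / max(1, n_organs)
  gains <- 1 + 0.12 * cos(phase + 2 * pi * (0:2) / 3)
  px <- array(0, c(s, s, 3))
  for (ch in 1:3) px[, , ch] <- clamp(g * gains[ch], 0, 255)
  px
}

#' Generate a pyramidal synthetic slide with annotations
#'
#' Paints class textures into the requested rectangles on a noise
#' background, builds the 40x/20x/10x/5x pyramid by successive 2x box
#' downsampling, and returns annotation regions shrunk to cover ~80% of each
#' painted area (annotators outline most, not all, of what they see).
#'
#' @param spec A [fixture_spec()].
#' @param width,height Base-frame (40x) dimensions in pixels.
#' @param regions data.frame with columns `x`, `y`, `w`, `h`, `class`
#'   (class index or name); base-frame coordinates.
#' @param slide_id Identifier (default "synthetic01").
#' @return List with `slide` ([slide_image()]) and `annotations` (list of
#'   [annotation_region()]).
#' @export
generate_slide <- function(spec, width, height, regions,
                           slide_id = "synthetic01") {
  stopifnot(all(regions$x + regions$w <= width),
            all(regions$y + regions$h <= height))
  cls <- fixture_class_names(spec$n_classes)
  base <- with_seed(derive_seed(spec$seed, 424243), {
    g <- 128 + 10 * matrix(stats::rnorm(width * height), height, width)
    for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      ci <- if (is.numeric(r$class)) r$class else match(r$class, cls)
      tex <- 128 + 16 * bandpass_noise_rect(r$h, r$w, class_band(ci, spec$n_classes)) *
        max(spec$separability, 1)
      g[(r$y + 1):(r$y + r$h), (r$x + 1):(r$x + r$w)] <- tex
    }
    clamp(g, 0, 255)
  })
  px <- array(0, c(height, width, 3))
  for (ch in 1:3) px[, , ch] <- base
  levels <- list("40x" = list(pixels = px, mpp = 0.25))
  cur <- px
  for (mag in c("20x", "10x", "5x")) {
    cur <- downsample2(cur)
    levels[[mag]] <- list(pixels = cur,
                          mpp = 0.25 * 2^match(mag, c("20x", "10x", "5x")))
  }
  slide <- slide_image(slide_id, levels)
  ann <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    f <- sqrt(0.8)  # shrink each side so area covered is 80%
    aw <- round(r$w * f); ah <- round(r$h * f)
    nm <- if (is.numeric(r$class)) cls[r$class] else r$class
    annotation_region(slide_id, nm,
                      x = r$x + round((r$w - aw) / 2),
                      y = r$y + round((r$h - ah) / 2), w = aw, h = ah)
  })
  list(slide = slide, annotations = ann)
}

bandpass_noise_rect <- function(h, w, band) {
  s <- max(h, w)
  bandpass_noise(s, band)[seq_len(h), seq_len(w), drop = FALSE]
}

# 2x2 box-mean downsampling of an h x w x c array (even dims assumed).
downsample2 <- function(a) {
  d <- dim(a)
  h2 <- d[1] %/% 2; w2 <- d[2] %/% 2
  out <- array(0, c(h2, w2, d[3]))
  for (ch in seq_len(d[3])) {
    m <- a[seq_len(2 * h2), seq_len(2 * w2), ch]
    out[, , ch] <- (m[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2)] +
                      m[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2)] +
                      m[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2)] +
                      m[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2)]) / 4
  }
  out
}

#' Synthetic metadata corpus for a canonical study design
#'
#' Lays out a labeled patch corpus (metadata only — no pixels) sized so that
#' [balanced_subsample()] can draw the design's per-class database and query
#' counts from disjoint slide sets: fixture class/organ names are mapped
#' onto the design's histologic features, organs, or Gleason categories, and
#' excluded combinations (prostate lymphocyte) are absent from the corpus,
#' as they were from the annotated slides.
#'
#' @param design One of [canonical_designs()] (or a compatible
#'   [study_design()]).
#' @param seed Corpus seed (defaults to the design seed).
#' @param margin Oversampling factor above the minimum per-class need
#'   (default 1.15).
#' @return data.frame with `slide_id`, `class` (recorded study key),
#'   `organ`, `class_true`, and coordinates.
#' @export
design_fixture_meta <- function(design, seed = design$seed, margin = 1.15) {
  n_slides <- design$n_db_slides + design$n_query_slides
  share_db <- design$n_db_slides / n_slides
  ppc <- ceiling(margin * max(design$db_per_class / share_db,
                              design$query_per_class / (1 - share_db)))
  is_combo <- any(grepl("/", design$classes, fixed = TRUE))
  if (is_combo) {
    orgs <- sort(unique(sub("/.*$", "", design$classes)))
    feats <- sort(unique(sub("^[^/]+/", "", design$classes)))
    spec <- fixture_spec(n_classes = length(feats), n_organs = length(orgs),
                         patches_per_cell = ppc, n_slides = n_slides,
                         seed = seed)
    meta <- generate_patch_set(spec, pixels = FALSE)$meta
    meta$organ <- orgs[match(meta$organ, fixture_organ_names(length(orgs)))]
    fmap <- function(x) feats[match(x, fixture_class_names(length(feats)))]
    meta$class_true <- paste0(meta$organ, "/", fmap(meta$class_true))
    meta$class <- paste0(meta$organ, "/", fmap(meta$class))
    # combinations outside the design never occur in the corpus
    meta <- meta[meta$class %in% design$classes &
                   meta$class_true %in% design$classes, , drop = FALSE]
  } else {
    keys <- sort(design$classes)
    spec <- fixture_spec(n_classes = length(keys), patches_per_cell = ppc,
                         n_slides = n_slides, seed = seed)
    meta <- generate_patch_set(spec, pixels = FALSE)$meta
    kmap <- function(x) keys[match(x, fixture_class_names(length(keys)))]
    meta$class_true <- kmap(meta$class_true)
    meta$class <- kmap(meta$class)
  }
  rownames(meta) <- NULL
  meta
}
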