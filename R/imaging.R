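# Patch extraction, dihedral orientations, and the embedder resize contract.
#
# Conventions used throughout:
#   * pixel arrays are (height, width, channels) with values in [0, 255];
#   * coordinates are 0-based, top-left origin, half-open rectangles;
#   * patch origins and footprints are stored in the base frame, i.e. the
#     highest-magnification level of the slide, so patches from different
#     magnifications are directly comparable.

MAG_LEVELS <- c("40x", "20x", "10x", "5x")

mag_value <- function(label) {
  v <- suppressWarnings(as.numeric(sub("x$", "", sub("^x", "", label))))
  if (any(is.na(v))) stop("unrecognized magnification label: ", label)
  v
}

#' Create a pyramidal slide image
#'
#' A slide is a named list of magnification levels, each an RGB pixel array
#' plus its microns-per-pixel resolution. All levels depict the same scene;
#' linear dimensions halve per 2x magnification step.
#'
#' @param slide_id Character identifier.
#' @param levels Named list (names are magnification labels such as `"40x"`,
#'   `"10x"`); each element is a list with `pixels` (h x w x 3 array, values
#'   in `[0, 255]`) and optionally `mpp` (microns per pixel).
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(slide_id, levels) {
  stopifnot(is.character(slide_id), length(slide_id) == 1L, length(levels) >= 1L)
  if (is.null(names(levels)) || any(!nzchar(names(levels)))) {
    stop("levels must be named by magnification label")
  }
  mags <- mag_value(names(levels))
  base <- names(levels)[which.max(mags)]
  bd <- dim(levels[[base]]$pixels)
  for (nm in names(levels)) {
    px <- levels[[nm]]$pixels
    if (length(dim(px)) != 3L) stop("level ", nm, ": pixels must be h x w x c")
    sc <- mag_value(base) / mag_value(nm)
    if (any(abs(dim(px)[1:2] - bd[1:2] / sc) > 1)) {
      stop("level ", nm, ": dimensions inconsistent with base level ", base)
    }
  }
  structure(list(slide_id = slide_id, levels = levels, base = base),
            class = "slide_image")
}

#' Create an annotation region
#'
#' Regions are rectangles or polygons in base-frame pixel coordinates,
#' carrying a category label and an annotation purity (the fraction of the
#' region's area that truly belongs to the label; pathologist annotations in
#' the motivating setting are only ~70% pure).
#'
#' @param slide_id Slide the region belongs to.
#' @param label Category label (histologic feature or grade); non-empty.
#' @param x,y,w,h Rectangle in base-frame pixels (used when `polygon` is NULL).
#' @param polygon Optional n x 2 matrix of (x, y) vertices.
#' @param purity Fraction in (0, 1]; default 0.7.
#' @return An object of class `annotation_region`.
#' @export
annotation_region <- function(slide_id, label, x = NULL, y = NULL, w = NULL,
                              h = NULL, polygon = NULL, purity = 0.7) {
  stopifnot(nzchar(label), purity > 0, purity <= 1)
  if (is.null(polygon)) {
    stopifnot(w > 0, h > 0)
    shape <- list(type = "rect", x = x, y = y, w = w, h = h)
  } else {
    stopifnot(is.matrix(polygon), ncol(polygon) == 2L, nrow(polygon) >= 3L)
    if (abs(polygon_area(polygon)) <= 0) stop("polygon area must be > 0")
    shape <- list(type = "polygon", vertices = polygon)
  }
  structure(list(slide_id = slide_id, shape = shape, label = label,
                 purity = purity),
            class = "annotation_region")
}

#' Construct a patch
#'
#' @param slide_id Source slide identifier.
#' @param origin Length-2 numeric, 0-based (x, y) in base-frame pixels.
#' @param magnification Magnification label of the pixel data.
#' @param size Length-2 (w, h) in pixels at that magnification (default 300).
#' @param pixels h x w x 3 array in `[0, 255]`, or NULL for metadata-only
#'   patches.
#' @param labels Character vector of category labels.
#' @param base_scale Base-frame pixels per patch-frame pixel (ratio of base to
#'   patch magnification); the base-frame footprint is `size * base_scale`.
#' @return An object of class `hq_patch`.
#' @export
new_patch <- function(slide_id, origin, magnification, size = c(300, 300),
                      pixels = NULL, labels = character(), base_scale = 1) {
  if (!is.null(pixels)) {
    stopifnot(length(dim(pixels)) == 3L,
              dim(pixels)[1] == size[2], dim(pixels)[2] == size[1])
  }
  structure(list(slide_id = slide_id, origin = as.numeric(origin),
                 magnification = magnification, size = as.numeric(size),
                 pixels = pixels, labels = labels,
                 base_scale = as.numeric(base_scale)),
            class = "hq_patch")
}

# Base-frame center of a patch's footprint.
patch_center <- function(p) p$origin + p$size * p$base_scale / 2

#' Tile a slide level into fixed-size patches
#'
#' Patches tile the level left-to-right, top-to-bottom; incomplete boundary
#' tiles are dropped (fixed-size patches only). With `stride = size` the
#' footprints are pairwise non-overlapping.
#'
#' @param slide A [slide_image()].
#' @param magnification Level label to extract from.
#' @param size Patch side length in pixels at that magnification.
#' @param stride Step between patch origins; defaults to `size`.
#' @return List of [new_patch()] objects, origins recorded in the base frame.
#' @export
extract_patches <- function(slide, magnification, size = 300, stride = size) {
  stopifnot(inherits(slide, "slide_image"), stride >= 1)
  lvl <- slide$levels[[magnification]]
  if (is.null(lvl)) {
    stop("magnification ", magnification, " absent from slide ",
         slide$slide_id)
  }
  px <- lvl$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  if (size > h || size > w) stop("patch size exceeds level dimensions")
  sc <- mag_value(slide$base) / mag_value(magnification)
  xs <- seq.int(0L, w - size, by = stride)
  ys <- seq.int(0L, h - size, by = stride)
  out <- vector("list", length(xs) * length(ys))
  i <- 1L
  for (y in ys) {
    for (x in xs) {
      out[[i]] <- new_patch(slide$slide_id, origin = c(x, y) * sc,
                            magnification = magnification,
                            size = c(size, size),
                            pixels = px[(y + 1):(y + size),
                                        (x + 1):(x + size), , drop = FALSE],
                            base_scale = sc)
      i <- i + 1L
    }
  }
  out
}

#' Extract labeled patches from annotation regions
#'
#' Candidate footprints tile each region's bounding box (non-overlapping
#' within a region). A candidate is kept when its footprint overlaps the
#' source region by at least `min_overlap` (default 0.7, mirroring the ~70%
#' annotation purity); it inherits the label of every region it overlaps by
#' at least that fraction, so patches under two sufficiently overlapping
#' regions become multi-label. Regions smaller than one footprint simply
#' yield no patches.
#'
#' @param slide A [slide_image()].
#' @param regions List of [annotation_region()] belonging to the slide.
#' @param magnification Level to extract pixel data from.
#' @param size Patch side length at that magnification.
#' @param min_overlap Minimum footprint/region overlap fraction in (0, 1].
#' @return List of labeled [new_patch()] objects.
#' @export
patches_from_annotations <- function(slide, regions, magnification,
                                     size = 300, min_overlap = 0.7) {
  stopifnot(inherits(slide, "slide_image"))
  if (!all(vapply(regions, function(r) r$slide_id, "") == slide$slide_id)) {
    stop("all regions must belong to slide ", slide$slide_id)
  }
  lvl <- slide$levels[[magnification]]
  if (is.null(lvl)) stop("magnification ", magnification, " absent from slide")
  px <- lvl$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  sc <- mag_value(slide$base) / mag_value(magnification)
  side <- size * sc  # base-frame footprint side
  seen <- character(0)
  out <- list()
  for (r in regions) {
    bb <- region_bbox(r)
    nx <- floor(bb["w"] / side); ny <- floor(bb["h"] / side)
    if (nx < 1 || ny < 1) next
    for (iy in seq_len(ny) - 1) {
      for (ix in seq_len(nx) - 1) {
        fx <- bb["x"] + ix * side; fy <- bb["y"] + iy * side
        if (region_overlap_fraction(r, fx, fy, side) < min_overlap) next
        key <- paste(fx, fy, sep = ",")
        if (key %in% seen) next
        labs <- unique(unlist(lapply(regions, function(q) {
          if (region_overlap_fraction(q, fx, fy, side) >= min_overlap)
            q$label else NULL
        })))
        lx <- round(fx / sc); ly <- round(fy / sc)
        if (lx < 0 || ly < 0 || lx + size > w || ly + size > h) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- new_patch(
          slide$slide_id, origin = c(fx, fy), magnification = magnification,
          size = c(size, size),
          pixels = px[(ly + 1):(ly + size), (lx + 1):(lx + size), ,
                      drop = FALSE],
          labels = labs, base_scale = sc)
      }
    }
  }
  out
}

region_bbox <- function(r) {
  if (r$shape$type == "rect") {
    c(x = r$shape$x, y = r$shape$y, w = r$shape$w, h = r$shape$h)
  } else {
    v <- r$shape$vertices
    c(x = min(v[, 1]), y = min(v[, 2]),
      w = max(v[, 1]) - min(v[, 1]), h = max(v[, 2]) - min(v[, 2]))
  }
}

# Fraction of the (fx, fy, side, side) footprint covered by region r.
region_overlap_fraction <- function(r, fx, fy, side) {
  if (r$shape$type == "rect") {
    ix <- max(0, min(fx + side, r$shape$x + r$shape$w) - max(fx, r$shape$x))
    iy <- max(0, min(fy + side, r$shape$y + r$shape$h) - max(fy, r$shape$y))
    (ix * iy) / (side * side)
  } else {
    clipped <- clip_polygon_rect(r$shape$vertices, fx, fy, fx + side, fy + side)
    if (is.null(clipped) || nrow(clipped) < 3) return(0)
    abs(polygon_area(clipped)) / (side * side)
  }
}

polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2]) / 2
}

# Sutherland-Hodgman clipping of polygon v against an axis-aligned rectangle.
clip_polygon_rect <- function(v, x0, y0, x1, y1) {
  clip_edge <- function(poly, inside, intersect) {
    if (is.null(poly) || nrow(poly) == 0) return(poly)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(poly)
    for (i in seq_len(n)) {
      a <- poly[if (i == 1) n else i - 1, ]
      b <- poly[i, ]
      ain <- inside(a); bin <- inside(b)
      if (bin) {
        if (!ain) out <- rbind(out, intersect(a, b))
        out <- rbind(out, b)
      } else if (ain) {
        out <- rbind(out, intersect(a, b))
      }
    }
    out
  }
  ix <- function(a, b, t) a + (b - a) * t
  v <- clip_edge(v, function(p) p[1] >= x0, function(a, b)
    ix(a, b, (x0 - a[1]) / (b[1] - a[1])))
  v <- clip_edge(v, function(p) p[1] <= x1, function(a, b)
    ix(a, b, (x1 - a[1]) / (b[1] - a[1])))
  v <- clip_edge(v, function(p) p[2] >= y0, function(a, b)
    ix(a, b, (y0 - a[2]) / (b[2] - a[2])))
  v <- clip_edge(v, function(p) p[2] <= y1, function(a, b)
    ix(a, b, (y1 - a[2]) / (b[2] - a[2])))
  v
}

#' Apply one of the eight dihedral (D4) orientations
#'
#' Orientation indices 0-3 are counter-clockwise rotations by 0/90/180/270
#' degrees; 4-7 are the horizontal mirror followed by the same rotations.
#' Together they form the symmetry group of the square, which is how the
#' database achieves orientation-invariant retrieval: histology has no
#' canonical "up".
#'
#' @param pixels Square h x w x c array.
#' @param orientation Integer 0-7.
#' @return Transformed pixel array.
#' @export
apply_orientation <- function(pixels, orientation) {
  stopifnot(length(dim(pixels)) == 3L, orientation %in% 0:7)
  if (dim(pixels)[1] != dim(pixels)[2]) {
    stop("dihedral orientations require a square patch")
  }
  if (orientation >= 4) {
    pixels <- pixels[, dim(pixels)[2]:1, , drop = FALSE]  # horizontal mirror
    orientation <- orientation - 4
  }
  for (i in seq_len(orientation)) pixels <- rot90_ccw(pixels)
  pixels
}

rot90_ccw <- function(a) {
  d <- dim(a)
  out <- array(a, dim = c(d[2], d[1], d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- t(a[, , ch])[d[2]:1, , drop = FALSE]
  }
  out
}

#' Inverse of a dihedral orientation index
#'
#' Rotations invert to the complementary rotation; mirrored orientations are
#' involutions.
#' @param orientation Integer 0-7.
#' @return The index whose transform undoes `orientation`.
#' @export
inverse_orientation <- function(orientation) {
  stopifnot(orientation %in% 0:7)
  c(0L, 3L, 2L, 1L, 4L, 5L, 6L, 7L)[orientation + 1]
}

#' All eight dihedral orientations of a patch
#'
#' @param patch A [new_patch()] with square pixels, or a square pixel array.
#' @return List of 8 pixel arrays, indexed by orientation 0-7.
#' @export
dihedral_orientations <- function(patch) {
  px <- if (inherits(patch, "hq_patch")) patch$pixels else patch
  lapply(0:7, function(k) apply_orientation(px, k))
}

#' Resize a patch to the embedder input size
#'
#' Every embedder input — 300x300 database patches and 200-400px query
#' crops alike — passes through one corner-aligned bilinear resize to
#' 224 x 224, so query and database embeddings share a single contract.
#' Inputs outside the 200-400px query-size rule are rejected.
#'
#' @param pixels h x w x 3 array with h, w in `[200, 400]`.
#' @param out_size Output side length (default 224).
#' @return `out_size` x `out_size` x 3 array, values clamped to `[0, 255]`.
#' @export
resize_for_embedding <- function(pixels, out_size = 224) {
  d <- dim(pixels)
  stopifnot(length(d) == 3L)
  if (any(d[1:2] < 200) || any(d[1:2] > 400)) {
    stop("input must be between 200 and 400 pixels in height and width, got ",
         d[1], "x", d[2])
  }
  if (d[1] == out_size && d[2] == out_size) return(pixels)
  Wr <- bilinear_weights(d[1], out_size)
  Wc <- bilinear_weights(d[2], out_size)
  out <- array(0, c(out_size, out_size, d[3]))
  for (ch in seq_len(d[3])) {
    out[, , ch] <- Wr %*% pixels[, , ch] %*% t(Wc)
  }
  clamp(out, 0, 255)
}

# Corner-aligned bilinear interpolation weights, n_out x n_in; rows sum to 1.
bilinear_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  if (n_in == 1) { W[, 1] <- 1; return(W) }
  src <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  i0 <- pmin(floor(src), n_in - 2)
  f <- src - i0
  for (r in seq_len(n_out)) {
    W[r, i0[r] + 1] <- W[r, i0[r] + 1] + (1 - f[r])
    W[r, i0[r] + 2] <- W[r, i0[r] + 2] + f[r]
  }
  W
}
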