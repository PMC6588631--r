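# Patch extraction, annotation-driven labeling, dihedral orientations, and
# the resize contract.

test_that("extract_patches tiles a level and drops incomplete tiles", {
  sl <- one_level_slide(noise_px(600))
  ps <- extract_patches(sl, "10x", size = 300, stride = 300)
  expect_length(ps, 4)
  origins <- t(vapply(ps, function(p) p$origin, c(0, 0)))
  expect_equal(origins, rbind(c(0, 0), c(300, 0), c(0, 300), c(300, 300)))

  # 599x599: only one complete tile remains
  ps1 <- extract_patches(one_level_slide(noise_px(599)), "10x", 300, 300)
  expect_length(ps1, 1)
  expect_equal(ps1[[1]]$origin, c(0, 0))

  # 900x300 with stride 150: origins 0,150,300,450,600
  ps2 <- extract_patches(one_level_slide(noise_px(300, 900)), "10x", 300, 150)
  expect_length(ps2, 5)
  expect_equal(vapply(ps2, function(p) p$origin[1], 0), c(0, 150, 300, 450, 600))

  expect_error(extract_patches(sl, "40x", 300), "absent")
})

test_that("patch pixels match their footprint on the source level", {
  px <- noise_px(600)
  ps <- extract_patches(one_level_slide(px), "10x", 300, 300)
  expect_identical(ps[[2]]$pixels, px[1:300, 301:600, , drop = FALSE])
  expect_identical(ps[[3]]$pixels, px[301:600, 1:300, , drop = FALSE])
})

test_that("non-overlap invariant holds when stride equals size", {
  ps <- extract_patches(one_level_slide(noise_px(900)), "10x", 300, 300)
  rects <- t(vapply(ps, function(p) c(p$origin, p$size * p$base_scale),
                    numeric(4)))
  for (i in seq_len(nrow(rects))) {
    for (j in seq_len(nrow(rects))) {
      if (i < j) {
        ox <- min(rects[i, 1] + rects[i, 3], rects[j, 1] + rects[j, 3]) -
          max(rects[i, 1], rects[j, 1])
        oy <- min(rects[i, 2] + rects[i, 4], rects[j, 2] + rects[j, 4]) -
          max(rects[i, 2], rects[j, 2])
        expect_true(ox <= 0 || oy <= 0)
      }
    }
  }
})

test_that("annotation regions yield labeled, sufficiently overlapping patches", {
  sl <- one_level_slide(noise_px(1200))
  artery <- annotation_region("slideA", "artery", x = 0, y = 0, w = 900, h = 900)
  ps <- patches_from_annotations(sl, list(artery), "10x", size = 300)
  expect_length(ps, 9)
  expect_true(all(vapply(ps, function(p) identical(p$labels, "artery"), TRUE)))

  # two overlapping regions above threshold each -> multi-label patch
  fat <- annotation_region("slideA", "fat", x = 0, y = 0, w = 300, h = 300)
  ps2 <- patches_from_annotations(sl, list(artery, fat), "10x", size = 300)
  first <- ps2[[which(vapply(ps2, function(p) all(p$origin == c(0, 0)), TRUE))]]
  expect_setequal(first$labels, c("artery", "fat"))

  # region covering only 50% of every candidate footprint -> no patches
  half <- annotation_region("slideA", "vein", x = 0, y = 0, w = 300, h = 150)
  expect_length(patches_from_annotations(sl, list(half), "10x", 300), 0)

  # region smaller than a footprint -> zero patches, not an error
  tiny <- annotation_region("slideA", "nerve", x = 10, y = 10, w = 50, h = 50)
  expect_length(patches_from_annotations(sl, list(tiny), "10x", 300), 0)
})

test_that("rectangular polygons behave like the equivalent rectangles", {
  sl <- one_level_slide(noise_px(1200))
  poly <- annotation_region("slideA", "stroma",
                            polygon = rbind(c(0, 0), c(900, 0),
                                            c(900, 600), c(0, 600)))
  rect <- annotation_region("slideA", "stroma", x = 0, y = 0, w = 900, h = 600)
  pp <- patches_from_annotations(sl, list(poly), "10x", 300)
  pr <- patches_from_annotations(sl, list(rect), "10x", 300)
  expect_equal(lapply(pp, function(p) p$origin), lapply(pr, function(p) p$origin))
  expect_length(pp, 6)
})

test_that("dihedral orientations enumerate the 2x2 transforms exactly", {
  m <- array(c(1, 3, 2, 4), c(2, 2, 1))  # rows: (1 2 / 3 4)
  o <- dihedral_orientations(m)
  as_rows <- function(a) as.vector(t(a[, , 1]))
  got <- lapply(o, as_rows)
  # brute-force expectation: R^k and R^k o M on [[a,b],[c,d]]
  expected <- list(c(1, 2, 3, 4),  # identity
                   c(2, 4, 1, 3),  # 90 ccw
                   c(4, 3, 2, 1),  # 180
                   c(3, 1, 4, 2),  # 270
                   c(2, 1, 4, 3),  # mirror
                   c(1, 3, 2, 4),  # mirror + 90
                   c(3, 4, 1, 2),  # mirror + 180
                   c(4, 2, 3, 1))  # mirror + 270
  expect_equal(got, expected)
})

test_that("dihedral group properties hold bit-exactly", {
  px <- noise_px(32, seed = 9)
  # orientation 2 applied twice is the identity
  expect_identical(apply_orientation(apply_orientation(px, 2), 2), px)
  # every orientation composed with its inverse recovers the input
  for (k in 0:7) {
    expect_identical(
      apply_orientation(apply_orientation(px, k), inverse_orientation(k)), px)
  }
  # constant patch: all 8 orientations identical
  oc <- dihedral_orientations(const_px(16))
  for (k in 2:8) expect_identical(oc[[k]], oc[[1]])
  expect_error(apply_orientation(noise_px(16, 20), 1), "square")
})

test_that("resize_for_embedding meets the bilinear contract", {
  # identity on 224 inputs (and hence idempotent)
  px <- noise_px(224)
  expect_identical(resize_for_embedding(px), px)
  # constants are preserved
  expect_equal(resize_for_embedding(const_px(300, value = 42)),
               const_px(224, value = 42))
  # a horizontal linear ramp keeps its endpoint values (corner alignment)
  ramp <- array(rep(seq(0, 255, length.out = 300), each = 300), c(300, 300, 3))
  r <- resize_for_embedding(ramp)
  expect_equal(dim(r), c(224, 224, 3))
  expect_equal(r[1, 1, 1], 0)
  expect_equal(r[5, 224, 2], 255)
  # interior of the ramp is still linear in column index
  expect_equal(r[10, , 1], seq(0, 255, length.out = 224), tolerance = 1e-12)
  # out-of-range inputs are rejected
  expect_error(resize_for_embedding(noise_px(150)), "200")
  expect_error(resize_for_embedding(noise_px(450)), "200")
})
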