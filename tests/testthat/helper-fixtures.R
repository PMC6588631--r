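# Shared test fixtures, built in code. Heavier objects are cached for the
# duration of the test run.

.hq_test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (is.null(.hq_test_cache[[key]])) .hq_test_cache[[key]] <- builder()
  .hq_test_cache[[key]]
}

# Deterministic noise pixels in [0, 255].
noise_px <- function(h, w = h, channels = 3, seed = 1) {
  set.seed(seed)
  array(runif(h * w * channels) * 255, c(h, w, channels))
}

const_px <- function(h, w = h, value = 100) {
  array(value, c(h, w, 3))
}

# Single-level slide at 10x from a pixel array.
one_level_slide <- function(px, slide_id = "slideA") {
  slide_image(slide_id, list("10x" = list(pixels = px, mpp = 1)))
}

# Small separable texture corpus (224 px patches; resize is identity), with
# a deterministic slide split. Shared across embedding/search tests.
separable_set <- function() {
  cache_get("separable_set", function() {
    spec <- fixture_spec(n_classes = 3, patches_per_cell = 8,
                         patch_size = 224, n_slides = 6, separability = 1.5,
                         label_purity = 1, seed = 5)
    generate_patch_set(spec)
  })
}

separable_db <- function() {
  cache_get("separable_db", function() {
    build_database(separable_set()$patches, default_embedder())
  })
}

# Raw-vector database: n records x 8 orientations of dimension d, with
# patch coordinates spaced far apart on distinct slides by default.
vector_db <- function(n, d, seed = 1, meta = NULL) {
  set.seed(seed)
  V <- matrix(rnorm(8 * n * d), 8 * n, d)
  db_from_vectors(V, meta = meta)
}

# Metadata frame for constructed search-filter databases.
collinear_meta <- function(n, spacing, slide_id = "s1", size = 300) {
  data.frame(record_id = seq_len(n), slide_id = slide_id,
             x = (seq_len(n) - 1) * spacing, y = 0, w = size, h = size,
             magnification = "10x", labels = "",
             stringsAsFactors = FALSE)
}
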