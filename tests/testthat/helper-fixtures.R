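# Shared fixtures, built once per test session on first use. The expensive
# ones (the 25x8 face-view set, the 200-face training set and its fitted face
# space) are reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# Full-cardinality 25-identity x 8-view stimulus set.
fv_set_full <- function() {
  cached_fixture("fv_full", make_face_view_set(25, seed = 7))
}

# 200 annotated frontal faces and the face space fitted on them.
annotated_frontal_200 <- function() {
  cached_fixture("ann200", make_annotated_face_dataset(200, "frontal", seed = 2))
}

face_space_200 <- function() {
  cached_fixture("fs200", fit_face_space(annotated_frontal_200()))
}

# A small untrained CNN for structural tests.
cnn_small <- function() {
  cached_fixture("cnn_small",
                 untrained_cnn_fixture(depth = 2, widths = c(6, 8), seed = 3))
}

# A metadata-only stimulus set carrying ground-truth feature vectors, for the
# designed linear units (no rasters are needed).
feature_stimulus_set <- function(features) {
  meta <- data.frame(image_id = seq_len(nrow(features)), category = "face")
  attr(meta, "feature_matrix") <- features
  stimulus_set(vector("list", nrow(features)), meta)
}

cosine_of <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
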