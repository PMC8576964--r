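# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# A tiny untrained detector model (deterministic init).
tiny_model <- function() memo("tiny_model", function() {
  wbc_model(default_config(tiny = TRUE, seed = 42))
})

# One deterministic tiny annotated image.
tiny_image <- function() memo("tiny_image", function() {
  generate_smear_image(smear_spec_tiny(seed = 7), image_id = 1L)
})

# A small on-disk training dataset (12 images) shared by train/CLI tests.
tiny_dataset_dir <- function() memo("tiny_dataset_dir", function() {
  dir <- file.path(tempdir(), "wbc_tiny_ds")
  if (!dir.exists(dir)) {
    generate_smear_dataset(smear_spec_tiny(seed = 19), 12L, dir)
  }
  dir
})

tiny_dataset <- function() memo("tiny_dataset", function() {
  read_coco(file.path(tiny_dataset_dir(), "annotations.json"))
})

# A quick low-resolution spec whose fields render in a few milliseconds
# (used where many images are needed, e.g. the augmentation count checks).
fast_spec <- function(seed = 1L) {
  cls <- default_cell_classes(size_scale = 0.18)
  for (nm in names(cls)) cls[[nm]]$lambda <- cls[[nm]]$lambda * 0.3
  smear_spec(width = 48, height = 48, classes = cls, seed = seed)
}
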