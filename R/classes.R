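#' The seven white-blood-cell classes
#'
#' The fixed foreground category table used throughout the package. Internal
#' class ids are 0-based (`0..6`) in this order; COCO category ids are the
#' 1-based equivalents (`1..7`). Background is an eighth, internal-only
#' category used by the classification head and never emitted in detections.
#'
#' @return Character vector of the 7 class names.
#' @export
wbc_classes <- function() {
  c("Granulocyte", "Erythrocyte", "Lymphocyte", "Megakaryocyte",
    "Plasma cell", "Monocyte", "Others")
}

#' Number of foreground classes
#' @return Integer, 7.
#' @export
n_wbc_classes <- function() length(wbc_classes())
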