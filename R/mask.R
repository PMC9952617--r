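#' Annotation vocabulary
#'
#' The fixed vocabulary of pathology annotation labels used on masks:
#' cancer cell nests and their stroma, DCIS nests and their stroma, fiber,
#' fat, normal mammary gland, and background (unannotated).  Index 0 is
#' background by convention.
#'
#' @return Character vector of the eight labels, in index order (0-based
#'   codes `0:7`).
#' @export
annotation_vocabulary <- function() {
  c("background", "cancer_nest", "cancer_stroma", "dcis", "dcis_stroma",
    "fiber", "fat", "normal_gland")
}

# map an annotation label to the phantom region context used by the
# peak library; background carries no peaks
label_region <- function(label) {
  map <- c(cancer_nest = "nest", dcis = "nest",
           cancer_stroma = "stroma", dcis_stroma = "stroma", fiber = "stroma",
           fat = "adipose", normal_gland = "normal", background = NA_character_)
  unname(map[label])
}

# stroma labels accepted for a diagnosis: DCIS accepts both stromal tags
stroma_labels <- function(diagnosis) {
  switch(diagnosis,
    IBC = "cancer_stroma",
    DCIS = c("dcis_stroma", "cancer_stroma"),
    config_error("unknown diagnosis '%s'", diagnosis)
  )
}

#' Construct an annotation mask
#'
#' @param labels Character matrix of annotation labels, or integer matrix of
#'   0-based codes into `vocabulary`.
#' @param vocabulary Label vocabulary (index order); defaults to
#'   [annotation_vocabulary()].
#' @return A `sers_mask`: integer code matrix plus its vocabulary.
#' @export
annotation_mask <- function(labels, vocabulary = annotation_vocabulary()) {
  if (!is.matrix(labels)) config_error("mask labels must be a matrix")
  if (is.character(labels)) {
    codes <- match(labels, vocabulary) - 1L
    if (anyNA(codes)) {
      bad <- unique(labels[is.na(codes)])
      data_error("unknown annotation label '%s'", bad[1])
    }
    codes <- matrix(codes, nrow(labels), ncol(labels))
  } else {
    codes <- labels
    storage.mode(codes) <- "integer"
    if (anyNA(codes) || any(codes < 0L) || any(codes >= length(vocabulary))) {
      data_error("mask contains label codes outside the declared vocabulary")
    }
  }
  structure(list(codes = codes, vocabulary = vocabulary), class = "sers_mask")
}

#' Label matrix of a mask
#'
#' @param mask A `sers_mask`.
#' @return Character matrix of annotation labels.
#' @export
mask_labels <- function(mask) {
  matrix(mask$vocabulary[mask$codes + 1L], nrow(mask$codes), ncol(mask$codes))
}

#' @export
dim.sers_mask <- function(x) dim(x$codes)

#' @export
print.sers_mask <- function(x, ...) {
  cat(sprintf("<sers_mask> %d x %d pixels\n", nrow(x$codes), ncol(x$codes)))
  tab <- table(factor(mask_labels(x), levels = x$vocabulary))
  tab <- tab[tab > 0]
  for (nm in names(tab)) cat(sprintf("  %-14s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Tidy a mask into per-pixel records
#'
#' @param x A `sers_mask`.
#' @param ... Unused.
#' @return Tibble with 0-based pixel coordinates `x`, `y` and `label`.
#' @export
as_tibble.sers_mask <- function(x, ...) {
  h <- nrow(x$codes); w <- ncol(x$codes)
  labels <- as.vector(mask_labels(x))
  tibble(
    x = rep(0:(w - 1L), each = h),
    y = rep(0:(h - 1L), times = w),
    label = labels
  )
}
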