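#' Tissue-layout parameters for synthetic phantoms
#'
#' Area fractions of the generated regions.  The remainder after nests,
#' fat and normal gland is stroma; fractions summing above 1 leave no
#' stroma and are rejected.
#'
#' @param nest_fraction Target area fraction of cancer (or DCIS) nests.
#' @param fat_fraction Target fraction of adipose patches at the margins.
#' @param normal_fraction Target fraction of normal mammary gland.
#' @param background_fraction Target fraction of unannotated background.
#' @param n_nests Number of nest blobs.
#' @return A named list of layout parameters.
#' @export
phantom_layout <- function(nest_fraction = 0.30, fat_fraction = 0.15,
                           normal_fraction = 0.05, background_fraction = 0,
                           n_nests = 3) {
  p <- list(nest_fraction = nest_fraction, fat_fraction = fat_fraction,
            normal_fraction = normal_fraction,
            background_fraction = background_fraction, n_nests = n_nests)
  if (any(unlist(p[1:4]) < 0)) config_error("layout fractions must be >= 0")
  if (sum(unlist(p[1:4])) >= 1) {
    config_error("layout fractions leave no stroma (sum %.2f >= 1)",
                 sum(unlist(p[1:4])))
  }
  if (n_nests < 1) config_error("need at least one nest blob")
  p
}

# grow one connected blob into pixels currently labelled `into`
grow_blob <- function(lab, target_n, into, code, seeds_idx) {
  h <- nrow(lab); w <- ncol(lab)
  if (target_n < 1) return(lab)
  start <- seeds_idx[lab[seeds_idx] == into]
  if (!length(start)) return(lab)
  cur <- if (length(start) == 1) start else sample(start, 1)
  lab[cur] <- code
  n <- 1L
  frontier <- integer(0)
  add_neighbours <- function(idx, frontier) {
    r <- (idx - 1L) %% h + 1L
    cc <- (idx - 1L) %/% h + 1L
    nb <- c(if (r > 1) idx - 1L, if (r < h) idx + 1L,
            if (cc > 1) idx - h, if (cc < w) idx + h)
    union(frontier, nb[lab[nb] == into])
  }
  frontier <- add_neighbours(cur, frontier)
  while (n < target_n && length(frontier)) {
    pick <- if (length(frontier) == 1) frontier else sample(frontier, 1)
    frontier <- setdiff(frontier, pick)
    if (lab[pick] != into) next
    lab[pick] <- code
    n <- n + 1L
    frontier <- add_neighbours(pick, frontier)
    frontier <- frontier[lab[frontier] == into]
  }
  lab
}

#' Generate a synthetic tissue phantom
#'
#' Produces a per-pixel region layout emulating an annotated lesion:
#' connected nest blobs embedded in stroma, adipose patches at the image
#' margins, and a small patch of normal gland.  For IBC phantoms the nests
#' are `cancer_nest` with `cancer_stroma`; for DCIS they are `dcis` with
#' `dcis_stroma`.  Deterministic per seed.
#'
#' @param shape Integer vector `c(height, width)`, at least 8 x 8.
#' @param diagnosis `"DCIS"` or `"IBC"`.
#' @param layout Layout parameters from [phantom_layout()].
#' @param seed Integer seed.
#' @param patient_id Optional patient identifier.
#' @return A `sers_phantom`: the annotation mask plus diagnosis and
#'   patient id.
#' @examples
#' ph <- make_phantom(c(16, 16), "IBC", seed = 1)
#' table(mask_labels(ph$mask))
#' @export
make_phantom <- function(shape, diagnosis = c("IBC", "DCIS"),
                         layout = phantom_layout(), seed = 1,
                         patient_id = NULL) {
  diagnosis <- match.arg(diagnosis)
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 8)) {
    config_error("phantom shape must be at least 8 x 8 pixels")
  }
  h <- shape[1]; w <- shape[2]
  npix <- h * w
  stroma_lab <- if (diagnosis == "IBC") "cancer_stroma" else "dcis_stroma"
  nest_lab <- if (diagnosis == "IBC") "cancer_nest" else "dcis"

  lab <- with_seed(seed, {
    lab <- matrix(stroma_lab, h, w)
    interior <- which(matrix(
      rep(seq_len(h), w) > 1 & rep(seq_len(h), w) < h &
        rep(seq_len(w), each = h) > 1 & rep(seq_len(w), each = h) < w, h, w))
    border <- setdiff(seq_len(npix), interior)
    # nests: connected blobs seeded in the interior
    per_nest <- round(layout$nest_fraction * npix / layout$n_nests)
    for (k in seq_len(layout$n_nests)) {
      lab <- grow_blob(lab, per_nest, stroma_lab, nest_lab, interior)
    }
    # adipose at the margins
    lab <- grow_blob(lab, round(layout$fat_fraction * npix), stroma_lab,
                     "fat", border)
    # small normal-gland patch
    if (layout$normal_fraction > 0) {
      lab <- grow_blob(lab, round(layout$normal_fraction * npix), stroma_lab,
                       "normal_gland", seq_len(npix))
    }
    if (layout$background_fraction > 0) {
      lab <- grow_blob(lab, round(layout$background_fraction * npix),
                       stroma_lab, "background", border)
    }
    lab
  })

  if (!any(lab == stroma_lab)) data_error("phantom layout left no stroma")
  structure(
    list(mask = annotation_mask(lab), diagnosis = diagnosis,
         patient_id = patient_id %||% sprintf("%s-00", diagnosis)),
    class = "sers_phantom"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sers_phantom <- function(x, ...) {
  cat(sprintf("<sers_phantom> %s patient %s\n", x$diagnosis, x$patient_id))
  print(x$mask)
  invisible(x)
}
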