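#' Tag spectra with their pathology annotation
#'
#' Joins a cube with its annotation mask: one record per non-background
#' pixel carrying the pixel coordinates, the annotation tag and the full
#' spectrum -- the flat `(x, y, tag, spectrum)` export format.
#'
#' @param cube A `sers_cube` (binned to the mask's grid).
#' @param mask A `sers_mask` of the same shape.
#' @return A `sers_tagged` tibble: columns `x`, `y` (0-based pixel
#'   coordinates), `tag`, and one `wn_*` column per channel; the axis,
#'   patient id and diagnosis ride along as attributes.
#' @export
tag_spectra <- function(cube, mask) {
  stopifnot(inherits(cube, "sers_cube"), inherits(mask, "sers_mask"))
  d <- dim(cube$intensities)
  if (!identical(d[1:2], dim(mask$codes))) {
    data_error("cube grid %d x %d does not match mask %d x %d",
               d[1], d[2], nrow(mask$codes), ncol(mask$codes))
  }
  labs <- as.vector(mask_labels(mask))
  keep <- labs != "background"
  mat <- spectra_matrix(cube)
  px <- tibble(
    x = rep(0:(d[2] - 1L), each = d[1]),
    y = rep(0:(d[1] - 1L), times = d[2]),
    tag = labs
  )[keep, ]
  spec <- as_tibble(mat[keep, , drop = FALSE], .name_repair = "minimal")
  names(spec) <- wn_col(cube$axis)
  out <- dplyr::bind_cols(px, spec)
  attr(out, "axis") <- cube$axis
  attr(out, "patient_id") <- cube$metadata$patient_id
  attr(out, "diagnosis") <- cube$metadata$diagnosis
  class(out) <- c("sers_tagged", class(out))
  out
}

tagged_axis <- function(table) {
  ax <- attr(table, "axis")
  if (is.null(ax)) ax <- wn_from_col(names(table)[is_wn_col(names(table))])
  ax
}

#' Write / read a tagged spectrum table
#'
#' Tab-separated text with a header row of wavenumbers, one record per
#' annotated pixel: `x`, `y`, `tag`, then the spectrum.  Intensities are
#' written with 6 significant digits, so round trips are lossless to that
#' precision.  Patient id and diagnosis are carried in `#`-comment lines.
#'
#' @param table A `sers_tagged` tibble.
#' @param path File path.
#' @return `write_tagged` returns `path` invisibly; `read_tagged` the
#'   parsed `sers_tagged` tibble.  Malformed rows raise an error naming
#'   the offending line.
#' @export
write_tagged <- function(table, path) {
  wn_cols <- names(table)[is_wn_col(names(table))]
  hdr <- c("x", "y", "tag", format(wn_from_col(wn_cols), trim = TRUE))
  spec <- as.matrix(table[, wn_cols])
  body <- paste(table$x, table$y, table$tag,
                apply(spec, 1, function(r) paste(sprintf("%.6g", r), collapse = "\t")),
                sep = "\t")
  if (!nrow(table)) body <- character(0)
  meta <- c(
    sprintf("# patient_id=%s", attr(table, "patient_id") %||% "NA"),
    sprintf("# diagnosis=%s", attr(table, "diagnosis") %||% "NA")
  )
  writeLines(c(meta, paste(hdr, collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname write_tagged
#' @export
read_tagged <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines)
  get_meta <- function(key) {
    m <- grep(sprintf("^# %s=", key), lines, value = TRUE)
    if (!length(m)) return(NULL)
    v <- sub(sprintf("^# %s=", key), "", m[1])
    if (v == "NA") NULL else v
  }
  body_at <- setdiff(seq_along(lines), meta)
  if (!length(body_at)) data_error("no header row in %s", path)
  hdr <- strsplit(lines[body_at[1]], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 4 || !identical(hdr[1:3], c("x", "y", "tag"))) {
    data_error("line %d: malformed header", body_at[1])
  }
  axis <- as.numeric(hdr[-(1:3)])
  if (anyNA(axis)) data_error("line %d: non-numeric wavenumber in header", body_at[1])
  nfield <- length(hdr)
  rows <- body_at[-1]
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    if (length(fields[[i]]) != nfield) {
      data_error("line %d: expected %d fields, got %d",
                 rows[i], nfield, length(fields[[i]]))
    }
  }
  vocab <- annotation_vocabulary()
  n <- length(fields)
  xs <- suppressWarnings(vapply(fields, function(f) as.integer(f[1]), integer(1)))
  ys <- suppressWarnings(vapply(fields, function(f) as.integer(f[2]), integer(1)))
  tags <- vapply(fields, `[[`, character(1), 3)
  spec <- suppressWarnings(
    t(vapply(fields, function(f) as.numeric(f[-(1:3)]), numeric(length(axis)))))
  if (n == 0) spec <- matrix(numeric(), 0, length(axis))
  bad <- which(is.na(xs) | is.na(ys) | rowSums(is.na(spec)) > 0)
  if (length(bad)) data_error("line %d: non-numeric value", rows[bad[1]])
  badtag <- which(!tags %in% vocab)
  if (length(badtag)) {
    data_error("line %d: unknown tag '%s'", rows[badtag[1]], tags[badtag[1]])
  }
  colnames(spec) <- wn_col(axis)
  out <- dplyr::bind_cols(
    tibble(x = xs, y = ys, tag = tags),
    as_tibble(spec)
  )
  attr(out, "axis") <- axis
  attr(out, "patient_id") <- get_meta("patient_id")
  attr(out, "diagnosis") <- get_meta("diagnosis")
  class(out) <- c("sers_tagged", class(out))
  out
}

#' Build the stromal region-of-interest mesh
#'
#' One mesh cell per stroma-labelled binned pixel: `cancer_stroma` for IBC
#' patients, and either `dcis_stroma` or `cancer_stroma` for DCIS
#' patients.  Each cell carries the patient's diagnosis as its class
#' label; the mesh is the unit of classification.
#'
#' @param mask A `sers_mask` on the binned grid.
#' @param diagnosis Patient diagnosis, `"DCIS"` or `"IBC"`.
#' @param patient_id Optional patient identifier to attach.
#' @return A `sers_mesh` tibble with `x`, `y`, `patient_id`, `diagnosis`.
#' @export
stroma_mesh <- function(mask, diagnosis, patient_id = NA_character_) {
  stopifnot(inherits(mask, "sers_mask"))
  ok <- stroma_labels(diagnosis)
  px <- as_tibble(mask)
  cells <- px[px$label %in% ok, c("x", "y")]
  if (!nrow(cells)) data_error("patient has no stroma ROI")
  out <- dplyr::mutate(cells, patient_id = patient_id, diagnosis = diagnosis)
  class(out) <- c("sers_mesh", class(out))
  out
}
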