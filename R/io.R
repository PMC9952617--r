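#' Read and write the cube container
#'
#' One self-describing container file per patient cube (R serialization
#' with a format tag and version), holding the intensity array, axis,
#' pixel pitch and metadata.
#'
#' @param cube A `sers_cube`.
#' @param path File path (conventionally `.rds`).
#' @return `write_cube` returns `path` invisibly; `read_cube` the cube.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "sers_cube"))
  saveRDS(list(format = "sers_cube", version = 1L, cube = cube), path)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sers_cube") || !identical(obj$version, 1L)) {
    data_error("%s is not a version-1 sers_cube container", path)
  }
  obj$cube
}

#' Read and write annotation masks
#'
#' Masks are stored as 8-bit grayscale indexed PNG (pixel value = label
#' code) with a JSON sidecar declaring the code-to-label vocabulary.
#' Reading a PNG containing a code absent from the sidecar is an error.
#'
#' @param mask A `sers_mask`.
#' @param path PNG path; the sidecar is `<path>.json`.
#' @return `write_mask` returns `path` invisibly; `read_mask` the mask.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "sers_mask"))
  png::writePNG(mask$codes / 255, path)
  jsonlite::write_json(
    list(vocabulary = setNames(as.list(mask$vocabulary),
                               seq_along(mask$vocabulary) - 1L)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  codes <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  side <- jsonlite::read_json(paste0(path, ".json"))
  vocab_idx <- as.integer(names(side$vocabulary))
  vocab <- unlist(side$vocabulary)
  declared <- sort(vocab_idx)
  undeclared <- setdiff(unique(as.vector(codes)), declared)
  if (length(undeclared)) {
    data_error("mask %s contains undeclared label index %d", path, undeclared[1])
  }
  # map to dense 0-based codes over the declared vocabulary order
  full <- character(max(declared) + 1L)
  full[vocab_idx + 1L] <- vocab
  annotation_mask(matrix(full[codes + 1L], nrow(codes), ncol(codes)),
                  vocabulary = unname(vocab[order(vocab_idx)]))
}

#' Read and write tabular artifacts as TSV
#'
#' @param table A data frame.
#' @param path TSV path.
#' @return `write_table_tsv` returns `path` invisibly; `read_table_tsv`
#'   the tibble.
#' @export
write_table_tsv <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
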