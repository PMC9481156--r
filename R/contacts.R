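## Cell-contact extraction from segmentation label images.

#' Contacts from a 2D label image
#'
#' Two segmented regions are in contact when they share more than one
#' boundary-adjacent pixel pair under 4-connectivity (a single touching
#' pixel pair is not a contact). Background is 0.
#'
#' @param labels Integer matrix; positive labels, 0 background.
#' @return A `data.table` with columns `cell_id_a`, `cell_id_b`
#'   (`a < b`, each pair once).
#' @export
contacts_from_labels <- function(labels) {
  m <- as.matrix(labels)
  if (any(m != round(m)) || any(m < 0)) stop("label image must contain non-negative integers")
  pairs <- rbind(
    cbind(as.vector(m[-nrow(m), ]), as.vector(m[-1, ])),
    cbind(as.vector(m[, -ncol(m)]), as.vector(m[, -1])))
  sel <- pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2]
  if (!any(sel)) return(data.table::data.table(cell_id_a = integer(), cell_id_b = integer()))
  a <- pmin(pairs[sel, 1], pairs[sel, 2])
  b <- pmax(pairs[sel, 1], pairs[sel, 2])
  cnt <- data.table::data.table(a = a, b = b)[, list(n = .N), by = c("a", "b")]
  cnt <- cnt[cnt$n > 1L, ]
  data.table::data.table(cell_id_a = as.integer(cnt$a), cell_id_b = as.integer(cnt$b))
}

#' Read a single-channel integer label image (TIFF or PNG)
#'
#' @param path Image path; format from the extension.
#' @return Integer matrix of labels.
#' @export
read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
                  tiff::readTIFF(path, as.is = TRUE)
                },
                png = {
                  if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required")
                  round(png::readPNG(path) * 65535)
                },
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  storage.mode(img) <- "integer"
  img
}
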