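## Tabular interchange formats: track tables and contact tables.
##
## A track table has one row per cell per frame with columns
##   frame cell_id parent_id fate area g1 [x y]
## (tab-separated, header row, '.' decimal). parent_id is -1 for cells that
## are not newborn daughters; a non-dividing cell keeps its cell_id across
## frames. fate uses the on-disk codes NB / DEL / DIV / CENSOR.
## A contact table lists unordered same-frame contact pairs once:
##   frame cell_id_a cell_id_b

.fate_levels <- c("NB", "Del", "Div", "Censored")
.fate_codes <- c(NB = "NB", DEL = "Del", DIV = "Div", CENSOR = "Censored")

fate_from_code <- function(x) {
  out <- .fate_codes[as.character(x)]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown fate code(s): ", paste(bad, collapse = ", "))
  }
  unname(out)
}

fate_to_code <- function(x) {
  names(.fate_codes)[match(x, .fate_codes)]
}

#' Read a cell track table
#'
#' Reads the tab-separated per-cell-per-frame table used as the package's
#' tracking interchange format. Required columns are `frame`, `cell_id`,
#' `parent_id` (-1 when the cell is not a newborn daughter), `fate`
#' (NB/DEL/DIV/CENSOR), `area` and `g1`; extra columns (for example `x`, `y`
#' centroids) are kept.
#'
#' @param path Path to a TSV file.
#' @return A `data.table` with fates converted to the canonical labels
#'   `NB`, `Del`, `Div`, `Censored`.
#' @export
read_track_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("frame", "cell_id", "parent_id", "fate", "area", "g1")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("track table missing column(s): ", paste(miss, collapse = ", "))
  dt$fate <- fate_from_code(dt$fate)
  dt
}

#' Write a cell track table
#'
#' @param tracks A data.frame/data.table with the canonical track columns;
#'   fates may be given as canonical labels or on-disk codes.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(tracks, path) {
  dt <- data.table::as.data.table(tracks)
  if (all(dt$fate %in% .fate_levels)) dt$fate <- fate_to_code(dt$fate)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a cell contact table
#'
#' @param path Path to a TSV with columns `frame`, `cell_id_a`, `cell_id_b`
#'   (unordered same-frame pairs, listed once).
#' @return A `data.table`.
#' @export
read_contact_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("frame", "cell_id_a", "cell_id_b")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("contact table missing column(s): ", paste(miss, collapse = ", "))
  dt
}

#' Write a cell contact table
#'
#' @param contacts A data.frame/data.table with columns `frame`, `cell_id_a`,
#'   `cell_id_b`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(contacts, path) {
  data.table::fwrite(data.table::as.data.table(contacts), path, sep = "\t")
  invisible(path)
}
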