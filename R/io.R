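#' @include IncidenceExperiment-methods.R
NULL

#' Read a site-by-species presence/absence matrix
#'
#' Reads a comma-separated incidence table. By default plots are rows and
#' species are columns (first column = plot id, header row = species ids);
#' `orientation = "species_rows"` accepts the transposed layout.
#'
#' @param path file path to a CSV file.
#' @param orientation `"plots_rows"` (default) or `"species_rows"`.
#' @return integer matrix, plots x species, with dimnames.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeIncidenceMatrix(matrix(c(1, 0, 0, 1), 2,
#'   dimnames = list(c("p1", "p2"), c("a", "b"))), f)
#' readIncidenceMatrix(f)
#' @export
readIncidenceMatrix <- function(path,
                                orientation = c("plots_rows", "species_rows")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop("duplicate identifier(s) in first column of ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m)))
    stop("duplicate identifier(s) in header of ", path)
  suppressWarnings(storage.mode(m) <- "numeric")
  bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-binary cell in %s at row '%s', column '%s'",
      path, ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- ids
  storage.mode(m) <- "integer"
  if (orientation == "species_rows") m <- t(m)
  m
}

#' Write a site-by-species matrix to CSV
#'
#' Inverse of [readIncidenceMatrix()] (bit-exact round trip): plots as rows,
#' species as columns, first column `plot_id`.
#'
#' @param x plots-by-species matrix or an [IncidenceExperiment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeIncidenceMatrix <- function(x, path) {
  if (methods::is(x, "IncidenceExperiment")) x <- incidence(x)
  df <- data.frame(plot_id = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plot metadata table
#'
#' Reads the CSV mapping plots to the nested design. Required columns:
#' `plot_id`, `location`, `elevation`, `habitat`; optional: `mat` (mean
#' annual temperature, degC), `map` (mean annual precipitation, mm/a).
#' Habitat labels are normalised to `OG`/`DE`/`SE`.
#'
#' @param path file path to a CSV file.
#' @return data.frame of plot records.
#' @export
readPlotMetadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "location", "elevation", "habitat")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("metadata file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$plot_id))
    stop("duplicate plot_id in ", path)
  meta$habitat <- as.character(normalizeHabitat(meta$habitat))
  meta
}

#' Read a species attribute table
#'
#' Required columns: `species_id`, `endemic` (logical, 0/1, or yes/no).
#'
#' @param path file path to a CSV file.
#' @return data.frame of species records.
#' @export
readSpeciesAttributes <- function(path) {
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "endemic") %in% colnames(sp)))
    stop("species file ", path, " needs columns species_id and endemic")
  if (anyDuplicated(sp$species_id))
    stop("duplicate species_id in ", path)
  e <- sp$endemic
  if (is.character(e))
    e <- tolower(trimws(e)) %in% c("1", "true", "yes", "y")
  sp$endemic <- as.logical(e)
  sp
}

#' Load a complete survey dataset
#'
#' Reads the incidence matrix, plot metadata and optional species attributes
#' and assembles a validated [IncidenceExperiment-class].
#'
#' @param matrix_path CSV incidence matrix (see [readIncidenceMatrix()]).
#' @param meta_path CSV plot metadata (see [readPlotMetadata()]).
#' @param species_path optional CSV species attributes.
#' @param orientation layout of the matrix file, see [readIncidenceMatrix()].
#' @return an [IncidenceExperiment-class].
#' @export
loadDataset <- function(matrix_path, meta_path, species_path = NULL,
                        orientation = c("plots_rows", "species_rows")) {
  m <- readIncidenceMatrix(matrix_path, orientation)
  meta <- readPlotMetadata(meta_path)
  species <- if (!is.null(species_path)) readSpeciesAttributes(species_path)
  IncidenceExperiment(m, meta, species)
}

#' Write a survey dataset to CSV files
#'
#' Writes `matrix.csv`, `meta.csv` and `species.csv` into a directory, in the
#' layouts the readers expect.
#'
#' @param x an [IncidenceExperiment-class].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeDataset <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeIncidenceMatrix(x, file.path(dir, "matrix.csv"))
  utils::write.csv(plotData(x), file.path(dir, "meta.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(speciesData(x), file.path(dir, "species.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
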