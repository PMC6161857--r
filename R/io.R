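#' Write / read an activity raster as CSV
#'
#' Neurons in rows, one column per timestep; the header row carries the
#' timestep indices and the first column the neuron ids. A `.gz` suffix
#' writes/reads through a gzip connection.
#'
#' @param raster An [activity_raster()].
#' @param path Output path (`.csv` or `.csv.gz`).
#' @return `write_raster_csv` returns `path` invisibly; `read_raster_csv`
#'   returns an [activity_raster()].
#' @export
write_raster_csv <- function(raster, path) {
  stopifnot(inherits(raster, "activity_raster"))
  df <- data.frame(neuron = raster$neuron_ids, raster$values,
                   check.names = FALSE)
  names(df) <- c("neuron", seq_len(ncol(raster$values)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_csv
#' @param dt Seconds per timestep to annotate the raster with.
#' @export
read_raster_csv <- function(path, dt = 1) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  df <- utils::read.csv(con, check.names = FALSE)
  activity_raster(as.matrix(df[, -1, drop = FALSE]), dt = dt,
                  neuron_ids = as.character(df[[1]]))
}

#' Write / read a dense weight matrix as CSV
#'
#' Full numeric precision is preserved (values are written with 17 significant
#' digits).
#'
#' @param w A numeric matrix (e.g. the EE block).
#' @param path Output path.
#' @export
write_weights_csv <- function(w, path) {
  utils::write.table(format(w, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_weights_csv
#' @export
read_weights_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}

#' Write / read the EE block in MatrixMarket format
#'
#' @param w A numeric matrix.
#' @param path Output path (`.mtx`).
#' @export
write_ee_mtx <- function(w, path) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(w), "generalMatrix"),
                              "CsparseMatrix"), path)
  invisible(path)
}

#' @rdname write_ee_mtx
#' @export
read_ee_mtx <- function(path) {
  as.matrix(Matrix::readMM(path))
}

#' Write / read an assembly set as JSON
#'
#' Format: `{"source": ..., "n_neurons": ..., "assemblies": [[i, ...], ...]}`
#' with 1-based neuron indices.
#'
#' @param aset An [assembly_set()].
#' @param path Output path (`.json`).
#' @export
write_assembly_json <- function(aset, path) {
  stopifnot(inherits(aset, "assembly_set"))
  jsonlite::write_json(list(source = aset$source,
                            n_neurons = aset$n_neurons,
                            assemblies = aset$assemblies),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_assembly_json
#' @export
read_assembly_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  assemblies <- if (is.matrix(x$assemblies))
    lapply(seq_len(nrow(x$assemblies)), function(i) x$assemblies[i, ])
  else as.list(x$assemblies)
  assembly_set(assemblies, n_neurons = x$n_neurons, source = x$source)
}
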