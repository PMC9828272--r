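# Readers and writers: comma-delimited trajectories, plain-text covariate
# rasters with a small header, field-map tables, and flat key = value run
# configuration files. Everything is plain text; inputs are assumed to be in
# planar coordinates already.

#' Read trajectories from a delimited text file
#'
#' The file must have a header with columns `id,time,x,y` (extra columns are
#' carried through). Rows are sorted by time within each individual;
#' duplicated timestamps within an individual are an error.
#'
#' @param path Path to a comma-delimited file.
#' @return A named list with one `data.frame` per individual, ordered by
#'   identifier, so the result is independent of row order in the file.
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "time", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trajectory file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$time)) || any(!is.finite(df$x)) ||
      any(!is.finite(df$y))) {
    stop("trajectory file ", path, " contains non-finite time/x/y values",
         call. = FALSE)
  }
  ids <- sort(unique(df$id))
  out <- lapply(ids, function(i) {
    tr <- df[df$id == i, , drop = FALSE]
    tr <- tr[order(tr$time), , drop = FALSE]
    dup <- which(diff(tr$time) == 0)
    if (length(dup)) {
      stop(sprintf("duplicated timestamp for id '%s' at time %g", i,
                   tr$time[dup[1] + 1]), call. = FALSE)
    }
    rownames(tr) <- NULL
    tr
  })
  names(out) <- as.character(ids)
  out
}

#' Write trajectories to a delimited text file
#'
#' @param trajectories A list of per-individual `data.frame`s (as returned by
#'   [read_trajectories()] or [simulate_crw()]), or a single `data.frame`
#'   with an `id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  df <- if (is.data.frame(trajectories)) trajectories else
    do.call(rbind, trajectories)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- covariate rasters -----------------------------------------------------

#' Read a gridded covariate raster from plain text
#'
#' The format is a small self-describing header followed by row-major values:
#' lines `x0`, `y0` (coordinates of the centre of the first cell), `cellsize`,
#' `nrow`, `ncol`, each as `key value`, then `nrow` lines of `ncol`
#' whitespace-separated numbers. Row r, column c is the cell centred at
#' `(x0 + (c-1) cellsize, y0 + (r-1) cellsize)`.
#'
#' @param path Path to the raster file.
#' @return A list with `x0`, `y0`, `cellsize`, `values` (nrow x ncol matrix),
#'   class `crwgp_raster`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  hdr <- list()
  for (k in 1:5) {
    kv <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    hdr[[kv[1]]] <- as.numeric(kv[2])
  }
  need <- c("x0", "y0", "cellsize", "nrow", "ncol")
  if (!all(need %in% names(hdr))) {
    stop("raster header must define: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  vals <- scan(text = paste(lines[-(1:5)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != hdr$nrow * hdr$ncol) {
    stop("raster ", path, " has ", length(vals), " values, expected ",
         hdr$nrow * hdr$ncol, call. = FALSE)
  }
  structure(list(x0 = hdr$x0, y0 = hdr$y0, cellsize = hdr$cellsize,
                 values = matrix(vals, hdr$nrow, hdr$ncol, byrow = TRUE)),
            class = "crwgp_raster")
}

#' Write a covariate raster to plain text
#'
#' @param raster A `crwgp_raster` (see [read_raster()] for the fields).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("x0", format(raster$x0, digits = 17)),
               paste("y0", format(raster$y0, digits = 17)),
               paste("cellsize", format(raster$cellsize, digits = 17)),
               paste("nrow", nrow(raster$values)),
               paste("ncol", ncol(raster$values))), con)
  utils::write.table(format(raster$values, digits = 17, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build a covariate stack from named rasters
#'
#' Covariates are standardised over their cells (zero mean, unit variance),
#' so downstream coefficients are per standard deviation of the covariate.
#' Lookups are nearest-cell and are clamped to the raster extent, so values
#' are defined everywhere in the plane.
#'
#' @param rasters Named list of `crwgp_raster` objects (or paths to raster
#'   files, which are read first).
#' @return An object of class `crwgp_covs`.
#' @export
covariate_stack <- function(rasters) {
  if (is.null(names(rasters)) || any(names(rasters) == "")) {
    stop("rasters must be a named list", call. = FALSE)
  }
  rasters <- lapply(rasters, function(r) {
    if (is.character(r)) read_raster(r) else r
  })
  stats_ <- lapply(rasters, function(r) {
    v <- as.numeric(r$values)
    s <- stats::sd(v)
    list(mean = mean(v), sd = if (is.finite(s) && s > 0) s else 1)
  })
  structure(list(rasters = rasters, stats = stats_), class = "crwgp_covs")
}

#' Look up standardised covariate values at locations
#'
#' @param covs A [covariate_stack()].
#' @param X Locations (matrix with two columns).
#' @return A `nrow(X) x n_covariates` matrix of standardised values, columns
#'   named after the covariates.
#' @export
covariate_lookup <- function(covs, X) {
  X <- .as_locations(X)
  out <- vapply(names(covs$rasters), function(nm) {
    r <- covs$rasters[[nm]]
    st <- covs$stats[[nm]]
    ci <- pmin(pmax(round((X[, 1] - r$x0) / r$cellsize) + 1, 1),
               ncol(r$values))
    ri <- pmin(pmax(round((X[, 2] - r$y0) / r$cellsize) + 1, 1),
               nrow(r$values))
    (r$values[cbind(ri, ci)] - st$mean) / st$sd
  }, numeric(nrow(X)))
  matrix(out, nrow = nrow(X),
         dimnames = list(NULL, names(covs$rasters)))
}

# --- field maps ------------------------------------------------------------

#' Write posterior field maps to a delimited text file
#'
#' @param maps A `data.frame` of class `crwgp_maps` as returned by
#'   [predict.crwgp()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_maps <- function(maps, path) {
  if (!is.data.frame(maps) || nrow(maps) == 0) {
    stop("'maps' must be a non-empty data.frame", call. = FALSE)
  }
  df <- as.data.frame(maps)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read posterior field maps written by [write_field_maps()]
#'
#' @param path Path to the file.
#' @return A `data.frame` of class `crwgp_maps`.
#' @export
read_field_maps <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("crwgp_maps", "data.frame")
  df
}

# --- flat key = value configuration ---------------------------------------

.config_keys <- function() {
  c(names(formals(crwgp_config)), names(formals(sim_config)),
    "input", "covariates", "out", "kernel", "time_unit")
}

#' Read a flat `key = value` configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Keys must belong to
#' the documented configuration vocabulary (the union of [crwgp_config()] and
#' [sim_config()] arguments plus file paths); unknown keys are an error.
#' Values that parse as numbers become numeric; comma-separated values become
#' vectors.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% .config_keys()) {
      stop("unknown configuration key: ", key, call. = FALSE)
    }
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(num))) num else val
  }
  out
}

#' Write a flat `key = value` configuration file
#'
#' @param config Named list of scalar or vector values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- config[!vapply(config, is.null, TRUE)]
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    v <- if (is.numeric(v)) paste(format(v, digits = 17), collapse = ", ")
         else paste(as.character(v), collapse = ", ")
    paste(k, "=", v)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
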