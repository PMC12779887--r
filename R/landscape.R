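#' @title Landscape grid for the managed grassland
#'
#' @description
#' The model landscape is a rectangular grid of 1-ha patches (100 m side).
#' Each patch carries an integer type code:
#' \itemize{
#'   \item \code{-1} roost site,
#'   \item \code{0} other (non-grassland, non-roost),
#'   \item \code{1} agricultural grassland in the scaring area,
#'   \item \code{2} agricultural grassland in the accommodation area,
#'   \item \code{3} (semi-)natural grassland in the nature area.
#' }
#' Grassland patches (types 1-3) additionally carry a grass height (m) and a
#' per-species ledger of cumulative flock-hours. Coordinates are 0-based
#' \code{(col, row)} with the origin at the top-left corner; distances are
#' Euclidean between cell centres in patch units (1 patch = 1 hm = 100 m).
#'
#' @name landscape
NULL

PATCH_CODES <- c(-1L, 0L, 1L, 2L, 3L)
GRASS_CODES <- c(1L, 2L, 3L)

#' Construct a landscape from a type matrix
#'
#' @param type_grid integer matrix (rows = grid rows, cols = grid columns) of
#'   patch type codes in \{-1, 0, 1, 2, 3\}.
#' @param species character vector of species names for the flock-hour
#'   ledgers (default the four study species).
#' @param initial_height initial grass height (m) on grassland cells.
#' @param patch_length side of a patch in metres.
#' @return An object of class \code{goose_landscape}: a list with the type
#'   matrix, grass-height matrix (NA off grassland), per-species flock-hour
#'   matrices, roost cell index, and grid metadata.
#' @export
new_landscape <- function(type_grid, species = SPECIES_CODES,
                          initial_height = 0.094, patch_length = 100) {
  if (!is.matrix(type_grid))
    stop("type_grid must be a matrix")
  storage.mode(type_grid) <- "integer"
  bad <- matrix(!(type_grid %in% PATCH_CODES), nrow(type_grid))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown patch type code %d at cell (col=%d, row=%d)",
                 type_grid[bad][1L], idx[2L] - 1L, idx[1L] - 1L))
  }
  grass <- type_grid %in% GRASS_CODES
  height <- matrix(NA_real_, nrow(type_grid), ncol(type_grid))
  height[grass] <- initial_height
  fh <- lapply(species, function(s)
    matrix(0, nrow(type_grid), ncol(type_grid)))
  names(fh) <- species
  structure(list(
    type = type_grid,
    height = height,
    flock_hours = fh,
    grazed_cm = matrix(0, nrow(type_grid), ncol(type_grid)),
    roost_index = which(type_grid == -1L),
    width = ncol(type_grid),
    height_patches = nrow(type_grid),
    patch_length = patch_length,
    initial_height = initial_height
  ), class = "goose_landscape")
}

#' @export
print.goose_landscape <- function(x, ...) {
  tab <- table(factor(x$type, levels = PATCH_CODES))
  cat(sprintf("<goose_landscape> %d x %d patches (%.0f m cells)\n",
              x$width, x$height_patches, x$patch_length))
  cat(sprintf("  roost %d | other %d | scaring %d | accommodation %d | nature %d\n",
              tab[["-1"]], tab[["0"]], tab[["1"]], tab[["2"]], tab[["3"]]))
  invisible(x)
}

## cell ids are 1-based matrix linear indices; user-facing coordinates are
## 0-based (col,row).
cell_id <- function(land, col, row) {
  if (any(col < 0L | col >= land$width | row < 0L | row >= land$height_patches))
    stop("cell outside grid bounds")
  as.integer(row + 1L + col * land$height_patches)
}

cell_colrow <- function(land, id) {
  id0 <- id - 1L
  cbind(col = id0 %/% land$height_patches, row = id0 %% land$height_patches)
}

#' Euclidean distance between two cells, in patch units
#'
#' Distances are computed between cell centres; multiply by
#' \code{patch_length} (100 m) to obtain metres.
#'
#' @param land a \code{goose_landscape}.
#' @param a,b cells, either as length-2 \code{c(col, row)} 0-based vectors or
#'   as linear cell ids.
#' @return distance in patches (real, non-negative, symmetric).
#' @export
cell_distance <- function(land, a, b) {
  a <- as_cell(land, a); b <- as_cell(land, b)
  unname(sqrt((a[1L] - b[1L])^2 + (a[2L] - b[2L])^2))
}

as_cell <- function(land, x) {
  if (length(x) == 1L) {
    cr <- cell_colrow(land, x)
    c(cr[1L, 1L], cr[1L, 2L])
  } else {
    if (x[1L] < 0 || x[1L] >= land$width || x[2L] < 0 ||
        x[2L] >= land$height_patches)
      stop("cell outside grid bounds")
    c(x[1L], x[2L])
  }
}

#' Cells of a given patch type
#'
#' @param land a \code{goose_landscape}.
#' @param type a patch type code in \{-1, 0, 1, 2, 3\}.
#' @return integer vector of linear cell ids with that code.
#' @export
cells_of_type <- function(land, type) {
  type <- as.integer(type)
  if (!(type %in% PATCH_CODES)) stop("unknown patch type code ", type)
  which(land$type == type)
}

#' Read a landscape from an ASCII grid file
#'
#' The on-disk format is an ESRI-ASCII-grid-style header (\code{ncols},
#' \code{nrows}, \code{xllcorner}, \code{yllcorner}, \code{cellsize},
#' \code{NODATA_value}) followed by \code{nrows} whitespace-separated rows of
#' integer type codes, top row first. Codes are validated against the patch
#' type alphabet; round-trips through \code{\link{write_landscape}} are
#' bit-exact on the codes.
#'
#' @param path file path.
#' @param ... passed to \code{\link{new_landscape}} (e.g.
#'   \code{initial_height}).
#' @return a \code{goose_landscape}.
#' @export
read_landscape <- function(path, ...) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows))
    stop("raster format error: missing ncols/nrows header")
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows)
    stop(sprintf("raster format error: expected %d data rows, found %d",
                 hdr$nrows, length(body)))
  rows <- lapply(body, function(l) {
    v <- suppressWarnings(as.integer(strsplit(trimws(l), "\\s+")[[1L]]))
    if (anyNA(v)) stop("raster format error: non-integer entry")
    v
  })
  n <- vapply(rows, length, integer(1L))
  if (any(n != hdr$ncols))
    stop(sprintf("raster format error: non-rectangular grid (row %d has %d of %d columns)",
                 which(n != hdr$ncols)[1L], n[n != hdr$ncols][1L], hdr$ncols))
  grid <- do.call(rbind, rows)
  new_landscape(grid, ...)
}

#' Write a landscape's type grid to an ASCII grid file
#'
#' @param land a \code{goose_landscape}.
#' @param path file path.
#' @export
write_landscape <- function(land, path) {
  hdr <- c(
    sprintf("ncols %d", land$width),
    sprintf("nrows %d", land$height_patches),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %d", as.integer(land$patch_length)),
    "NODATA_value -9999")
  body <- apply(land$type, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Export per-cell ledgers as a data frame
#'
#' One row per grid cell with 0-based coordinates, the type code, grass
#' height and the per-species flock-hour ledgers; suitable for CSV export.
#'
#' @param land a \code{goose_landscape}.
#' @return a data.frame with columns \code{cell_x}, \code{cell_y},
#'   \code{type}, \code{grass_height} and one \code{hours_<species>} column
#'   per species.
#' @export
landscape_table <- function(land) {
  ids <- seq_len(land$width * land$height_patches)
  cr <- cell_colrow(land, ids)
  out <- data.frame(cell_x = cr[, "col"], cell_y = cr[, "row"],
                    type = as.vector(land$type),
                    grass_height = as.vector(land$height))
  for (s in names(land$flock_hours))
    out[[paste0("hours_", s)]] <- as.vector(land$flock_hours[[s]])
  out
}
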