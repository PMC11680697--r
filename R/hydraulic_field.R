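#' Construct a raster flow scenario
#'
#' A flow scenario is one horizontal layer of a hydrodynamic model output,
#' discretised on a rectangular grid of square cells. Each cell carries the
#' longitudinal velocity `u` (m/s, positive downstream), transversal velocity
#' `v` (m/s, positive right-to-left bank), vertical velocity `w` (m/s,
#' positive upward) and turbulent kinetic energy `tke` (m^2/s^2). Dry or
#' out-of-channel cells are represented by `NA` in all four layers.
#'
#' The horizontal resultant (speed and heading) of every active cell is
#' precomputed from `u` and `v`; headings use the mathematical convention:
#' degrees counter-clockwise from the +u (downstream) axis, in `[0, 360)`.
#'
#' Internally cells are addressed as 1-based `(row, col)` matrix indices; row
#' increases along +v, column along +u. Cell `(row, col)` has its centre at
#' `x = (col - 0.5) * cell_size`, `y = (row - 0.5) * cell_size`.
#'
#' @param u,v,w,tke numeric matrices of equal dimension; `NA` marks absent
#'   cells and must coincide across all four.
#' @param cell_size cell edge length in metres (default 0.5).
#' @param discharge_q total discharge of the scenario, m^3/s (metadata).
#' @param bypass_fraction fraction of discharge routed past the intake,
#'   in `[0, 1]` (metadata only; not used by the simulator).
#' @param layer_index 1-based vertical plane index of the layer (default 2,
#'   the second plane below the surface, where smolts typically travel).
#' @param regions named list of logical matrices (same dimension as the grid)
#'   marking cell sets; the simulator requires `"intake"` and
#'   `"exit_boundary"` masks for fate accounting.
#' @return an object of class `flow_scenario`.
#' @seealso [load_scenario()], [flow_heading()], [resultant_flow()]
#' @export
flow_scenario <- function(u, v, w, tke, cell_size = 0.5, discharge_q = NA_real_,
                          bypass_fraction = NA_real_, layer_index = 2L,
                          regions = list()) {
  if (!is.matrix(u) || nrow(u) < 1L || ncol(u) < 1L)
    stop("grid must be a non-empty matrix", call. = FALSE)
  dims <- dim(u)
  for (nm in c("v", "w", "tke")) {
    m <- get(nm)
    if (!is.matrix(m) || !identical(dim(m), dims))
      stop("layer '", nm, "' does not match the grid dimensions", call. = FALSE)
  }
  absent <- is.na(u)
  for (m in list(v, w, tke)) {
    if (!identical(is.na(m), absent))
      stop("absent (NA) cells must coincide across u, v, w and tke", call. = FALSE)
  }
  if (all(absent)) stop("grid has no active cells", call. = FALSE)
  if (any(tke < 0, na.rm = TRUE)) stop("tke must be non-negative", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number", call. = FALSE)
  if (!is.list(regions) || (length(regions) && is.null(names(regions))))
    stop("regions must be a named list of logical masks", call. = FALSE)
  regions <- lapply(regions, function(msk) {
    if (!is.logical(msk) || !identical(dim(msk), dims))
      stop("every region mask must be a logical matrix of grid dimension",
           call. = FALSE)
    msk & !is.na(msk)
  })
  for (nm in intersect(c("intake", "exit_boundary"), names(regions))) {
    if (any(regions[[nm]] & absent))
      stop("region '", nm, "' covers absent cells", call. = FALSE)
  }

  res <- resultant_flow(u, v)
  structure(list(
    u = u, v = v, w = w, tke = tke,
    speed = matrix(res$speed, dims[1], dims[2]),
    heading = matrix(res$heading, dims[1], dims[2]),
    active = !absent,
    cell_size = cell_size,
    discharge_q = discharge_q,
    bypass_fraction = bypass_fraction,
    layer_index = as.integer(layer_index),
    regions = regions
  ), class = "flow_scenario")
}

#' @export
print.flow_scenario <- function(x, ...) {
  cat(sprintf("<flow_scenario> %d x %d cells (%.2f m), %d active\n",
              nrow(x$u), ncol(x$u), x$cell_size, sum(x$active)))
  cat(sprintf("  discharge Q = %s m^3/s, layer %d, regions: %s\n",
              format(x$discharge_q), x$layer_index,
              if (length(x$regions)) paste(names(x$regions), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Horizontal resultant of the flow
#'
#' Combines longitudinal and transversal velocity into the horizontal flow
#' vector: `speed = sqrt(u^2 + v^2)` and its bearing in degrees
#' counter-clockwise from the +u axis, in `[0, 360)`. A zero vector has
#' heading 0 by convention.
#'
#' @param u,v velocity components, m/s (vectorised).
#' @return list with numeric components `speed` and `heading`.
#' @examples
#' resultant_flow(1, 1)  # speed sqrt(2), heading 45
#' @export
resultant_flow <- function(u, v) {
  list(speed = sqrt(u^2 + v^2), heading = bearing_deg(u, v))
}

#' Flow heading at a cell
#'
#' @param scenario a [flow_scenario()].
#' @param cell integer `(row, col)` pair, 1-based.
#' @return heading in degrees, `[0, 360)`.
#' @export
flow_heading <- function(scenario, cell) {
  stopifnot(inherits(scenario, "flow_scenario"))
  r <- cell[[1]]; c <- cell[[2]]
  if (r < 1L || r > nrow(scenario$u) || c < 1L || c > ncol(scenario$u))
    stop("cell (", r, ", ", c, ") outside the grid", call. = FALSE)
  if (!scenario$active[r, c])
    stop("cell (", r, ", ", c, ") is not navigable water", call. = FALSE)
  scenario$heading[r, c]
}

# centre coordinates (metres) of cells; rows/cols 1-based, vectorised
cell_center <- function(scenario, row, col) {
  cs <- scenario$cell_size
  cbind(x = (col - 0.5) * cs, y = (row - 0.5) * cs)
}

# map metric coordinates to (row, col); may fall outside the grid
xy_to_cell <- function(scenario, x, y) {
  cs <- scenario$cell_size
  cbind(row = floor(y / cs) + 1L, col = floor(x / cs) + 1L)
}

# TRUE when (row, col) is inside the grid and active
cell_active <- function(scenario, row, col) {
  row >= 1L & row <= nrow(scenario$u) & col >= 1L & col <= ncol(scenario$u) &
    scenario$active[cbind(pmax(pmin(row, nrow(scenario$u)), 1L),
                          pmax(pmin(col, ncol(scenario$u)), 1L))]
}

# hydraulics of one cell as a named numeric vector
cell_hydraulics <- function(scenario, row, col) {
  c(u = scenario$u[row, col], v = scenario$v[row, col],
    w = scenario$w[row, col], tke = scenario$tke[row, col])
}

#' Read a flow scenario from its interchange files
#'
#' The field table is a CSV with header `x_index,y_index,u,v,w,tke` where
#' `x_index` (column, along +u) and `y_index` (row, along +v) are 0-based cell
#' indices; cells missing from the table are marked absent (dry). The
#' metadata JSON supplies `cell_size_m`, `discharge_q`, `bypass_fraction`,
#' `layer_index` and `regions` (region name to list of 0-based
#' `[row, col]` pairs).
#'
#' @param field_table_path path to the field CSV.
#' @param metadata_path path to the metadata JSON.
#' @return a [flow_scenario()].
#' @export
load_scenario <- function(field_table_path, metadata_path) {
  tab <- utils::read.csv(field_table_path)
  need <- c("x_index", "y_index", "u", "v", "w", "tke")
  if (!all(need %in% names(tab)))
    stop("field table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L) stop("field table is empty", call. = FALSE)
  if (anyDuplicated(tab[, c("x_index", "y_index")]))
    stop("duplicate (x_index, y_index) pairs in field table", call. = FALSE)
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)

  if (any(tab$x_index < 0) || any(tab$y_index < 0))
    stop("cell indices must be non-negative", call. = FALSE)
  # explicit dims preserve dry border rows/cols through a round trip
  nr <- max(tab$y_index + 1L, meta$n_rows %||% 0L)
  nc <- max(tab$x_index + 1L, meta$n_cols %||% 0L)
  mk <- function(vals) {
    m <- matrix(NA_real_, nr, nc)
    m[cbind(tab$y_index + 1L, tab$x_index + 1L)] <- vals
    m
  }
  regions <- list()
  if (!is.null(meta$regions)) {
    regions <- lapply(meta$regions, function(pairs) {
      msk <- matrix(FALSE, nr, nc)
      if (length(pairs)) {
        pairs <- matrix(as.integer(unlist(pairs)), ncol = 2L, byrow = !is.matrix(pairs))
        if (is.matrix(pairs) && ncol(pairs) == 2L) {
          if (any(pairs < 0L) || any(pairs[, 1] >= nr) || any(pairs[, 2] >= nc))
            stop("region mask references out-of-range cell indices", call. = FALSE)
          msk[pairs + 1L] <- TRUE
        }
      }
      msk
    })
  }
  flow_scenario(
    u = mk(tab$u), v = mk(tab$v), w = mk(tab$w), tke = mk(tab$tke),
    cell_size = meta$cell_size_m %||% 0.5,
    discharge_q = meta$discharge_q %||% NA_real_,
    bypass_fraction = meta$bypass_fraction %||% NA_real_,
    layer_index = meta$layer_index %||% 2L,
    regions = regions
  )
}

#' Write a flow scenario to its interchange files
#'
#' Inverse of [load_scenario()]: active cells only, 0-based indices, row-major
#' order. `load_scenario(write_scenario(s))` reproduces the field table.
#'
#' @param scenario a [flow_scenario()].
#' @param field_table_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_scenario <- function(scenario, field_table_path, metadata_path) {
  stopifnot(inherits(scenario, "flow_scenario"))
  idx <- which(t(scenario$active))  # row-major traversal
  nc <- ncol(scenario$u)
  col <- (idx - 1L) %% nc + 1L
  row <- (idx - 1L) %/% nc + 1L
  tab <- data.frame(
    x_index = col - 1L, y_index = row - 1L,
    u = scenario$u[cbind(row, col)], v = scenario$v[cbind(row, col)],
    w = scenario$w[cbind(row, col)], tke = scenario$tke[cbind(row, col)]
  )
  utils::write.csv(tab, field_table_path, row.names = FALSE, quote = FALSE)
  regions <- lapply(scenario$regions, function(msk) {
    ij <- which(msk, arr.ind = TRUE)
    unname(lapply(seq_len(nrow(ij)), function(k) c(ij[k, 1] - 1L, ij[k, 2] - 1L)))
  })
  meta <- list(cell_size_m = scenario$cell_size,
               n_rows = nrow(scenario$u), n_cols = ncol(scenario$u),
               discharge_q = scenario$discharge_q,
               bypass_fraction = scenario$bypass_fraction,
               layer_index = scenario$layer_index,
               regions = regions)
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(c(field_table_path, metadata_path))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
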