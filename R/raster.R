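#' Gridded environmental layer on a planar equal-area coordinate system
#'
#' A `raster_layer` is a rectangular grid of values with a stated cell side
#' length in km and a lower-left corner origin. Coordinates are planar km on
#' an idealized equal-area plane; there is no geodesy. Row 1 of the value
#' matrix is the southernmost (lowest-y) row and columns increase eastwards,
#' so the cell at `values[r, c]` has its centre at
#' `origin + (c - 0.5, r - 0.5) * cell_km`. Missing cells are `NA`.
#'
#' @param values numeric matrix of cell values (`NA` = nodata).
#' @param cell_km positive cell side length in km.
#' @param origin numeric length-2, (x0, y0) of the lower-left corner in km.
#' @param name layer name.
#' @param kind `"continuous"` or `"categorical"`. Categorical layers must
#'   contain only integer codes (or `NA`).
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, cell_km = 1, origin = c(0, 0),
                         name = "layer", kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have at least one row and one column", call. = FALSE)
  if (!is.numeric(cell_km) || length(cell_km) != 1L || cell_km <= 0)
    stop("`cell_km` must be a single positive number", call. = FALSE)
  if (length(origin) != 2L || !is.numeric(origin))
    stop("`origin` must be numeric of length 2", call. = FALSE)
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v)))
      stop("categorical layers may contain only integer codes or NA", call. = FALSE)
  }
  structure(list(values = values, cell_km = as.numeric(cell_km),
                 origin = as.numeric(origin), name = as.character(name),
                 kind = kind),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_layer> '%s' (%s): %d x %d cells of %g km",
              x$name, x$kind, nrow(x$values), ncol(x$values), x$cell_km))
  if (length(v))
    cat(sprintf(", range [%g, %g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' @export
dim.raster_layer <- function(x) dim(x$values)

#' @export
as.matrix.raster_layer <- function(x, ...) x$values

#' Stack of congruent raster layers
#'
#' All layers must share shape, cell size and origin, and layer names must
#' be unique. The stack holds the environmental predictors used throughout
#' the modelling pipeline.
#'
#' @param ... `raster_layer` objects, or a single list of them.
#' @return An object of class `env_stack` (a named list of layers).
#' @export
env_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "raster_layer"))
    layers <- layers[[1L]]
  if (!length(layers)) stop("an env_stack needs at least one layer", call. = FALSE)
  ok <- vapply(layers, inherits, logical(1), "raster_layer")
  if (!all(ok)) stop("all elements must be raster_layer objects", call. = FALSE)
  ref <- layers[[1L]]
  for (l in layers) {
    if (!identical(dim(l$values), dim(ref$values)) ||
        !isTRUE(all.equal(l$cell_km, ref$cell_km)) ||
        !isTRUE(all.equal(l$origin, ref$origin)))
      stop("layers are not congruent (shape, cell size and origin must match)",
           call. = FALSE)
  }
  nms <- vapply(layers, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("layer names must be unique", call. = FALSE)
  names(layers) <- nms
  structure(layers, class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x[[1L]]$values)
  cat(sprintf("<env_stack> %d layer(s), %d x %d cells of %g km\n",
              length(x), d[1L], d[2L], x[[1L]]$cell_km))
  for (l in x) cat("  ", format(l$name, width = 12), l$kind, "\n")
  invisible(x)
}

#' @rdname env_stack
#' @param stack an `env_stack`.
#' @export
layer_names <- function(stack) {
  vapply(unclass(stack), `[[`, character(1), "name")
}

#' Number of cells in a layer or stack
#' @param x a `raster_layer` or `env_stack`.
#' @return Integer cell count (rows x cols).
#' @export
n_cells <- function(x) {
  if (inherits(x, "env_stack")) x <- x[[1L]]
  as.integer(prod(dim(x$values)))
}

#' Cell centre coordinates
#'
#' Returns the planar (x, y) centre of every cell in column-major (R native)
#' order, matching `as.vector(layer$values)`.
#'
#' @param x a `raster_layer` or `env_stack`.
#' @return data.frame with columns `x`, `y` (km) and one row per cell.
#' @export
cell_centers <- function(x) {
  if (inherits(x, "env_stack")) x <- x[[1L]]
  nr <- nrow(x$values); nc <- ncol(x$values)
  data.frame(
    x = x$origin[1L] + (rep(seq_len(nc), each = nr) - 0.5) * x$cell_km,
    y = x$origin[2L] + (rep(seq_len(nr), times = nc) - 0.5) * x$cell_km
  )
}

#' Locate points on the grid
#'
#' Cell membership uses half-open intervals: a point belongs to the cell
#' `floor((coord - origin) / cell_km)` on each axis, so a point on a shared
#' interior edge is assigned to the cell on the larger-coordinate side.
#'
#' @param x,y point coordinates in km.
#' @param grid a `raster_layer` or `env_stack`.
#' @return Integer vector of 1-based linear (column-major) cell indices;
#'   `NA` for points outside the grid extent.
#' @export
point_to_cell <- function(x, y, grid) {
  if (inherits(grid, "env_stack")) grid <- grid[[1L]]
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((x - grid$origin[1L]) / grid$cell_km) + 1
  row <- floor((y - grid$origin[2L]) / grid$cell_km) + 1
  out <- (col - 1) * nr + row
  out[col < 1 | col > nc | row < 1 | row > nr] <- NA
  as.integer(out)
}

#' Extract layer values at cells
#'
#' @param stack an `env_stack`.
#' @param cells integer cell indices (column-major); default all cells.
#' @return data.frame, one column per layer, one row per cell.
#' @export
stack_values <- function(stack, cells = NULL) {
  vals <- lapply(unclass(stack), function(l) {
    v <- as.vector(l$values)
    if (is.null(cells)) v else v[cells]
  })
  as.data.frame(vals, optional = TRUE)
}

#' Cells with complete (non-nodata) data across a stack
#' @param stack an `env_stack`.
#' @return Integer vector of cell indices where no layer is `NA`.
#' @export
complete_cells <- function(stack) {
  ok <- !is.na(as.vector(stack[[1L]]$values))
  for (l in unclass(stack)[-1L]) ok <- ok & !is.na(as.vector(l$values))
  which(ok)
}

#' Write and read ESRI ASCII grids
#'
#' Plain-text grid exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows from north to south).
#' Cell size is in km, matching the package's planar coordinate system.
#'
#' @param layer a `raster_layer`.
#' @param path file path.
#' @param nodata sentinel written for `NA` cells.
#' @return `write_asc` returns `path` invisibly; `read_asc` a `raster_layer`.
#' @export
write_asc <- function(layer, path, nodata = -9999) {
  stopifnot(inherits(layer, "raster_layer"))
  v <- layer$values
  v[is.na(v)] <- nodata
  hdr <- c(paste("ncols", ncol(v)), paste("nrows", nrow(v)),
           paste("xllcorner", layer$origin[1L]),
           paste("yllcorner", layer$origin[2L]),
           paste("cellsize", layer$cell_km),
           paste("NODATA_value", nodata))
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L,
                paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_asc
#' @param name,kind layer metadata for the object read back.
#' @export
read_asc <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                     kind = "continuous") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- strsplit(trimws(hdr), "\\s+")
  h <- stats::setNames(as.numeric(vapply(kv, `[`, character(1), 2L)),
                       tolower(vapply(kv, `[`, character(1), 1L)))
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(vals, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[m == h[["nodata_value"]]] <- NA
  raster_layer(m, cell_km = h[["cellsize"]],
               origin = c(h[["xllcorner"]], h[["yllcorner"]]),
               name = name, kind = kind)
}

#' Write an environmental stack as one ASCII grid per layer
#' @param stack an `env_stack`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_stack_asc <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(unclass(stack), function(l)
    write_asc(l, file.path(dir, paste0(l$name, ".asc"))), character(1))
  invisible(paths)
}

#' Aggregate a stack to a coarser resolution
#'
#' The target cell size must be an integer multiple of the source cell size
#' (no interpolation is invented). Continuous layers are aggregated by the
#' mean of contributing source cells, categorical layers by the modal code
#' with ties broken toward the smallest code; a target cell is nodata only
#' when all its contributors are nodata. Partial blocks at the top/right
#' edges aggregate over the cells available.
#'
#' @param stack an `env_stack`.
#' @param target_cell_km target cell side length (km), >= source cell size.
#' @return A coarser `env_stack` with the same origin.
#' @export
resample_stack <- function(stack, target_cell_km) {
  src <- stack[[1L]]$cell_km
  if (target_cell_km < src)
    stop("target cell size must not be smaller than the source (no interpolation)",
         call. = FALSE)
  f <- target_cell_km / src
  if (abs(f - round(f)) > 1e-8)
    stop("target cell size must be an integer multiple of the source cell size",
         call. = FALSE)
  f <- as.integer(round(f))
  if (f == 1L) return(stack)
  agg <- function(l) {
    v <- l$values
    nr <- nrow(v); nc <- ncol(v)
    NR <- ceiling(nr / f); NC <- ceiling(nc / f)
    out <- matrix(NA_real_, NR, NC)
    for (R in seq_len(NR)) for (C in seq_len(NC)) {
      rows <- ((R - 1L) * f + 1L):min(R * f, nr)
      cols <- ((C - 1L) * f + 1L):min(C * f, nc)
      block <- v[rows, cols]
      block <- block[!is.na(block)]
      if (!length(block)) next
      out[R, C] <- if (l$kind == "categorical") {
        tab <- table(block)
        codes <- as.numeric(names(tab))
        min(codes[tab == max(tab)])            # tie -> smallest code
      } else mean(block)
    }
    raster_layer(out, cell_km = target_cell_km, origin = l$origin,
                 name = l$name, kind = l$kind)
  }
  env_stack(lapply(unclass(stack), agg))
}

#' Pearson correlation matrix among stack layers
#'
#' Computed over cells that are jointly non-nodata across all requested
#' layers, at the stack's own resolution. Categorical codes are treated
#' numerically if included (screening normally restricts to continuous
#' layers).
#'
#' @param stack an `env_stack`.
#' @param variables layer names to include (default: all continuous layers).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(stack, variables = NULL) {
  if (is.null(variables)) {
    kinds <- vapply(unclass(stack), `[[`, character(1), "kind")
    variables <- layer_names(stack)[kinds == "continuous"]
  }
  missing <- setdiff(variables, layer_names(stack))
  if (length(missing))
    stop("unknown layer(s): ", paste(missing, collapse = ", "), call. = FALSE)
  vals <- stack_values(stack)[variables]
  stats::cor(as.matrix(vals), use = "complete.obs")
}
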