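#' Gridded spatial layer
#'
#' A minimal raster container: a numeric matrix of cell values plus grid
#' geometry (lower-left corner and cell size). Continuous layers used by the
#' looking models (utilisation distribution, predator resource-selection
#' surface, encounter risk, familiarity) are kept on the unit interval by
#' [linear_stretch()]; the habitat layer holds integer codes into
#' [habitat_levels()].
#'
#' @param values numeric matrix of cell values (rows = northings, cols =
#'   eastings).
#' @param kind one of `"ud"`, `"familiarity"`, `"leopard_rsf"`,
#'   `"encounter_risk"`, `"habitat"`.
#' @param origin numeric length-2, x/y coordinate of the lower-left corner.
#' @param cellsize positive cell edge length.
#' @return An object of class `spatial_layer`.
#' @export
spatial_layer <- function(values, kind = "ud", origin = c(0, 0), cellsize = 1) {
  stopifnot(is.matrix(values), length(origin) == 2L, cellsize > 0)
  kind <- match.arg(kind,
    c("ud", "familiarity", "leopard_rsf", "encounter_risk", "habitat"))
  structure(list(values = values, kind = kind, origin = as.numeric(origin),
                 cellsize = as.numeric(cellsize)),
            class = "spatial_layer")
}

#' @export
print.spatial_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<spatial_layer '%s'> %d x %d cells, cellsize %g, range [%g, %g]\n",
              x$kind, nrow(v), ncol(v), x$cellsize,
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.spatial_layer <- function(x) dim(x$values)

#' Habitat category levels
#'
#' The eight habitat classes recorded at the end of each focal observation.
#' @return character vector of length 8.
#' @export
habitat_levels <- function() {
  c("forest", "woodland", "bush", "grassland", "rock", "camps", "farms", "roads")
}

same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$cellsize, b$cellsize))
}

#' Linear stretch of a layer onto [0, 1]
#'
#' Rescales cell values as `(v - min) / (max - min)` so the minimum maps to 0
#' and the maximum to 1, as used to turn a raw utilisation distribution into a
#' continuous familiarity surface. A constant layer is defined to stretch to
#' all zeros (the 0/0 case). `NA` cells (no-data) are passed through.
#'
#' @param layer a [spatial_layer()] or numeric vector/matrix.
#' @return object of the same type with values in [0, 1].
#' @export
linear_stretch <- function(layer) {
  if (inherits(layer, "spatial_layer")) {
    layer$values <- linear_stretch(layer$values)
    return(layer)
  }
  v <- layer
  ok <- !is.na(v)
  if (any(!is.finite(v[ok])))
    stop("linear_stretch: non-finite cell values")
  if (!any(ok)) return(v)
  rng <- range(v[ok])
  if (rng[1] == rng[2]) {
    v[ok] <- 0           # constant layer -> all zeros by convention
    return(v)
  }
  v[ok] <- (v[ok] - rng[1]) / (rng[2] - rng[1])
  v
}

#' Invert a stretched layer
#'
#' Maps `v -> 1 - v`, turning a familiarity surface into a risk-facing scale
#' (high = unfamiliar).
#' @inheritParams linear_stretch
#' @export
invert_layer <- function(layer) {
  if (inherits(layer, "spatial_layer")) {
    layer$values <- 1 - layer$values
    layer$kind <- "familiarity"
    return(layer)
  }
  1 - layer
}

#' Inter-group encounter risk surface
#'
#' Divides the stretched encounter distribution cellwise by the stretched
#' range-use (utilisation) distribution — a proxy for the probability of
#' meeting another group given the focal group's own use of the cell — and
#' stretches the result back onto [0, 1]. Cells never used by the group
#' (`range_ud == 0`) carry no information and are masked as no-data.
#'
#' @param encounter_ud stretched [spatial_layer()] of encounter intensity.
#' @param range_ud stretched [spatial_layer()] of the group's utilisation
#'   distribution, same geometry.
#' @return `spatial_layer` of kind `"encounter_risk"` with values in [0, 1]
#'   (NA where `range_ud` is 0).
#' @export
encounter_risk_layer <- function(encounter_ud, range_ud) {
  stopifnot(inherits(encounter_ud, "spatial_layer"),
            inherits(range_ud, "spatial_layer"))
  if (!same_geometry(encounter_ud, range_ud))
    stop("encounter_risk_layer: layer geometries differ")
  e <- encounter_ud$values
  u <- range_ud$values
  bad <- range(c(e, u), na.rm = TRUE)
  if (bad[1] < 0 || bad[2] > 1)
    stop("encounter_risk_layer: inputs must be stretched to [0, 1] first")
  r <- e / u
  r[!is.na(u) & u == 0] <- NA_real_
  out <- spatial_layer(linear_stretch(r), kind = "encounter_risk",
                       origin = encounter_ud$origin,
                       cellsize = encounter_ud$cellsize)
  out
}

#' Combine predator selection surfaces across scales
#'
#' Integrates second- and third-order resource selection surfaces into one
#' relative-risk layer. The default combiner multiplies the two stretched
#' surfaces cellwise and re-stretches (a cell is risky only if selected at
#' both scales); `method = "mean"` averages instead. The combiner is
#' deliberately pluggable because published scale-integration recipes vary.
#'
#' @param rsf2,rsf3 stretched [spatial_layer()]s on the same grid.
#' @param method `"product"` (default) or `"mean"`.
#' @return `spatial_layer` of kind `"leopard_rsf"` on [0, 1].
#' @export
integrate_rsf <- function(rsf2, rsf3, method = c("product", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(rsf2, "spatial_layer"), inherits(rsf3, "spatial_layer"))
  if (!same_geometry(rsf2, rsf3)) stop("integrate_rsf: layer geometries differ")
  v <- switch(method,
              product = rsf2$values * rsf3$values,
              mean    = (rsf2$values + rsf3$values) / 2)
  spatial_layer(linear_stretch(v), kind = "leopard_rsf",
                origin = rsf2$origin, cellsize = rsf2$cellsize)
}

#' Familiarity class of a utilisation-distribution value
#'
#' Classifies locations as `core`, `frequent` or `boundary` by isopleths
#' placed at thirds of the cumulative utilisation mass: the most-used cells
#' jointly holding the top third of total use are core, the next third
#' frequent, the rest boundary. A location drawn at random in proportion to
#' use therefore falls in each class with probability ~1/3.
#'
#' @param ud_value numeric vector of stretched UD values to classify.
#' @param layer the stretched UD [spatial_layer()] defining the isopleths.
#' @return factor with levels `core`, `frequent`, `boundary`.
#' @export
familiarity_class <- function(ud_value, layer) {
  stopifnot(inherits(layer, "spatial_layer"))
  if (any(ud_value < 0 | ud_value > 1, na.rm = TRUE))
    stop("familiarity_class: ud_value outside [0, 1]")
  th <- familiarity_thresholds(layer)
  cls <- ifelse(ud_value >= th[1], "core",
         ifelse(ud_value >= th[2], "frequent", "boundary"))
  factor(cls, levels = c("core", "frequent", "boundary"))
}

# Cell-value thresholds such that cells with value >= th[1] hold >= 1/3 of the
# total utilisation mass and cells >= th[2] hold >= 2/3.
familiarity_thresholds <- function(layer) {
  v <- as.vector(layer$values)
  v <- v[!is.na(v)]
  tot <- sum(v)
  if (tot <= 0) return(c(0, 0))   # degenerate flat layer: everything core
  o <- order(v, decreasing = TRUE)
  cm <- cumsum(v[o]) / tot
  t1 <- v[o][which(cm >= 1 / 3)[1]]
  t2 <- v[o][which(cm >= 2 / 3)[1]]
  c(t1, t2)
}

#' Look up layer values at grid coordinates
#'
#' @param layer a [spatial_layer()].
#' @param row,col integer cell indices (1-based).
#' @return numeric vector of cell values.
#' @export
layer_lookup <- function(layer, row, col) {
  layer$values[cbind(row, col)]
}

# --- ESRI ASCII grid I/O (no raster package required) -----------------------

#' Write a layer as an ESRI ASCII grid
#'
#' @param layer a [spatial_layer()].
#' @param path output file path (conventionally `.asc`).
#' @export
write_asc <- function(layer, path) {
  v <- layer$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", layer$origin[1]),
    sprintf("yllcorner %.10g", layer$origin[2]),
    sprintf("cellsize %.10g", layer$cellsize),
    "NODATA_value -9999"), con)
  # ASCII grids run north to south: first data row is the top matrix row
  out <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  out[is.na(out)] <- -9999
  writeLines(apply(out, 1L, function(r) paste(sprintf("%.10g", r), collapse = " ")),
             con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param kind layer kind to stamp on the result.
#' @return a [spatial_layer()].
#' @export
read_asc <- function(path, kind = "ud") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]   # back to south-up storage
  spatial_layer(m, kind = kind,
                origin = c(hdr$xllcorner, hdr$yllcorner),
                cellsize = hdr$cellsize)
}

# Repeated 3x3 box smoothing with reflecting edges; used by the landscape
# generator to obtain spatially autocorrelated surfaces.
smooth_matrix <- function(m, passes = 2L) {
  n <- nrow(m); p <- ncol(m)
  for (k in seq_len(passes)) {
    up    <- m[c(1L, seq_len(n - 1L)), , drop = FALSE]
    down  <- m[c(seq_len(n)[-1L], n), , drop = FALSE]
    left  <- m[, c(1L, seq_len(p - 1L)), drop = FALSE]
    right <- m[, c(seq_len(p)[-1L], p), drop = FALSE]
    m <- (m + up + down + left + right) / 5
  }
  m
}
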