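# Region polygons: areas by the shoelace formula, point-in-polygon region
# assignment, and region volumes from per-slice areas.

#' Construct a region outline polygon
#'
#' A closed 2D outline of one region on one atlas plate, supplied by the
#' user in place of atlas boundary data.
#'
#' @param acronym region code, e.g. "dDG".
#' @param vertices numeric matrix (or data frame) with columns x, y in um,
#'   at least 3 vertices; the polygon is closed implicitly.
#' @param hemisphere one of "left", "right", "both".
#' @param ap_mm anterior-posterior coordinate of the plate in mm.
#' @return object of class `region_polygon`.
#' @export
region_polygon <- function(acronym, vertices,
                           hemisphere = c("both", "left", "right"),
                           ap_mm = NA_real_) {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)[, 1:2, drop = FALSE]
  abort_if(nrow(vertices) < 3, "a polygon needs at least 3 vertices")
  abort_if(polygon_area(vertices) == 0, "polygon has zero area")
  structure(list(acronym = acronym, vertices = unname(vertices),
                 hemisphere = hemisphere, ap_mm = ap_mm),
            class = "region_polygon")
}

#' Polygon area by the shoelace (Gauss) formula
#'
#' Absolute value of the signed shoelace sum; independent of vertex
#' orientation.
#'
#' @param vertices matrix with columns x, y (um), at least 3 rows.
#' @return area in um^2.
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)[, 1:2, drop = FALSE]
  abort_if(nrow(v) < 3, "a polygon needs at least 3 vertices")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# Even-odd point-in-polygon with boundary counting as inside.
# pts: n x 2, verts: m x 2. Returns logical n.
point_in_polygon <- function(pts, verts) {
  n <- nrow(pts)
  if (n == 0) return(logical(0))
  m <- nrow(verts)
  x <- pts[, 1]; y <- pts[, 2]
  inside <- logical(n)
  on_edge <- logical(n)
  j <- m
  for (i in seq_len(m)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    # boundary test: point on segment (i, j)
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    within <- pmin(xi, xj) - 1e-9 <= x & x <= pmax(xi, xj) + 1e-9 &
      pmin(yi, yj) - 1e-9 <= y & y <= pmax(yi, yj) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-9 * (abs(xj - xi) + abs(yj - yi) + 1) &
                            within)
    # even-odd crossing test
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Assign points to region polygons
#'
#' Even-odd point-in-polygon with the boundary counting as inside. A point
#' contained in several polygons is assigned to the first-listed one, so
#' callers should order child regions before their parents when outlines
#' nest.
#'
#' @param points matrix (or data frame) with columns x, y in um.
#' @param polygons list of [region_polygon()]s for one slice/plate.
#' @return character vector of region acronyms, `NA` where a point falls in
#'   no polygon.
#' @export
assign_regions <- function(points, polygons) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0) return(character(0))
  pts <- pts[, 1:2, drop = FALSE]
  out <- rep(NA_character_, nrow(pts))
  todo <- rep(TRUE, nrow(pts))
  for (poly in polygons) {
    stopifnot(inherits(poly, "region_polygon"))
    if (!any(todo)) break
    hit <- point_in_polygon(pts[todo, , drop = FALSE], poly$vertices)
    out[which(todo)[hit]] <- poly$acronym
    todo[which(todo)[hit]] <- FALSE
  }
  out
}

#' Region volume from per-slice areas
#'
#' Volume = sum of the per-slice areas times the imaged section thickness,
#' converted from um^3 to mm^3.
#'
#' @param areas numeric vector of per-slice areas in um^2.
#' @param z_thickness imaged z-thickness per slice in um (default 9, a
#'   typical confocal stack depth).
#' @return volume in mm^3.
#' @export
region_volume <- function(areas, z_thickness = 9) {
  abort_if(!(z_thickness > 0), "`z_thickness` must be positive")
  abort_if(any(areas < 0), "areas must be nonnegative")
  sum(areas) * z_thickness / 1e9
}

#' Read region polygons from CSV
#'
#' Expected columns: acronym, hemisphere, ap_mm, vertex_index, x_um, y_um.
#' Vertices are ordered by `vertex_index` within each
#' (acronym, hemisphere, ap_mm) group.
#'
#' @param path CSV file.
#' @return list of [region_polygon()]s in file order.
#' @export
read_polygons_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("acronym", "hemisphere", "ap_mm", "vertex_index", "x_um", "y_um")
  missing <- setdiff(need, names(df))
  abort_if(length(missing) > 0,
           paste("polygon CSV is missing columns:",
                 paste(missing, collapse = ", ")))
  keys <- unique(df[, c("acronym", "hemisphere", "ap_mm")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- dplyr::semi_join(df, keys[i, ],
                            by = c("acronym", "hemisphere", "ap_mm"))
    sub <- sub[order(sub$vertex_index), ]
    region_polygon(keys$acronym[i], cbind(sub$x_um, sub$y_um),
                   hemisphere = keys$hemisphere[i], ap_mm = keys$ap_mm[i])
  })
}
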