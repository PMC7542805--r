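#' 100% minimum convex polygon (convex hull) of a point set
#'
#' The classical home-range estimator: the smallest convex polygon
#' containing all locations.
#'
#' @param points tibble/data frame with `x_km`, `y_km`, or a 2-column
#'   matrix.
#' @return a 2-column matrix of hull vertices (`x_km`, `y_km`) in
#'   counter-clockwise order, not closed.
#' @export
#' @examples
#' compute_mcp(cbind(c(0, 1, 0, 1, 0.5), c(0, 0, 1, 1, 0.5)))
compute_mcp <- function(points) {
  xy <- as_xy_matrix(points)
  if (nrow(xy) < 3) stop_cfg("need at least 3 points for an MCP")
  h <- grDevices::chull(xy)
  if (length(h) < 3) stop_cfg("points are collinear; MCP is degenerate")
  poly <- xy[h, , drop = FALSE]
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  if (polygon_area(poly) <= 1e-12)
    stop_cfg("points are collinear; MCP is degenerate")
  colnames(poly) <- c("x_km", "y_km")
  poly
}

as_xy_matrix <- function(points) {
  if (is.matrix(points)) return(unname(points[, 1:2, drop = FALSE]))
  cbind(points$x_km, points$y_km)
}

#' Signed (shoelace) area of a polygon
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param poly 2-column vertex matrix (open ring).
#' @return signed area in squared coordinate units.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Buffer (Minkowski-dilate) a convex polygon by a disc
#'
#' Offsets every edge outward by `dist_km` and joins the offsets with
#' polygonal circular arcs at the vertices, giving the standard home-range
#' buffer (e.g. 300 km around an MCP). The arc approximation uses
#' `arc_segments` segments per full circle.
#'
#' @param poly 2-column convex vertex matrix, counter-clockwise.
#' @param dist_km buffer distance, km (>= 0).
#' @param arc_segments segments per full circle (>= 64).
#' @return buffered vertex matrix, counter-clockwise.
#' @export
buffer_polygon <- function(poly, dist_km, arc_segments = 128) {
  if (dist_km < 0) stop_cfg("`dist_km` must be >= 0")
  if (dist_km == 0) return(poly)
  arc_segments <- max(64, arc_segments)
  n <- nrow(poly)
  if (polygon_area(poly) < 0) stop_cfg("polygon must be counter-clockwise")
  nxt <- c(2:n, 1)
  prv <- c(n, 1:(n - 1))
  out <- list()
  for (k in seq_len(n)) {
    # outward unit normals of the incoming and outgoing edges at vertex k
    e_in <- poly[k, ] - poly[prv[k], ]
    e_out <- poly[nxt[k], ] - poly[k, ]
    n_in <- c(e_in[2], -e_in[1]) / sqrt(sum(e_in^2))
    n_out <- c(e_out[2], -e_out[1]) / sqrt(sum(e_out^2))
    a1 <- atan2(n_in[2], n_in[1])
    a2 <- atan2(n_out[2], n_out[1])
    sweep <- (a2 - a1) %% (2 * pi)
    nseg <- max(1L, ceiling(arc_segments * sweep / (2 * pi)))
    ang <- a1 + sweep * seq(0, 1, length.out = nseg + 1)
    arc <- cbind(poly[k, 1] + dist_km * cos(ang),
                 poly[k, 2] + dist_km * sin(ang))
    out[[k]] <- arc
  }
  res <- do.call(rbind, out)
  colnames(res) <- c("x_km", "y_km")
  res
}

#' Test whether points lie inside a polygon
#'
#' @param poly 2-column vertex matrix (open ring).
#' @param points tibble with `x_km`, `y_km` or 2-column matrix.
#' @return logical vector.
#' @export
points_in_polygon <- function(poly, points) {
  ring <- rbind(poly, poly[1, ])
  mgcv::in.out(ring, as_xy_matrix(points))
}

#' Sample uniform background points inside a polygon
#'
#' Rejection sampling from the bounding box; the availability sample used
#' to characterize the environments accessible to a flyway (conventionally
#' 10 000 points inside the 300-km-buffered MCP).
#'
#' @param poly 2-column vertex matrix.
#' @param n number of points (>= 1).
#' @param seed integer seed; the point set is deterministic given the seed.
#' @return tibble with `point_id`, `x_km`, `y_km`, all inside `poly`.
#' @export
sample_background <- function(poly, n = 10000, seed = 1L) {
  if (n < 1) stop_cfg("`n` must be >= 1")
  area <- abs(polygon_area(poly))
  if (area <= 1e-12) stop_cfg("polygon has zero area")
  bbox <- c(range(poly[, 1]), range(poly[, 2]))
  box_area <- (bbox[2] - bbox[1]) * (bbox[4] - bbox[3])
  xs <- numeric(0); ys <- numeric(0)
  with_substream(substream_seed(seed, "background"), {
    while (length(xs) < n) {
      m <- ceiling(1.3 * (n - length(xs)) * box_area / area) + 100
      cx <- runif(m, bbox[1], bbox[2])
      cy <- runif(m, bbox[3], bbox[4])
      ok <- points_in_polygon(poly, cbind(cx, cy))
      xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
    }
  })
  tibble::tibble(point_id = seq_len(n), x_km = xs[seq_len(n)],
                 y_km = ys[seq_len(n)])
}

#' Write a polygon as WKT
#'
#' @param poly 2-column vertex matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_polygon_wkt <- function(poly, path) {
  ring <- rbind(poly, poly[1, ])
  wkt <- sprintf("POLYGON ((%s))",
                 paste(sprintf("%.6f %.6f", ring[, 1], ring[, 2]),
                       collapse = ", "))
  writeLines(wkt, path)
  invisible(path)
}
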