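# Planar geometry for LA polygons: alpha-shape concave hulls, Minkowski
# buffering with round joins, point-in-polygon tests. Coordinates are planar
# micrometres, y increasing upward; all containment tests are
# boundary-inclusive.

.shoelace <- function(x, y) {
  n <- length(x)
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Polygon region
#'
#' A single closed, non-self-intersecting ring in planar micrometres, stored
#' open (first vertex not repeated) and oriented counter-clockwise.
#'
#' @param x,y Vertex coordinates (the first vertex is not repeated at the
#'   end; trailing duplicates are removed).
#' @param label Optional label, e.g. `"tumor_bed"` or `"LA"`.
#' @param check_simple Verify the ring is non-self-intersecting (O(m^2);
#'   internal constructors skip it for rings produced by the clipper).
#' @return An object of class `region_polygon`: a list with `x`, `y`,
#'   `label` and an `area` (um^2).
#' @export
#' @examples
#' region_polygon(c(0, 100, 100, 0), c(0, 0, 100, 100))
region_polygon <- function(x, y, label = NULL, check_simple = TRUE) {
  stopifnot(length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("region_polygon: coordinates must be finite")
  }
  n <- length(x)
  if (n >= 2L && x[1] == x[n] && y[1] == y[n]) { # accept closed input
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  keep <- c(TRUE, x[-1] != x[-n] | y[-1] != y[-n])
  x <- x[keep]; y <- y[keep]
  if (length(unique(complex(real = x, imaginary = y))) < 3L) {
    stop("region_polygon: need at least 3 distinct vertices")
  }
  a <- .shoelace(x, y)
  if (abs(a) < .Machine$double.eps) stop("region_polygon: degenerate (zero area)")
  if (a < 0) { x <- rev(x); y <- rev(y); a <- -a }
  if (check_simple && .ring_self_intersects(x, y)) {
    stop("region_polygon: ring is self-intersecting")
  }
  structure(list(x = x, y = y, label = label, area = a),
            class = "region_polygon")
}

#' @export
print.region_polygon <- function(x, ...) {
  cat(sprintf("<region_polygon%s: %d vertices, area %.1f um^2>\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$x), x$area))
  invisible(x)
}

# does the open ring (x, y) self-intersect? Adjacent edges may share their
# common endpoint only.
.ring_self_intersects <- function(x, y) {
  n <- length(x)
  nx <- c(x[-1], x[1]); ny <- c(y[-1], y[1])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)] # skip edges adjacent to i
    if (!length(js)) next
    o1 <- orient(x[i], y[i], nx[i], ny[i], x[js], y[js])
    o2 <- orient(x[i], y[i], nx[i], ny[i], nx[js], ny[js])
    o3 <- orient(x[js], y[js], nx[js], ny[js], x[i], y[i])
    o4 <- orient(x[js], y[js], nx[js], ny[js], nx[i], ny[i])
    if (any(o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0)) {
      return(TRUE)
    }
  }
  FALSE
}

# circumradius of triangle (robust to near-degenerate: returns Inf)
.circumradius <- function(ax, ay, bx, by, cx, cy) {
  a <- sqrt((bx - cx)^2 + (by - cy)^2)
  b <- sqrt((ax - cx)^2 + (ay - cy)^2)
  ca <- sqrt((ax - bx)^2 + (ay - by)^2)
  k <- abs((bx - ax) * (cy - ay) - (by - ay) * (cx - ax)) / 2
  if (k <= 0) return(Inf)
  a * b * ca / (4 * k)
}

# Alpha-shape outer ring of a point set. Returns list(x, y) or NULL when the
# alpha complex is empty, disconnected, pinched, or omits input points --
# callers fall back to the convex hull.
.alpha_shape_ring <- function(x, y, alpha) {
  n <- length(x)
  tri <- tryCatch(
    deldir::triang.list(deldir::deldir(x, y, suppressMsge = TRUE)),
    error = function(e) NULL)
  if (is.null(tri) || !length(tri)) return(NULL)
  keep <- vapply(tri, function(tr) {
    .circumradius(tr$x[1], tr$y[1], tr$x[2], tr$y[2], tr$x[3], tr$y[3]) <= alpha
  }, logical(1))
  tri <- tri[keep]
  if (!length(tri)) return(NULL)
  verts <- unique(unlist(lapply(tri, function(tr) tr$ptNum)))
  if (length(verts) < n) return(NULL) # isolated points outside the complex
  # connectivity of the kept complex via union-find over shared edges
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  edges <- do.call(rbind, lapply(tri, function(tr) {
    p <- tr$ptNum
    cbind(c(p[1], p[2], p[3]), c(p[2], p[3], p[1]))
  }))
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  if (length(unique(vapply(verts, find, integer(1)))) > 1L) return(NULL)
  # boundary edges appear in exactly one kept triangle
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  if (!length(bkey)) return(NULL)
  bnd <- do.call(rbind, lapply(strsplit(bkey, " "), as.integer))
  # every boundary vertex must have degree exactly 2 (no pinch points)
  deg <- table(c(bnd[, 1], bnd[, 2]))
  if (any(deg != 2L)) return(NULL)
  rings <- .walk_rings(bnd)
  if (is.null(rings)) return(NULL)
  areas <- vapply(rings, function(r) abs(.shoelace(x[r], y[r])), numeric(1))
  outer <- rings[[which.max(areas)]]
  ring <- list(x = x[outer], y = y[outer])
  # the outer ring must enclose every input point (holes inside it are fine
  # and are absorbed by the buffer)
  if (!all(point_in_ring(x, y, ring))) return(NULL)
  ring
}

# walk undirected boundary edges (2-regular graph) into vertex cycles
.walk_rings <- function(bnd) {
  adj <- split(c(bnd[, 2], bnd[, 1]), c(bnd[, 1], bnd[, 2]))
  used <- new.env(parent = emptyenv())
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  rings <- list()
  for (start in as.integer(names(adj))) {
    nb0 <- adj[[as.character(start)]]
    nxt <- nb0[!vapply(nb0, function(b) isTRUE(used[[ekey(start, b)]]), logical(1))]
    if (!length(nxt)) next
    ring <- start; prev <- start; cur <- nxt[1]
    used[[ekey(prev, cur)]] <- TRUE
    guard <- 0L
    while (cur != start) {
      ring <- c(ring, cur)
      nb <- adj[[as.character(cur)]]
      nxt <- nb[nb != prev]
      if (length(nxt) != 1L) return(NULL)
      used[[ekey(cur, nxt)]] <- TRUE
      prev <- cur; cur <- nxt
      guard <- guard + 1L
      if (guard > nrow(bnd) + 1L) return(NULL)
    }
    rings[[length(rings) + 1L]] <- ring
  }
  if (!length(rings)) return(NULL)
  rings
}

# regular k-gon approximating a disc (k = 4 * quad_segs)
.disc_ring <- function(cx, cy, r, quad_segs) {
  k <- 4L * quad_segs
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  list(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Buffered concave-hull polygon of a cell cluster
#'
#' Builds the LA boundary: the alpha-shape (concave hull) of the member
#' coordinates, dilated by `hull_buffer` with round joins. Degenerate inputs
#' are handled in closed form: one point gives a disc, two points or a
#' collinear set gives a capsule. When the alpha complex is empty,
#' disconnected or pinched, the convex hull is used instead (logged via
#' `option(laggr.verbose)`), so the result always contains every input point.
#'
#' @param coords Two-column matrix or data frame of member x/y (um).
#' @param hull_buffer Dilation radius (um); default 100.
#' @param hull_alpha Alpha-shape disc radius (um); default 150.
#' @param quad_segs Segments per quarter turn approximating round joins
#'   (default 32).
#' @return A `region_polygon` with attribute `fallback` (TRUE when the convex
#'   hull replaced the alpha-shape).
#' @export
#' @examples
#' sq <- cbind(c(0, 200, 200, 0), c(0, 0, 200, 200))
#' p <- build_la_polygon(sq, hull_buffer = 100)
#' p$area # ~ 200^2 + 4*200*100 + pi*100^2
build_la_polygon <- function(coords, hull_buffer = 100, hull_alpha = 150,
                             quad_segs = 32L) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("build_la_polygon: no member points")
  if (!all(is.finite(coords))) stop("build_la_polygon: non-finite coordinates")
  stopifnot(hull_buffer > 0, hull_alpha > 0)
  pts <- unique(coords[, 1:2, drop = FALSE])
  x <- pts[, 1]; y <- pts[, 2]
  arctol <- hull_buffer * (1 - cos(pi / (4 * quad_segs)))
  fallback <- FALSE

  if (nrow(pts) == 1L) {
    ring <- .disc_ring(x, y, hull_buffer, quad_segs)
    return(.finish_polygon(ring, fallback))
  }

  # collinearity: smallest singular value of centered coordinates
  ctr <- scale(pts, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (nrow(pts) == 2L || sv[2] < 1e-9 * max(sv[1], 1)) {
    ax <- ctr %*% svd(ctr, nv = 2, nu = 0)$v[, 1]
    ord <- order(ax)
    ends <- pts[c(ord[1], ord[length(ord)]), , drop = FALSE]
    off <- polyclip::polylineoffset(
      list(x = ends[, 1], y = ends[, 2]), hull_buffer,
      jointype = "round", endtype = "openround", arctol = arctol)
    return(.finish_polygon(.largest_ring(off), fallback))
  }

  ring <- .alpha_shape_ring(x, y, hull_alpha)
  if (is.null(ring)) {
    fallback <- TRUE
    la_log("alpha-shape degenerate or disconnected; using convex hull (%d points)",
           nrow(pts))
    h <- grDevices::chull(x, y)
    ring <- list(x = x[h], y = y[h])
  }
  off <- polyclip::polyoffset(ring, hull_buffer, jointype = "round",
                              arctol = arctol)
  out <- .largest_ring(off)
  if (is.null(out)) {
    fallback <- TRUE
    h <- grDevices::chull(x, y)
    off <- polyclip::polyoffset(list(x = x[h], y = y[h]), hull_buffer,
                                jointype = "round", arctol = arctol)
    out <- .largest_ring(off)
  }
  .finish_polygon(out, fallback)
}

.largest_ring <- function(rings) {
  if (!length(rings)) return(NULL)
  areas <- vapply(rings, function(r) abs(.shoelace(r$x, r$y)), numeric(1))
  rings[[which.max(areas)]]
}

.finish_polygon <- function(ring, fallback) {
  p <- region_polygon(ring$x, ring$y, label = "LA", check_simple = FALSE)
  attr(p, "fallback") <- fallback
  p
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Vectorized crossing-number test; points within `tol` of a boundary segment
#' count as inside.
#'
#' @param px,py Point coordinates (um).
#' @param polygon A `region_polygon`, or a list with `x` and `y`.
#' @param tol Boundary tolerance (um); default 1e-8.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, polygon, tol = 1e-8) {
  point_in_ring(px, py, polygon, tol)
}

point_in_ring <- function(px, py, ring, tol = 1e-8) {
  x <- ring$x; y <- ring$y
  m <- length(x)
  inside <- logical(length(px))
  onb <- logical(length(px))
  j <- m
  for (i in seq_len(m)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    tt <- if (L2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / L2)) else 0
    onb <- onb | ((px - (xi + tt * dx))^2 + (py - (yi + tt * dy))^2 <= tol * tol)
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside | onb
}

# distance from points to a polygon (0 when inside or on the boundary)
dist_to_polygon <- function(px, py, polygon) {
  x <- polygon$x; y <- polygon$y
  m <- length(x)
  d2 <- rep(Inf, length(px))
  j <- m
  for (i in seq_len(m)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    tt <- if (L2 > 0) pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / L2)) else 0
    d2 <- pmin(d2, (px - (xi + tt * dx))^2 + (py - (yi + tt * dy))^2)
    j <- i
  }
  d <- sqrt(d2)
  d[point_in_ring(px, py, polygon)] <- 0
  d
}

# polygon centroid (area-weighted)
polygon_centroid <- function(polygon) {
  x <- polygon$x; y <- polygon$y
  nx <- c(x[-1], x[1]); ny <- c(y[-1], y[1])
  cr <- x * ny - nx * y
  a <- sum(cr) / 2
  c(sum((x + nx) * cr) / (6 * a), sum((y + ny) * cr) / (6 * a))
}
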