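#' Construct an area-of-interest (AOI) region
#'
#' An AOI is a simple polygon on the stimulus picture corresponding to an
#' expected information unit (a person, animal or background element).
#' Fixations landing inside the polygon are attributed to that element.
#'
#' @param label Region name, unique within a picture.
#' @param role Either `"active_agent"` (people/animals) or `"static_object"`
#'   (background elements).
#' @param vertices Two-column numeric matrix (or list of `c(x, y)` pairs) of
#'   polygon vertices in screen pixels, origin top-left. The ring is open
#'   (the first vertex is not repeated); at least 3 vertices; the polygon
#'   must be simple (non-self-intersecting, no zero-length edges).
#' @return An object of class `aoi_region`.
#' @export
aoi_region <- function(label, role, vertices) {
  if (!is.character(label) || length(label) != 1 || !nzchar(label)) {
    abort_config("AOI label must be a non-empty string")
  }
  check_enum(role, AOI_ROLES, "AOI role")
  v <- as_vertex_matrix(vertices, label)
  if (nrow(v) < 3) {
    abort_geometry(sprintf("AOI '%s' has %d vertices; at least 3 required",
                           label, nrow(v)))
  }
  # drop an explicitly closed ring
  n <- nrow(v)
  if (n > 3 && all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  if (!polygon_is_simple(v)) {
    abort_geometry(sprintf(
      "AOI '%s' polygon is degenerate or self-intersecting", label))
  }
  structure(list(label = label, role = role, vertices = v),
            class = "aoi_region")
}

as_vertex_matrix <- function(vertices, label) {
  if (is.list(vertices)) {
    vertices <- do.call(rbind, lapply(vertices, as.numeric))
  }
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2 || anyNA(v)) {
    abort_geometry(sprintf("AOI '%s' vertices must be numeric (x, y) pairs",
                           label))
  }
  dimnames(v) <- list(NULL, c("x", "y"))
  v
}

# Simple-polygon test: no zero-length edges, no contact between
# non-adjacent edges. O(n^2), adequate for hand-drawn AOI outlines.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  for (i in seq_len(n)) {
    if (all(v[i, ] == v[nxt[i], ])) return(FALSE)  # repeated vertex
  }
  if (n <= 3) return(TRUE)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adjacent <- (j == i + 1) || (i == 1 && j == n)
      if (adjacent) next
      if (segments_intersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

orient <- function(p, q, r) {
  val <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  sign(val)
}

on_segment <- function(p, q, r) {
  # r collinear with p-q: does r lie on the closed segment?
  min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
    min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
}

segments_intersect <- function(p1, p2, p3, p4) {
  o1 <- orient(p1, p2, p3); o2 <- orient(p1, p2, p4)
  o3 <- orient(p3, p4, p1); o4 <- orient(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_segment(p1, p2, p3)) ||
    (o2 == 0 && on_segment(p1, p2, p4)) ||
    (o3 == 0 && on_segment(p3, p4, p1)) ||
    (o4 == 0 && on_segment(p3, p4, p2))
}

polygon_centroid <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  cross <- v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2]
  a <- sum(cross) / 2
  if (abs(a) < 1e-9) return(colMeans(v))
  c(sum((v[, 1] + v[nxt, 1]) * cross) / (6 * a),
    sum((v[, 2] + v[nxt, 2]) * cross) / (6 * a))
}

# Minimum distance from each point to the polygon boundary (vectorised over
# points). Used to make boundary membership exact and to implement a uniform
# outward buffer: a point belongs to the buffered polygon iff it is inside
# or within `buffer` pixels of the boundary.
points_polygon_distance <- function(x, y, v) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  dmin <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    ax <- v[i, 1]; ay <- v[i, 2]
    bx <- v[nxt[i], 1]; by <- v[nxt[i], 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2))
    d <- sqrt((x - (ax + t * dx))^2 + (y - (ay + t * dy))^2)
    dmin <- pmin(dmin, d)
  }
  dmin
}

#' Point-in-region test with boundary and buffer handling
#'
#' Tests whether points fall inside an AOI polygon, counting the boundary as
#' inside, after optional uniform outward buffering by `buffer_px` pixels
#' (mirroring buffered freehand AOIs drawn "slightly larger than the
#' targets").
#'
#' @param x,y Numeric vectors of point coordinates in screen pixels.
#' @param region An [aoi_region()].
#' @param buffer_px Non-negative outward buffer in pixels (default 0).
#' @return Logical vector.
#' @export
point_in_region <- function(x, y, region, buffer_px = 0) {
  stopifnot(inherits(region, "aoi_region"))
  if (buffer_px < 0) abort_domain("buffer_px must be non-negative")
  if (length(x) == 0) return(logical(0))
  v <- region$vertices
  ring <- rbind(v, v[1, ])
  inside <- as.logical(mgcv::in.out(ring, cbind(as.numeric(x), as.numeric(y))))
  near <- points_polygon_distance(as.numeric(x), as.numeric(y), v) <= buffer_px
  inside | near
}

#' Construct an AOI configuration for one picture
#'
#' @param picture_id `"han_river"` or `"beach"`.
#' @param regions List of [aoi_region()] objects; labels must be unique.
#' @param screen Named numeric vector `c(width_px, height_px)`; defaults to
#'   the 1680 x 1050 recording screen.
#' @return An object of class `aoi_config`.
#' @export
aoi_config <- function(picture_id, regions,
                       screen = SCREEN_DEFAULT) {
  check_enum(picture_id, PRESPEECH_PICTURES, "picture_id")
  if (!all(vapply(regions, inherits, logical(1), "aoi_region"))) {
    abort_config("regions must be a list of aoi_region objects")
  }
  labels <- vapply(regions, `[[`, character(1), "label")
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0) {
    abort_config(sprintf("duplicate AOI label(s) in %s config: %s",
                         picture_id, paste(unique(dup), collapse = ", ")))
  }
  structure(list(picture_id = picture_id,
                 screen = c(width_px = unname(screen[["width_px"]]),
                            height_px = unname(screen[["height_px"]])),
                 regions = regions),
            class = "aoi_config")
}

#' @export
print.aoi_config <- function(x, ...) {
  roles <- vapply(x$regions, `[[`, character(1), "role")
  cat(sprintf("<aoi_config> picture '%s': %d regions (%d active agents, %d static objects)\n",
              x$picture_id, length(x$regions),
              sum(roles == "active_agent"), sum(roles == "static_object")))
  invisible(x)
}

#' AOI region labels of a configuration
#' @param config An [aoi_config()].
#' @return Character vector of labels, in configuration order.
#' @export
aoi_labels <- function(config) {
  vapply(config$regions, `[[`, character(1), "label")
}

#' Read an AOI polygon configuration from YAML
#'
#' The document holds `picture_id`, an optional `screen` block
#' (`width_px`, `height_px`) and a `regions` list of
#' `{label, role, vertices: [[x, y], ...]}` entries.
#'
#' @param path Path to a YAML file.
#' @return An [aoi_config()].
#' @export
read_aoi_config <- function(path) {
  doc <- yaml::read_yaml(path)
  for (field in c("picture_id", "regions")) {
    if (is.null(doc[[field]])) {
      abort_format(sprintf("AOI config '%s' lacks required field '%s'",
                           path, field))
    }
  }
  screen <- SCREEN_DEFAULT
  if (!is.null(doc$screen)) {
    screen <- c(width_px = doc$screen$width_px, height_px = doc$screen$height_px)
  }
  regions <- lapply(doc$regions, function(r) {
    for (field in c("label", "role", "vertices")) {
      if (is.null(r[[field]])) {
        abort_format(sprintf("AOI region in '%s' lacks field '%s'",
                             path, field))
      }
    }
    aoi_region(r$label, r$role, r$vertices)
  })
  aoi_config(doc$picture_id, regions, screen)
}

#' Write an AOI configuration to YAML
#' @param config An [aoi_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aoi_config <- function(config, path) {
  stopifnot(inherits(config, "aoi_config"))
  doc <- list(
    picture_id = config$picture_id,
    screen = list(width_px = unname(config$screen[["width_px"]]),
                  height_px = unname(config$screen[["height_px"]])),
    regions = lapply(config$regions, function(r) {
      list(label = r$label, role = r$role,
           vertices = lapply(seq_len(nrow(r$vertices)),
                             function(i) as.numeric(r$vertices[i, ])))
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Packaged default AOI configuration for a picture
#'
#' Returns the AOI layout shipped with the package: 12 regions per picture
#' (nine active agents and three static objects for the Han River picture;
#' six and six for the Beach picture). Region labels and roles follow the
#' published AOI inventory; the polygon coordinates are synthetic stand-ins
#' (the original freehand outlines are not published) laid out on the
#' 1680 x 1050 screen and pre-buffered, so the default assignment buffer
#' is 0.
#'
#' @param picture_id `"han_river"` or `"beach"`.
#' @return An [aoi_config()].
#' @export
default_aoi_config <- function(picture_id) {
  check_enum(picture_id, PRESPEECH_PICTURES, "picture_id")
  path <- system.file("extdata", paste0("aoi_", picture_id, "_synthetic.yaml"),
                      package = "prespeech")
  if (!nzchar(path)) abort_config("packaged AOI config not found")
  read_aoi_config(path)
}

#' Packaged default AOI configurations for both pictures
#' @return Named list of [aoi_config()] objects, one per picture.
#' @export
default_aoi_configs <- function() {
  cfgs <- lapply(PRESPEECH_PICTURES, default_aoi_config)
  names(cfgs) <- PRESPEECH_PICTURES
  cfgs
}
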