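#' Polygon layer container
#'
#' A minimal planar polygon layer: a data.frame with one row per polygon,
#' columns `area_id` and `state_id`, and a list-column `coords` of n x 2
#' vertex matrices (rings are implicitly closed). Row order is the stable
#' layer order used to break boundary ties deterministically.
#'
#' @param area_id character vector of polygon ids.
#' @param state_id character vector, the state each polygon belongs to.
#' @param coords list of numeric matrices with columns x, y.
#' @return data.frame of class `polygon_table`.
#' @export
polygon_table <- function(area_id, state_id, coords) {
  stopifnot(length(area_id) == length(state_id),
            length(area_id) == length(coords))
  ok <- vapply(coords, function(m) is.matrix(m) && ncol(m) == 2 &&
                 nrow(m) >= 3 && all(is.finite(m)), logical(1))
  if (!all(ok)) stop("each polygon needs a finite n x 2 matrix with n >= 3")
  out <- data.frame(area_id = as.character(area_id),
                    state_id = as.character(state_id),
                    stringsAsFactors = FALSE)
  out$coords <- coords
  class(out) <- c("polygon_table", "data.frame")
  out
}

#' Axis-aligned rectangle ring
#'
#' @param xmin,ymin,xmax,ymax rectangle bounds.
#' @return 4 x 2 vertex matrix (counter-clockwise).
#' @export
rect_coords <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

# Even-odd ray casting with explicit on-edge detection. Returns "inside",
# "edge" or "outside". Points exactly on a vertex or edge are "edge": the
# caller decides the tie-break (first polygon in layer order wins).
point_in_ring <- function(x, y, coords) {
  xs <- coords[, 1]; ys <- coords[, 2]
  n <- length(xs)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    # on-segment test: collinear and within bounding box of the edge
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    if (abs(cross) < 1e-12 &&
        x >= min(xi, xj) - 1e-12 && x <= max(xi, xj) + 1e-12 &&
        y >= min(yi, yj) - 1e-12 && y <= max(yi, yj) + 1e-12) {
      return("edge")
    }
    if ((yi > y) != (yj > y)) {
      xcross <- xi + (y - yi) * (xj - xi) / (yj - yi)
      if (x < xcross) inside <- !inside
    }
    j <- i
  }
  if (inside) "inside" else "outside"
}

#' Reassign survey clusters to updated area polygons
#'
#' Implements the bookkeeping used when survey clusters collected under an
#' older geography are linked to updated district or constituency polygons:
#'
#' * clusters whose microdata area is unchanged keep their original linkage
#'   (`kept_microdata`) — existing linkages are taken as-is;
#' * other clusters are assigned by point-in-polygon (`spatial_match`);
#' * a point contained in no polygon is *unmatched*; a point whose containing
#'   polygon lies in a different state than the microdata recorded is
#'   *mismatched*;
#' * unmatched/mismatched points in states that consist of a single area
#'   (`single_unit_states`) are assigned to that state's sole polygon
#'   (`fallback_single_unit`);
#' * remaining unmatched/mismatched points are `dropped` (no assignment);
#'   the `reason` column records whether a dropped or rescued cluster was
#'   unmatched or state-mismatched.
#'
#' Boundary points (exactly on an edge) belong to the first polygon in the
#' stable layer order — GIS tools differ here, so determinism is preferred
#' and documented. When `parent_map` is supplied, spatial candidates for a
#' changed cluster are limited to the child polygons of its original parent
#' area, mirroring the rule under which clusters falling outside every
#' eligible child district stay unassigned.
#'
#' @param points data.frame `cluster_id, x, y, microdata_state_id,
#'   microdata_area_id` (see [simulate_geometry()]).
#' @param polygons a [polygon_table()]; polygons must not overlap.
#' @param changed_area_ids areas whose boundaries changed; clusters in other
#'   areas keep their microdata linkage. `NULL` means all areas changed.
#' @param single_unit_states states in which the state is itself the sole
#'   area, used as the rescue rule for unmatched/mismatched clusters.
#' @param parent_map optional named character vector mapping child
#'   `area_id` to its parent (original) area id.
#' @return data.frame with one row per input cluster: `cluster_id,
#'   assigned_area_id, status, reason`. Status is one of `kept_microdata`,
#'   `spatial_match`, `fallback_single_unit`, `dropped`; `assigned_area_id`
#'   is `NA` exactly when status is `dropped`.
#' @export
assign_clusters <- function(points, polygons, changed_area_ids = NULL,
                            single_unit_states = NULL, parent_map = NULL) {
  stopifnot(inherits(polygons, "polygon_table"))
  need <- c("cluster_id", "x", "y", "microdata_state_id", "microdata_area_id")
  if (!all(need %in% names(points))) {
    stop("points must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(points$x)) || !all(is.finite(points$y))) {
    stop("cluster point coordinates must be finite")
  }

  n <- nrow(points)
  assigned <- rep(NA_character_, n)
  status <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    area0 <- points$microdata_area_id[i]
    state0 <- points$microdata_state_id[i]
    if (!is.null(changed_area_ids) && !(area0 %in% changed_area_ids)) {
      assigned[i] <- area0
      status[i] <- "kept_microdata"
      next
    }
    cand <- seq_len(nrow(polygons))
    if (!is.null(parent_map)) {
      cand <- cand[!is.na(parent_map[polygons$area_id]) &
                     parent_map[polygons$area_id] == area0]
    }
    hit_inside <- integer(0); hit_edge <- integer(0)
    for (p in cand) {
      where <- point_in_ring(points$x[i], points$y[i], polygons$coords[[p]])
      if (where == "inside") hit_inside <- c(hit_inside, p)
      else if (where == "edge") hit_edge <- c(hit_edge, p)
    }
    if (length(hit_inside) > 1) {
      stop("overlapping polygons contain cluster ", points$cluster_id[i],
           ": ", paste(polygons$area_id[hit_inside], collapse = ", "))
    }
    hit <- if (length(hit_inside) == 1) hit_inside else
      if (length(hit_edge) >= 1) hit_edge[1] else NA_integer_

    if (is.na(hit)) {
      reason[i] <- "unmatched"
    } else if (polygons$state_id[hit] != state0) {
      reason[i] <- "mismatched_state"
    } else {
      assigned[i] <- polygons$area_id[hit]
      status[i] <- "spatial_match"
      next
    }
    # rescue rule: single-area states absorb their unmatched/mismatched points
    if (state0 %in% single_unit_states) {
      sole <- which(polygons$state_id == state0)
      if (length(sole) != 1) {
        stop("state ", state0, " declared single-unit but has ",
             length(sole), " polygons")
      }
      assigned[i] <- polygons$area_id[sole]
      status[i] <- "fallback_single_unit"
    } else {
      status[i] <- "dropped"
    }
  }

  data.frame(cluster_id = points$cluster_id,
             assigned_area_id = assigned,
             status = status,
             reason = reason,
             stringsAsFactors = FALSE)
}

#' Summarize a cluster assignment
#'
#' Either summarizes an [assign_clusters()] result table, or — given printed
#' `total` and `dropped` counts — performs the included-cluster arithmetic
#' directly (`included = total - dropped`).
#'
#' @param results optional assignment result table.
#' @param total,dropped optional printed totals when no table is given.
#' @return list with `counts` (by status), `reasons` (by reason, table input
#'   only), `total`, `dropped`, `included`.
#' @export
assignment_summary <- function(results = NULL, total = NULL, dropped = NULL) {
  if (!is.null(results)) {
    counts <- table(factor(results$status,
                           levels = c("kept_microdata", "spatial_match",
                                      "fallback_single_unit", "dropped")))
    total <- nrow(results)
    dropped <- sum(results$status == "dropped")
    stopifnot(sum(counts) == total,
              all(is.na(results$assigned_area_id) ==
                    (results$status == "dropped")))
    return(list(counts = c(counts), reasons = c(table(results$reason)),
                total = total, dropped = dropped,
                included = total - dropped))
  }
  if (is.null(total) || is.null(dropped)) {
    stop("supply either a results table or both total and dropped")
  }
  if (dropped > total || total < 0 || dropped < 0) {
    stop("need 0 <= dropped <= total")
  }
  list(counts = NULL, reasons = NULL, total = total, dropped = dropped,
       included = total - dropped)
}

#' Write / read polygon layers and points as GeoJSON
#'
#' Plain-text GeoJSON keeps the synthetic fixtures diffable and lets the
#' layers be inspected with standard GIS tooling. Polygons are written as a
#' `FeatureCollection` of `Polygon` features (properties `area_id`,
#' `state_id`), points as `Point` features carrying the remaining columns as
#' properties.
#'
#' @param polygons a [polygon_table()].
#' @param path output file.
#' @return `path`, invisibly (writers); the reconstructed object (readers).
#' @export
write_geojson_polygons <- function(polygons, path) {
  stopifnot(inherits(polygons, "polygon_table"))
  feats <- lapply(seq_len(nrow(polygons)), function(i) {
    ring <- polygons$coords[[i]]
    ring <- rbind(ring, ring[1, ])  # close the ring
    list(type = "Feature",
         properties = list(area_id = polygons$area_id[i],
                           state_id = polygons$state_id[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(lapply(
                           seq_len(nrow(ring)),
                           function(r) as.numeric(ring[r, ]))))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson_polygons
#' @export
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  coords <- lapply(feats, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    colnames(ring) <- c("x", "y")
    ring
  })
  polygon_table(vapply(feats, function(f) f$properties$area_id, character(1)),
                vapply(feats, function(f) f$properties$state_id, character(1)),
                coords)
}

#' @param points data.frame with `x`, `y` and id columns.
#' @rdname write_geojson_polygons
#' @export
write_geojson_points <- function(points, path) {
  props <- setdiff(names(points), c("x", "y"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         properties = as.list(points[i, props, drop = FALSE]),
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson_polygons
#' @export
read_geojson_points <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  props <- do.call(rbind, lapply(feats, function(f)
    as.data.frame(f$properties, stringsAsFactors = FALSE)))
  props$x <- vapply(feats, function(f) f$geometry$coordinates[[1]], numeric(1))
  props$y <- vapply(feats, function(f) f$geometry$coordinates[[2]], numeric(1))
  props
}
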