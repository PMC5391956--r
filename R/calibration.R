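#' Canonical planar calibration-marker template
#'
#' The rig is calibrated from flat printed markers whose salient shape corners
#' can be located in each sensor's point cloud. The template fixes the corner
#' geometry and ordering once, in the marker's own frame: four corners of a
#' square of side `side`, counter-clockwise starting at the dent corner, lying
#' in the plane z = 0 (the marker normal is +z, the first in-plane edge is +x).
#'
#' @param side square side length in meters (default 0.30).
#' @return 4 x 3 numeric matrix of corner coordinates (meters), ordered.
#' @export
marker_template <- function(side = 0.30) {
  stopifnot(side > 0)
  h <- side / 2
  matrix(c(-h, -h, 0,
            h, -h, 0,
            h,  h, 0,
           -h,  h, 0), ncol = 3, byrow = TRUE)
}

# deterministic node ordering: markers before sensors, numeric ids ascending,
# then lexicographic. Used for every tie-break in the chaining BFS.
node_order <- function(names) {
  kind <- sub(":.*$", "", names)
  id <- sub("^[^:]*:", "", names)
  num <- suppressWarnings(as.numeric(id))
  order(kind, is.na(num), num, id)
}

sensor_node <- function(id) paste0("sensor:", id)
marker_node <- function(id) paste0("marker:", id)

#' Build the sensor-marker visibility graph
#'
#' The "sees" relation between sensors and markers forms a bipartite
#' undirected graph: one node per sensor, one per marker, and an edge wherever
#' a sensor has observed a marker's corners. If the graph is connected, every
#' sensor can be chained to the origin marker through shared observations.
#'
#' @param observations tibble of marker observations with columns `sensor_id`,
#'   `marker_id` (and typically `corner`, `x`, `y`, `z`; only the id columns
#'   are used here). Duplicate (sensor, marker) pairs collapse to one edge.
#' @return An [igraph::igraph] object; vertices carry `kind` ("sensor" or
#'   "marker") and bipartite `type` attributes, names are `"sensor:<id>"` /
#'   `"marker:<id>"`.
#' @export
build_visibility_graph <- function(observations) {
  edges <- dplyr::distinct(tibble::as_tibble(observations),
                           .data$sensor_id, .data$marker_id)
  sensors <- sort(unique(as.character(edges$sensor_id)))
  markers <- sort(unique(as.character(edges$marker_id)))
  verts <- tibble::tibble(
    name = c(marker_node(markers), sensor_node(sensors)),
    kind = c(rep("marker", length(markers)), rep("sensor", length(sensors))),
    type = c(rep(FALSE, length(markers)), rep(TRUE, length(sensors)))
  )
  el <- tibble::tibble(from = sensor_node(edges$sensor_id),
                       to = marker_node(edges$marker_id))
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
}

#' Per-edge marker-to-sensor transforms
#'
#' For every (sensor, marker) pair in the observations, rigidly fits the
#' template corners onto the observed corners. The fitted transform maps
#' marker-frame coordinates into that sensor's local frame.
#'
#' @param observations tibble with columns `sensor_id`, `marker_id`, `corner`
#'   (1-based index into the template rows), `x`, `y`, `z` (meters, sensor
#'   frame). Repeated sightings of a corner are averaged before fitting.
#' @param template corner matrix as from [marker_template()].
#' @return tibble with columns `sensor_id`, `marker_id`, `transform`
#'   (list of [rigid_transform], marker frame -> sensor frame), `rms` (m).
#' @export
pairwise_transforms <- function(observations, template = marker_template()) {
  obs <- tibble::as_tibble(observations)
  stopifnot(all(c("sensor_id", "marker_id", "corner", "x", "y", "z") %in% names(obs)))
  obs |>
    dplyr::group_by(.data$sensor_id, .data$marker_id, .data$corner) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
                     .groups = "drop") |>
    dplyr::group_by(.data$sensor_id, .data$marker_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) != nrow(template)) {
        stop("observation of marker ", key$marker_id, " by sensor ",
             key$sensor_id, " has ", nrow(d), " corners; template has ",
             nrow(template), call. = FALSE)
      }
      d <- d[order(d$corner), ]
      fit <- procrustes_fit(template, as.matrix(d[, c("x", "y", "z")]))
      tibble::tibble(transform = list(fit$transform), rms = fit$rms)
    }) |>
    dplyr::ungroup()
}

#' Chain sensor poses to the origin marker
#'
#' Walks the visibility graph from every sensor to the origin marker along the
#' shortest path (breadth-first, unweighted; ties broken by ascending node
#' identifier so results are deterministic) and concatenates the per-edge
#' Euclidean transforms into the sensor's pose in the global frame — the frame
#' of the origin marker. Shorter chains are preferred because every fitted
#' transform carries estimation error that compounds along the path.
#'
#' @param graph visibility graph from [build_visibility_graph()].
#' @param pairwise per-edge transforms from [pairwise_transforms()].
#' @param origin_marker id of the marker defining the global frame (default 1).
#' @return A `rig_calibration`: tibble with one row per sensor and columns
#'   `sensor_id`, `transform` (sensor-local -> global [rigid_transform]),
#'   `path` (list of node-name chains), `path_length` (edges), `rms`
#'   (root-mean-square corner residual along the chain, m), `refined`
#'   (logical). The graph and origin are kept as attributes.
#' @export
chain_to_origin <- function(graph, pairwise, origin_marker = 1) {
  origin <- marker_node(origin_marker)
  vnames <- igraph::V(graph)$name
  if (!origin %in% vnames) {
    stop("origin marker ", origin_marker, " is absent from the visibility graph",
         call. = FALSE)
  }
  # adjacency with deterministic neighbour order
  adj <- lapply(igraph::adjacent_vertices(graph, vnames), function(v) {
    nm <- v$name
    nm[node_order(nm)]
  })
  names(adj) <- vnames

  # BFS from the origin; parent pointers give shortest paths with the
  # ascending-id tie-break (first-discovered parent wins, neighbours visited
  # in sorted order)
  parent <- stats::setNames(rep(NA_character_, length(vnames)), vnames)
  dist <- stats::setNames(rep(Inf, length(vnames)), vnames)
  dist[origin] <- 0
  queue <- origin
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }

  sensors <- vnames[igraph::V(graph)$kind == "sensor"]
  sensors <- sensors[node_order(sensors)]
  unreachable <- sensors[is.infinite(dist[sensors])]
  if (length(unreachable)) {
    stop("visibility graph is not connected: no path from ",
         paste(unreachable, collapse = ", "), " to the origin marker ",
         origin_marker, call. = FALSE)
  }

  edge_tf <- function(sensor, marker) {
    hit <- pairwise$transform[pairwise$sensor_id == sensor &
                              pairwise$marker_id == marker]
    if (!length(hit)) {
      stop("no pairwise transform for edge (", sensor, ", ", marker, ")",
           call. = FALSE)
    }
    hit[[1]]
  }
  edge_rms <- function(sensor, marker) {
    pairwise$rms[pairwise$sensor_id == sensor & pairwise$marker_id == marker][[1]]
  }

  rows <- purrr::map(sensors, function(s) {
    path <- s
    while (path[length(path)] != origin) path <- c(path, parent[[path[length(path)]]])
    total <- rt_identity()
    rms2 <- numeric(0)
    for (i in seq_len(length(path) - 1)) {
      u <- path[i]; v <- path[i + 1]
      u_id <- sub("^[^:]*:", "", u); v_id <- sub("^[^:]*:", "", v)
      step <- if (startsWith(u, "sensor:")) {
        rt_invert(edge_tf(u_id, v_id))   # sensor frame -> marker frame
      } else {
        edge_tf(v_id, u_id)              # marker frame -> sensor frame
      }
      rms2 <- c(rms2, if (startsWith(u, "sensor:")) edge_rms(u_id, v_id)^2
                      else edge_rms(v_id, u_id)^2)
      total <- rt_compose(step, total)
    }
    n_edges <- length(path) - 1L
    tibble::tibble(sensor_id = sub("^sensor:", "", s),
                   transform = list(total),
                   path = list(path),
                   path_length = n_edges,
                   rms = sqrt(mean(rms2)),
                   refined = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "graph") <- graph
  attr(out, "origin_marker") <- as.character(origin_marker)
  class(out) <- c("rig_calibration", class(out))
  out
}

#' Calibrate a sensor rig from marker observations
#'
#' One-call wrapper: fits all per-edge transforms, builds the visibility
#' graph, verifies connectivity and chains every sensor to the origin marker.
#'
#' @inheritParams pairwise_transforms
#' @inheritParams chain_to_origin
#' @return A `rig_calibration` (see [chain_to_origin()]).
#' @examples
#' rig <- simulate_rig(n_rows = 2, seed = 1)
#' mk <- default_marker_poses(corridor_length = 5)
#' obs <- simulate_marker_observations(rig, mk, noise_sigma = 0, seed = 1)
#' cal <- calibrate_rig(obs)
#' glance(cal)
#' @export
calibrate_rig <- function(observations, template = marker_template(),
                          origin_marker = 1) {
  pw <- pairwise_transforms(observations, template)
  g <- build_visibility_graph(observations)
  chain_to_origin(g, pw, origin_marker)
}

#' @export
print.rig_calibration <- function(x, ...) {
  cat("<rig_calibration> ", nrow(x), " sensors, origin marker ",
      attr(x, "origin_marker"), "\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rig calibration
#'
#' One row per sensor with the pose flattened to a unit quaternion
#' (`qw, qx, qy, qz`) and translation (`tx, ty, tz`, meters).
#'
#' @param x a `rig_calibration`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.rig_calibration <- function(x, ...) {
  purrr::map2_dfr(x$sensor_id, x$transform, function(id, tf) {
    q <- rot_to_quat(tf$rotation)
    tibble::tibble(sensor_id = id, qw = q[1], qx = q[2], qy = q[3], qz = q[4],
                   tx = tf$translation[1], ty = tf$translation[2],
                   tz = tf$translation[3])
  }) |>
    dplyr::left_join(
      tibble::tibble(sensor_id = x$sensor_id, path_length = x$path_length,
                     rms = x$rms, refined = x$refined),
      by = "sensor_id")
}

#' @rdname tidy.rig_calibration
#' @export
glance.rig_calibration <- function(x, ...) {
  tibble::tibble(n_sensors = nrow(x),
                 max_path_length = max(x$path_length),
                 mean_rms = mean(x$rms),
                 n_refined = sum(x$refined))
}
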