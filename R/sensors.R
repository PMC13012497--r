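#' Sensor arrays and electrode adjacency
#'
#' A sensor array is a data frame with columns `label`, `x`, `y`, `z`
#' (3-D electrode coordinates in a right-handed head frame, arbitrary but
#' consistent length units, common origin). [sensor_array()] validates and
#' tags one; [spherical_cap_array()] builds a deterministic high-density
#' cap layout standing in for a commercial 256-channel net, whose real
#' coordinates are proprietary.
#'
#' @param positions data frame or matrix with columns `x`, `y`, `z`.
#' @param labels character vector of unique channel labels.
#' @return an object of class `sensor_array` (a data.frame).
#' @export
sensor_array <- function(positions, labels = NULL) {
  pos <- as.data.frame(positions)
  if (!all(c("x", "y", "z") %in% names(pos))) {
    stopifnot(ncol(pos) == 3L)
    names(pos) <- c("x", "y", "z")
  }
  if (is.null(labels)) {
    labels <- if (is.matrix(positions) && !is.null(rownames(positions)))
      rownames(positions)
    else sprintf("E%03d", seq_len(nrow(pos)))
  }
  if (anyDuplicated(labels)) stop("sensor labels must be unique")
  if (length(labels) != nrow(pos)) stop("one label per position required")
  if (!all(is.finite(as.matrix(pos[c("x", "y", "z")])))) {
    stop("sensor positions must be finite")
  }
  out <- data.frame(label = as.character(labels), pos[c("x", "y", "z")],
                    stringsAsFactors = FALSE)
  class(out) <- c("sensor_array", "data.frame")
  out
}

#' Deterministic spherical-cap electrode layout
#'
#' Places `n` electrodes on a spherical cap (golden-angle spiral), a
#' standard stand-in for a high-density EEG net when digitised positions
#' are unavailable. The cap covers polar angles up to `cap_deg` from the
#' vertex of a head sphere of radius `radius` (cm).
#'
#' @param n number of electrodes (default 256).
#' @param radius head sphere radius, cm.
#' @param cap_deg angular extent of the cap from the vertex, degrees.
#' @return a [sensor_array()].
#' @export
spherical_cap_array <- function(n = 256L, radius = 9, cap_deg = 120) {
  stopifnot(n >= 1)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  # uniform in cos(theta) over the cap
  cmin <- cos(cap_deg * pi / 180)
  ct <- 1 - (1 - cmin) * i / n
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- i * golden
  sensor_array(
    data.frame(x = radius * st * cos(phi),
               y = radius * st * sin(phi),
               z = radius * ct),
    labels = sprintf("E%03d", seq_len(n))
  )
}

sensor_dist <- function(sensors) {
  as.matrix(stats::dist(as.matrix(sensors[c("x", "y", "z")])))
}

#' Build an electrode adjacency graph
#'
#' Defines which electrodes count as "spatially contiguous" for cluster
#' formation. Two constructions are available: `"distance"` links pairs
#' closer than a threshold (default: 1.5 times the median nearest-neighbour
#' distance, which yields a connected, locally dense graph on regular
#' layouts), and `"knn"` links each electrode to its `k` nearest
#' neighbours, symmetrised.
#'
#' @param sensors a [sensor_array()].
#' @param method `"distance"` or `"knn"`.
#' @param threshold distance threshold (same units as positions); if `NULL`
#'   with `method = "distance"`, defaults to 1.5 x median nearest-neighbour
#'   distance.
#' @param k neighbour count for `method = "knn"`.
#' @return an `igraph` undirected graph whose vertex names are the channel
#'   labels, with the construction parameters stored in graph attributes.
#' @export
build_adjacency <- function(sensors, method = c("distance", "knn"),
                            threshold = NULL, k = 4L) {
  method <- match.arg(method)
  if (nrow(sensors) < 3L) stop("need at least 3 sensors")
  D <- sensor_dist(sensors)
  if (any(D[upper.tri(D)] == 0)) stop("duplicate sensor positions")
  diag(D) <- Inf
  if (method == "distance") {
    if (is.null(threshold)) {
      nn <- apply(D, 1L, min)
      threshold <- 1.5 * median(nn)
    }
    adj <- D <= threshold
  } else {
    adj <- matrix(FALSE, nrow(D), ncol(D))
    for (i in seq_len(nrow(D))) {
      nb <- order(D[i, ])[seq_len(min(k, nrow(D) - 1L))]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)
  }
  diag(adj) <- FALSE
  dimnames(adj) <- list(sensors$label, sensors$label)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    warning(sprintf("adjacency graph is disconnected (%d components)",
                    comp$no))
  }
  g <- igraph::set_graph_attr(g, "method", method)
  g <- igraph::set_graph_attr(g, "threshold",
                              if (method == "distance") threshold else NA_real_)
  g <- igraph::set_graph_attr(g, "k", if (method == "knn") k else NA_integer_)
  g
}

#' Inject a spatially clustered effect into an electrode coefficient map
#'
#' Creates ground truth for cluster-detection simulations: electrodes
#' within `radius` of a centre electrode receive coefficient `amplitude`
#' (optionally cosine-tapered towards the edge), all others 0.
#'
#' @param sensors a [sensor_array()].
#' @param center_label label of the centre electrode.
#' @param radius inclusion radius in position units (`>= 0`).
#' @param amplitude coefficient value at the centre.
#' @param taper `"none"` (flat disc) or `"cosine"` (smooth falloff to the
#'   radius edge).
#' @return named numeric vector, one coefficient per electrode.
#' @export
inject_cluster_effect <- function(sensors, center_label, radius, amplitude,
                                  taper = c("none", "cosine")) {
  taper <- match.arg(taper)
  if (!center_label %in% sensors$label) {
    stop(sprintf("unknown electrode label '%s'", center_label))
  }
  if (radius < 0) stop("radius must be >= 0")
  pos <- as.matrix(sensors[c("x", "y", "z")])
  ctr <- pos[match(center_label, sensors$label), ]
  d <- sqrt(rowSums(sweep(pos, 2L, ctr)^2))
  inside <- d <= radius
  coefs <- numeric(nrow(sensors))
  if (taper == "none") {
    coefs[inside] <- amplitude
  } else {
    coefs[inside] <- amplitude *
      0.5 * (1 + cos(pi * d[inside] / max(radius, .Machine$double.eps)))
  }
  coefs[match(center_label, sensors$label)] <- amplitude
  names(coefs) <- sensors$label
  coefs
}
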