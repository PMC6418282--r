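#' Detector arrays, state spaces and exposure matrices
#'
#' @description
#' A `trap_array` holds georeferenced detectors of one kind (live-traps used
#' for marking, or camera-traps used for resighting) together with an
#' occasion-level operation schedule. All coordinates are planar kilometres
#' in an equal-area projection; all model distances are Euclidean.
#'
#' @param coords numeric J x 2 matrix of detector coordinates (km).
#' @param kind `"live"` or `"camera"`.
#' @param operation numeric J x K matrix of per-occasion effort (0/1 for
#'   cameras; days for live-traps). Defaults to a single all-on occasion.
#' @return An object of class `trap_array`: a list with elements `kind`,
#'   `coords` and `operation`.
#' @export
trap_array <- function(coords, kind = c("camera", "live"), operation = NULL) {
  kind <- match.arg(kind)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L || nrow(coords) < 1L)
    stop("'coords' must be a J x 2 matrix with J >= 1")
  if (!all(is.finite(coords))) stop("detector coordinates must be finite")
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  if (is.null(operation)) operation <- matrix(1, nrow(coords), 1L)
  operation <- as.matrix(operation)
  if (nrow(operation) != nrow(coords))
    stop("'operation' must have one row per detector")
  if (any(operation < 0)) stop("operation entries must be >= 0")
  structure(list(kind = kind, coords = coords, operation = operation),
            class = "trap_array")
}

#' @export
print.trap_array <- function(x, ...) {
  cat(sprintf("<trap_array> %d %s detectors, %d occasions\n",
              nrow(x$coords), x$kind, ncol(x$operation)))
  invisible(x)
}

#' Build a clustered detector design
#'
#' Lays out `n_clusters` rectangular clusters of `cluster_rows` x
#' `cluster_cols` sampling cells with one detector at each cell centre.
#' Clusters are arranged on a near-square grid with `cluster_dx_km`
#' longitudinal spacing between cluster centres; latitudinal spacing
#' alternates between the two values of `cluster_dy_km` across cluster
#' columns when `stagger = TRUE`, producing a staggered layout.
#'
#' Cell coverage is `cell_spacing_km^2` and cluster coverage is
#' `cluster_rows * cluster_cols * cell_spacing_km^2` (e.g. a 3 x 3 cluster
#' at 3.5 km spacing covers 110.25 km^2).
#'
#' @param n_clusters number of clusters.
#' @param cluster_rows,cluster_cols cells per cluster in each direction.
#' @param cell_spacing_km within-cluster cell spacing (km, > 0).
#' @param cluster_dx_km longitudinal spacing between cluster centres (km).
#' @param cluster_dy_km latitudinal spacing(s) between cluster centres (km);
#'   length 1 or 2 (alternating when staggered).
#' @param stagger alternate the latitudinal spacing across cluster columns.
#' @param n_occasions number of resighting occasions for the operation
#'   schedule (all-on).
#' @param kind detector kind, `"camera"` by default.
#' @param dropout optional integer vector of cell indices (1..J) to drop,
#'   emulating cells that could not be instrumented.
#' @return A [trap_array()].
#' @examples
#' d <- make_clustered_design(9, 3, 3, 3.5)
#' nrow(d$coords)  # 81 detectors
#' @export
make_clustered_design <- function(n_clusters = 9L, cluster_rows = 3L,
                                  cluster_cols = 3L, cell_spacing_km = 3.5,
                                  cluster_dx_km = 28, cluster_dy_km = c(36, 45),
                                  stagger = TRUE, n_occasions = 17L,
                                  kind = "camera", dropout = NULL) {
  if (cell_spacing_km <= 0 || cluster_dx_km <= 0 || any(cluster_dy_km <= 0))
    stop("all spacings must be positive")
  if (n_clusters < 1L || cluster_rows < 1L || cluster_cols < 1L)
    stop("cluster counts must be >= 1")
  if (length(cluster_dy_km) == 1L) cluster_dy_km <- rep(cluster_dy_km, 2L)

  grid_cols <- ceiling(sqrt(n_clusters))
  grid_rows <- ceiling(n_clusters / grid_cols)
  centres <- matrix(NA_real_, n_clusters, 2L)
  k <- 0L
  for (r in seq_len(grid_rows)) {
    for (cc in seq_len(grid_cols)) {
      if (k >= n_clusters) break
      k <- k + 1L
      dy <- if (stagger) cluster_dy_km[((cc - 1L) %% 2L) + 1L] else cluster_dy_km[1L]
      centres[k, ] <- c((cc - 1L) * cluster_dx_km, (r - 1L) * dy)
    }
  }

  ox <- (seq_len(cluster_cols) - (cluster_cols + 1) / 2) * cell_spacing_km
  oy <- (seq_len(cluster_rows) - (cluster_rows + 1) / 2) * cell_spacing_km
  offs <- as.matrix(expand.grid(x = ox, y = oy))
  coords <- do.call(rbind, lapply(seq_len(n_clusters), function(i) {
    cbind(centres[i, 1L] + offs[, 1L], centres[i, 2L] + offs[, 2L])
  }))
  if (!is.null(dropout)) {
    if (any(dropout < 1L | dropout > nrow(coords)))
      stop("'dropout' indices out of range")
    coords <- coords[-dropout, , drop = FALSE]
  }
  trap_array(coords, kind = kind,
             operation = matrix(1, nrow(coords), n_occasions))
}

#' Rectangular state space around one or more detector arrays
#'
#' Buffers the joint coordinate extent of the supplied arrays by
#' `buffer_km` on every side. Density is expressed per 100 km^2 of this
#' rectangle's area.
#'
#' @param ... one or more [trap_array()] objects or J x 2 coordinate
#'   matrices.
#' @param buffer_km buffer width (km, > 0).
#' @return Object of class `state_space` with fields `xmin`, `xmax`,
#'   `ymin`, `ymax` and `area` (km^2).
#' @export
make_state_space <- function(..., buffer_km = 25) {
  if (buffer_km <= 0) stop("'buffer_km' must be positive")
  arrays <- list(...)
  if (length(arrays) == 0L) stop("at least one detector array is required")
  coords <- do.call(rbind, lapply(arrays, function(a) {
    if (inherits(a, "trap_array")) a$coords else as.matrix(a)
  }))
  if (nrow(coords) < 1L) stop("at least one detector is required")
  ss <- list(xmin = min(coords[, 1L]) - buffer_km,
             xmax = max(coords[, 1L]) + buffer_km,
             ymin = min(coords[, 2L]) - buffer_km,
             ymax = max(coords[, 2L]) + buffer_km)
  ss$area <- (ss$xmax - ss$xmin) * (ss$ymax - ss$ymin)
  structure(ss, class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> [%.2f, %.2f] x [%.2f, %.2f] km, area %.0f km^2\n",
              x$xmin, x$xmax, x$ymin, x$ymax, x$area))
  invisible(x)
}

#' Individual-by-trap exposure matrices and the mark-status matrix
#'
#' Computes the exposure of each individual to each detector -- the number
#' of occasions (trap-days for live-traps) during which the trap operated
#' and the individual was alive and in the population -- together with the
#' per-occasion mark-status matrix `m` for marked individuals
#' (0 = unmarked, 1 = marked, 2 = dead; dead is absorbing).
#'
#' Marking precedes resighting, so individuals retain full marking-period
#' exposure regardless of events on the resighting timescale. Events are
#' indexed on resighting occasions: `"marked"` at occasion k means the
#' individual carries a mark from occasion k onward (k = 1 for animals
#' marked before resighting began); `"died"` at occasion k means the animal
#' was dead from occasion k onward.
#'
#' @param live_operation J^M x K^M matrix of live-trap effort (days).
#' @param camera_operation J^R x K^R matrix of camera operation (0/1).
#' @param n_marked number of marked individuals.
#' @param events optional data frame with columns `individual`, `occasion`,
#'   `event` (`"marked"` or `"died"`); individuals absent from `events` are
#'   marked from occasion 1 and never die.
#' @return List with `E_M` (n_marked x J^M), `E_R` (n_marked x J^R),
#'   `m` (n_marked x K^R), and full-exposure row templates `eM_full`,
#'   `eR_full` used for augmented individuals.
#' @export
build_exposure <- function(live_operation, camera_operation, n_marked,
                           events = NULL) {
  live_operation <- as.matrix(live_operation)
  camera_operation <- as.matrix(camera_operation)
  JM <- nrow(live_operation); JR <- nrow(camera_operation)
  KR <- ncol(camera_operation)
  eM_full <- rowSums(live_operation)
  eR_full <- as.numeric(rowSums(camera_operation))

  m <- matrix(1L, n_marked, KR)
  if (!is.null(events) && nrow(events) > 0L) {
    if (!all(c("individual", "occasion", "event") %in% names(events)))
      stop("'events' needs columns individual, occasion, event")
    for (i in unique(events$individual)) {
      ev <- events[events$individual == i, , drop = FALSE]
      mk <- ev$occasion[ev$event == "marked"]
      dd <- ev$occasion[ev$event == "died"]
      mk <- if (length(mk)) min(mk) else 1L
      dd <- if (length(dd)) min(dd) else Inf
      if (dd < mk)
        stop(sprintf("individual %s recorded dead before being marked", i))
      row <- integer(KR)
      occ <- seq_len(KR)
      row[occ >= mk] <- 1L
      row[occ >= dd] <- 2L
      m[i, ] <- row
    }
  }

  alive <- m != 2L                      # n_marked x KR
  E_R <- alive %*% t(camera_operation)  # occasions trap on AND alive
  E_M <- matrix(rep(eM_full, each = n_marked), n_marked, JM)
  list(E_M = E_M, E_R = E_R, m = m, eM_full = eM_full, eR_full = eR_full)
}
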