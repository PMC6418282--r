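#' Read and write detector arrays
#'
#' Trap files are CSV with columns `trap_id`, `kind`, `x_km`, `y_km`,
#' followed by one column per occasion (0/1 operation for cameras, days
#' for live-traps).
#'
#' @param file path to a CSV file.
#' @return A [trap_array()].
#' @export
read_traps <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("trap_id", "kind", "x_km", "y_km")
  if (!all(need %in% names(df)))
    stop("trap file must have columns trap_id, kind, x_km, y_km, occ_*")
  occ <- setdiff(names(df), need)
  if (!length(occ)) stop("trap file has no occasion columns")
  op <- as.matrix(df[, occ, drop = FALSE])
  if (any(is.na(op)) || any(is.na(df$x_km)) || any(is.na(df$y_km)))
    stop(sprintf("malformed trap rows: %s",
                 paste(which(rowSums(is.na(cbind(op, df$x_km, df$y_km))) > 0),
                       collapse = ", ")))
  trap_array(cbind(df$x_km, df$y_km), kind = unique(df$kind)[1L],
             operation = op)
}

#' @rdname read_traps
#' @param traps a [trap_array()].
#' @export
write_traps <- function(traps, file) {
  J <- nrow(traps$coords)
  K <- ncol(traps$operation)
  df <- data.frame(trap_id = seq_len(J), kind = traps$kind,
                   x_km = traps$coords[, 1L], y_km = traps$coords[, 2L])
  op <- as.data.frame(traps$operation)
  names(op) <- paste0("occ_", seq_len(K))
  utils::write.csv(cbind(df, op), file, row.names = FALSE)
  invisible(file)
}

#' Write / read a complete SMR dataset as plain CSV files
#'
#' Serializes an [smr_data()] object into a directory:
#' `traps_live.csv`, `traps_cameras.csv`, `marking.csv` (individual x
#' live-trap capture counts in long form), `detections.csv` (identified
#' marked resights and identity-free unmarked records), `telemetry.csv`,
#' and `marked.csv` (per marked individual: sex, mark occasion, death
#' occasion). Exposure matrices are rebuilt on read from the operation
#' schedules and the marked table, so a write/read round trip reproduces
#' the object exactly.
#'
#' @param data an [smr_data()] object.
#' @param dir directory (created if needed).
#' @export
write_smr_data <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(data$live_traps))
    write_traps(data$live_traps, file.path(dir, "traps_live.csv"))
  write_traps(data$cameras, file.path(dir, "traps_cameras.csv"))
  if (!is.null(data$Y_M)) {
    nz <- which(data$Y_M > 0, arr.ind = TRUE)
    mk <- data.frame(individual_id = nz[, 1L], trap_id = nz[, 2L],
                     count = data$Y_M[nz])
    utils::write.csv(mk[order(mk$individual_id, mk$trap_id), ],
                     file.path(dir, "marking.csv"), row.names = FALSE)
  }
  mr <- data$marked_resights
  det <- rbind(
    data.frame(trap_id = mr$trap, occasion = mr$occasion, status = "marked",
               individual_id = mr$individual,
               observed_sex = ifelse(data$sex_marked[mr$individual] == 1L,
                                     "F", "M")),
    data.frame(trap_id = data$U$trap, occasion = data$U$occasion,
               status = "unmarked", individual_id = NA_integer_,
               observed_sex = data$U$obs_sex))
  det <- det[order(det$occasion, det$trap_id, det$status), ]
  det$record_id <- seq_len(nrow(det))
  utils::write.csv(det[, c("record_id", "trap_id", "occasion", "status",
                           "individual_id", "observed_sex")],
                   file.path(dir, "detections.csv"), row.names = FALSE)
  if (!is.null(data$telemetry))
    utils::write.csv(data$telemetry[, c("individual", "occasion", "x", "y")],
                     file.path(dir, "telemetry.csv"), row.names = FALSE)
  m <- data$exposure$m
  mark_occ <- apply(m, 1L, function(r) {
    w <- which(r == 1L); if (length(w)) min(w) else NA_integer_ })
  death_occ <- apply(m, 1L, function(r) {
    w <- which(r == 2L); if (length(w)) min(w) else NA_integer_ })
  utils::write.csv(
    data.frame(individual_id = seq_len(data$n_M),
               sex = ifelse(data$sex_marked == 1L, "F", "M"),
               mark_occasion = mark_occ, death_occasion = death_occ),
    file.path(dir, "marked.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_smr_data
#' @export
read_smr_data <- function(dir) {
  live <- if (file.exists(file.path(dir, "traps_live.csv")))
    read_traps(file.path(dir, "traps_live.csv")) else NULL
  cams <- read_traps(file.path(dir, "traps_cameras.csv"))
  marked <- utils::read.csv(file.path(dir, "marked.csv"),
                            stringsAsFactors = FALSE)
  n_M <- nrow(marked)
  Y_M <- NULL
  if (!is.null(live)) {
    Y_M <- matrix(0L, n_M, nrow(live$coords))
    if (file.exists(file.path(dir, "marking.csv"))) {
      mk <- utils::read.csv(file.path(dir, "marking.csv"))
      Y_M[cbind(mk$individual_id, mk$trap_id)] <- mk$count
    }
  }
  det <- utils::read.csv(file.path(dir, "detections.csv"),
                         stringsAsFactors = FALSE)
  bad <- which(!det$status %in% c("marked", "unmarked") |
                 !det$observed_sex %in% c("F", "M", "U") |
                 is.na(det$trap_id) | is.na(det$occasion))
  if (length(bad))
    stop(sprintf("malformed detection rows: %s", paste(bad, collapse = ", ")))
  mr <- det[det$status == "marked", , drop = FALSE]
  um <- det[det$status == "unmarked", , drop = FALSE]
  tel <- if (file.exists(file.path(dir, "telemetry.csv")))
    utils::read.csv(file.path(dir, "telemetry.csv")) else NULL
  events <- NULL
  ev <- list()
  for (i in seq_len(n_M)) {
    if (!is.na(marked$mark_occasion[i]) && marked$mark_occasion[i] > 1L)
      ev[[length(ev) + 1L]] <- data.frame(individual = i,
                                          occasion = marked$mark_occasion[i],
                                          event = "marked")
    if (!is.na(marked$death_occasion[i]))
      ev[[length(ev) + 1L]] <- data.frame(individual = i,
                                          occasion = marked$death_occasion[i],
                                          event = "died")
  }
  if (length(ev)) events <- do.call(rbind, ev)
  expo <- build_exposure(
    if (is.null(live)) matrix(0, 1L, 1L) else live$operation,
    cams$operation, n_marked = n_M, events = events)
  smr_data(live_traps = live, cameras = cams, Y_M = Y_M,
           marked_resights = data.frame(individual = mr$individual_id,
                                        trap = mr$trap_id,
                                        occasion = mr$occasion),
           U = data.frame(trap = um$trap_id, occasion = um$occasion,
                          obs_sex = um$observed_sex),
           telemetry = tel, sex_marked = marked$sex, exposure = expo)
}

#' Collapse time-stamped photo events into detections
#'
#' Applies the standard photo-processing rules: dependent kittens are
#' excluded; consecutive photographs at the same camera of the same
#' status (and, for identified animals, the same individual) are merged
#' into a single detection when separated by less than `window_hr` hours
#' (photographs one hour or more apart count as distinct detections); the
#' merged detection takes the non-unknown observed sex if the merged
#' photographs agree, otherwise unknown with a warning. Each detection is
#' assigned a survey occasion of `occasion_days` days counted from
#' `survey_start`.
#'
#' @param events data frame with columns `trap_id`, `timestamp`
#'   (POSIXct or parseable character), `status` (one of `marked_id`,
#'   `marked_unid`, `unmarked`, `unknown`), `individual_id` (required for
#'   `marked_id`), `observed_sex` ("F"/"M"/"U"), `age_class`
#'   (`independent`/`kitten`).
#' @param window_hr merge window in hours (default 1).
#' @param occasion_days days per occasion (default 7).
#' @param K number of occasions.
#' @param survey_start POSIXct start of the survey; defaults to midnight
#'   before the earliest event.
#' @return Data frame of detections: `trap_id`, `timestamp` (first photo),
#'   `occasion`, `status`, `individual_id`, `observed_sex`.
#' @export
collapse_events <- function(events, window_hr = 1.0, occasion_days = 7L,
                            K = 17L, survey_start = NULL) {
  ts <- events$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  if (any(is.na(ts))) stop("unparseable timestamps")
  events$timestamp <- ts
  if ("age_class" %in% names(events))
    events <- events[events$age_class != "kitten", , drop = FALSE]
  if (is.null(survey_start))
    survey_start <- trunc(min(events$timestamp), "days")
  events <- events[order(events$trap_id, events$timestamp), , drop = FALSE]
  if (!"individual_id" %in% names(events)) events$individual_id <- NA
  if (!"observed_sex" %in% names(events)) events$observed_sex <- "U"

  key <- paste(events$trap_id, events$status,
               ifelse(is.na(events$individual_id), "", events$individual_id))
  gap_hr <- c(Inf, diff(as.numeric(events$timestamp)) / 3600)
  same <- c(FALSE, key[-1L] == key[-length(key)])
  new_det <- !(same & gap_hr < window_hr)
  det_id <- cumsum(new_det)

  sex_of <- function(sx) {
    u <- unique(sx[sx != "U"])
    if (length(u) == 1L) u
    else if (length(u) > 1L) { warning("conflicting sexes within a merged detection"); "U" }
    else "U"
  }
  out <- do.call(rbind, lapply(split(seq_along(det_id), det_id), function(ii) {
    e <- events[ii, , drop = FALSE]
    data.frame(trap_id = e$trap_id[1L], timestamp = min(e$timestamp),
               status = e$status[1L], individual_id = e$individual_id[1L],
               observed_sex = sex_of(e$observed_sex))
  }))
  days <- as.numeric(difftime(out$timestamp, survey_start, units = "days"))
  out$occasion <- floor(days / occasion_days) + 1L
  drop <- out$occasion < 1L | out$occasion > K
  if (any(drop)) {
    warning(sprintf("%d detections outside the survey window dropped",
                    sum(drop)))
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out[order(out$occasion, out$trap_id, out$timestamp),
      c("trap_id", "timestamp", "occasion", "status", "individual_id",
        "observed_sex")]
}

#' Resolve unknown and unidentified mark statuses using telemetry
#'
#' A detection initially classed `marked_unid` or `unknown` is matched to
#' a collared individual if that individual has a telemetry fix within
#' `time_tol_hr` hours and `dist_tol_km` km of the camera. Exactly one
#' match: the detection becomes `marked_id` with that identity. No match:
#' `unknown` is reclassified `unmarked`; an unmatched `marked_unid` is an
#' error (a visibly collared animal must be resolvable). More than one
#' match: an error flags the record for manual resolution rather than
#' silently assigning an identity.
#'
#' @param detections output of [collapse_events()].
#' @param telemetry data frame `individual_id`, `timestamp`, `x_km`,
#'   `y_km` of raw (unthinned) fixes.
#' @param traps a [trap_array()]; `trap_id` indexes its rows.
#' @param time_tol_hr,dist_tol_km matching tolerances.
#' @return `detections` with `status` in \{`marked_id`, `unmarked`\} only.
#' @export
reconcile_mark_status <- function(detections, telemetry, traps,
                                  time_tol_hr = 2, dist_tol_km = 1) {
  tt <- telemetry$timestamp
  if (!inherits(tt, "POSIXct")) tt <- as.POSIXct(tt, tz = "UTC")
  for (r in seq_len(nrow(detections))) {
    if (detections$status[r] %in% c("marked_id", "unmarked")) next
    xy <- traps$coords[detections$trap_id[r], ]
    dt_hr <- abs(as.numeric(difftime(tt, detections$timestamp[r],
                                     units = "hours")))
    dist <- sqrt((telemetry$x_km - xy[1L])^2 + (telemetry$y_km - xy[2L])^2)
    hits <- unique(telemetry$individual_id[dt_hr <= time_tol_hr &
                                             dist <= dist_tol_km])
    if (length(hits) == 1L) {
      detections$status[r] <- "marked_id"
      detections$individual_id[r] <- hits
    } else if (length(hits) == 0L) {
      if (detections$status[r] == "marked_unid")
        stop(sprintf("row %d: collared but unidentifiable detection has no telemetry match", r))
      detections$status[r] <- "unmarked"
    } else {
      stop(sprintf("row %d: ambiguous telemetry match (individuals %s); resolve manually",
                   r, paste(hits, collapse = ", ")))
    }
  }
  detections
}

#' Thin telemetry to one fix per individual per occasion
#'
#' Retains one uniformly chosen fix per individual within each survey
#' occasion, reducing temporal dependence among locations.
#'
#' @param fixes data frame `individual_id`, `timestamp`, `x_km`, `y_km`.
#' @param survey_start POSIXct survey start.
#' @param occasion_days days per occasion.
#' @param K number of occasions; fixes outside 1..K are dropped.
#' @param seed optional RNG seed (same seed, same thinning).
#' @return Data frame `individual`, `occasion`, `x`, `y`.
#' @export
thin_telemetry <- function(fixes, survey_start, occasion_days = 7L, K = 17L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- fixes$timestamp
  if (!inherits(tt, "POSIXct")) tt <- as.POSIXct(tt, tz = "UTC")
  occ <- floor(as.numeric(difftime(tt, survey_start, units = "days")) /
                 occasion_days) + 1L
  keep <- occ >= 1L & occ <= K
  fixes <- fixes[keep, , drop = FALSE]
  occ <- occ[keep]
  idx <- unlist(lapply(split(seq_along(occ),
                             paste(fixes$individual_id, occ)), function(ii) {
    if (length(ii) == 1L) ii else sample(ii, 1L)
  }), use.names = FALSE)
  out <- data.frame(individual = fixes$individual_id[idx],
                    occasion = occ[idx], x = fixes$x_km[idx],
                    y = fixes$y_km[idx])
  out <- out[order(out$individual, out$occasion), ]
  rownames(out) <- NULL
  out
}

#' Convert longitude/latitude to planar kilometres
#'
#' Local equal-area (flat-earth) approximation about an origin: adequate
#' for study areas up to a few hundred kilometres across, which is the
#' regime all model distances are computed in.
#'
#' @param lon,lat coordinate vectors (degrees).
#' @param origin `c(lon0, lat0)`; defaults to the centroid.
#' @return Matrix with columns `x`, `y` (km) and attribute `origin`.
#' @export
latlon_to_km <- function(lon, lat, origin = NULL) {
  if (is.null(origin)) origin <- c(mean(lon), mean(lat))
  R <- 6371.0088
  x <- (pi / 180) * R * cos(origin[2L] * pi / 180) * (lon - origin[1L])
  y <- (pi / 180) * R * (lat - origin[2L])
  structure(cbind(x = x, y = y), origin = origin)
}

#' Write chains to CSV with a JSON sidecar of the run configuration
#'
#' @param chains an `smr_chains` object.
#' @param file CSV path; the sidecar is written next to it as
#'   `<file>.json`.
#' @export
write_chains <- function(chains, file) {
  utils::write.csv(as.data.frame(chains$draws), file, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    side <- list(area = chains$area, A = chains$A, n_M = chains$n_M,
                 config = chains$config[c("n_iter", "burn_in", "thin", "seed")])
    jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(file)
}
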