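#' @keywords internal
"_PACKAGE"

DETECTION_COLS <- c("id", "t", "x", "y", "z", "radius", "intensity", "eccentricity")

STATUS_LEVELS <- c("tracked", "unexplained_appearance", "deleted", "interpolated")

#' Tracking configuration
#'
#' Bundles every tunable of the tracing pipeline.  Distances are expressed in
#' microns after voxel scaling; all comparisons downstream assume isotropic
#' Euclidean space.
#'
#' @param safe_link_factor Fraction of the same-frame nearest-neighbor
#'   distance that a per-frame displacement must stay strictly below for a
#'   nearest-neighbor link to be considered safe (the "/2" of the safe-link
#'   displacement condition). In (0, 1].
#' @param bifurcation_distance_cutoff Candidate parents for an orphan are
#'   searched within this multiple of the candidate's radius.
#' @param termination_window_dt Temporal depth (frames) of the window, before
#'   a bifurcation, searched for terminating tracks (dangling ends).
#' @param termination_window_dx Spatial extent of that window, as a multiple
#'   of the median same-frame nearest-neighbor distance.
#' @param fp_max_track_length Typical maximal length (frames) of a track made
#'   of false-positive detections; used as a feature cap, not a hard rule.
#' @param max_other_iterations Maximum number of alternative parents tried
#'   for one orphan when bifurcations keep classifying as "other".
#' @param xy_resolution,z_resolution Microns per voxel, applied once at read
#'   time by [read_detections()].
#' @param rng_seed Seed for operations that need randomness (none of the
#'   tracing itself does; kept for provenance).
#' @return An object of class `tracking_config` (a validated list).
#' @export
tracking_config <- function(safe_link_factor = 0.5,
                            bifurcation_distance_cutoff = 3.0,
                            termination_window_dt = 3L,
                            termination_window_dx = 2.0,
                            fp_max_track_length = 3L,
                            max_other_iterations = 5L,
                            xy_resolution = 1.0,
                            z_resolution = 1.0,
                            rng_seed = 1L) {
  cfg <- list(
    safe_link_factor = as.numeric(safe_link_factor),
    bifurcation_distance_cutoff = as.numeric(bifurcation_distance_cutoff),
    termination_window_dt = as.integer(termination_window_dt),
    termination_window_dx = as.numeric(termination_window_dx),
    fp_max_track_length = as.integer(fp_max_track_length),
    max_other_iterations = as.integer(max_other_iterations),
    xy_resolution = as.numeric(xy_resolution),
    z_resolution = as.numeric(z_resolution),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$safe_link_factor > 0, cfg$safe_link_factor <= 1,
    cfg$bifurcation_distance_cutoff > 0,
    cfg$termination_window_dt >= 1,
    cfg$termination_window_dx > 0,
    cfg$fp_max_track_length >= 1,
    cfg$max_other_iterations >= 1,
    cfg$xy_resolution > 0, cfg$z_resolution > 0
  )
  structure(cfg, class = "tracking_config")
}

#' Build a detection table
#'
#' A detection is one observed nuclear object at one frame.  Coordinates are
#' in microns, `radius > 0`, `t >= 1` (1-based frames), `id` unique.
#' `eccentricity` is optional (NA when the detector does not report shape).
#'
#' @param id,t Integer vectors.
#' @param x,y,z,radius,intensity Numeric vectors (microns / arbitrary units).
#' @param eccentricity Numeric in \[0, 1\] or NA.
#' @return A `data.frame` with the canonical detection columns, sorted by id.
#' @export
detections <- function(id, t, x, y, z, radius, intensity,
                       eccentricity = NA_real_) {
  n <- length(id)
  rl <- function(v) rep_len(v, n)
  d <- data.frame(
    id = as.integer(id), t = rl(as.integer(t)),
    x = rl(as.numeric(x)), y = rl(as.numeric(y)), z = rl(as.numeric(z)),
    radius = rl(as.numeric(radius)), intensity = rl(as.numeric(intensity)),
    eccentricity = rl(as.numeric(eccentricity))
  )
  validate_detections(d)
  d[order(d$id), , drop = FALSE]
}

validate_detections <- function(d) {
  stopifnot(is.data.frame(d), all(DETECTION_COLS %in% names(d)))
  if (anyDuplicated(d$id)) stop("detection ids must be unique")
  if (nrow(d) > 0) {
    if (any(d$radius <= 0)) stop("radius must be > 0")
    if (any(d$t < 1)) stop("frame index t must be >= 1")
    if (any(d$intensity < 0)) stop("intensity must be >= 0")
  }
  invisible(d)
}

#' Create a lineage over a set of detections
#'
#' A lineage is the directed link structure of tracking: each detection has
#' at most one predecessor (previous frame) and at most two successors (next
#' frame; two marks a division).  Detections carry a status flag in
#' `tracked`, `unexplained_appearance`, `deleted`, `interpolated`.  Deleted
#' detections are kept (for provenance) but participate in no links.
#'
#' @param det Detection table as from [detections()].
#' @return An object of class `lineage`.
#' @export
lineage <- function(det) {
  det <- det[order(det$id), , drop = FALSE]
  rownames(det) <- NULL
  validate_detections(det)
  n <- nrow(det)
  structure(list(
    det = det,
    pred = rep(NA_integer_, n),
    succ1 = rep(NA_integer_, n),
    succ2 = rep(NA_integer_, n),
    status = rep("tracked", n)
  ), class = "lineage")
}

lin_row <- function(lin, id) {
  r <- match(id, lin$det$id)
  if (anyNA(r)) stop("unknown detection id(s): ", paste(id[is.na(r)], collapse = ","))
  r
}

#' @export
print.lineage <- function(x, ...) {
  nl <- sum(!is.na(x$succ1)) + sum(!is.na(x$succ2))
  cat(sprintf(
    "<lineage> %d detections over frames %s; %d links; status: %s\n",
    nrow(x$det),
    if (nrow(x$det)) paste(range(x$det$t), collapse = "-") else "-",
    nl,
    paste(sprintf("%s=%d", names(table(x$status)), table(x$status)), collapse = ", ")
  ))
  invisible(x)
}

#' Number of successors / accessors
#' @rdname lineage-accessors
#' @param lin A lineage.
#' @param id Detection id.
#' @return `successors()` an integer vector of 0-2 ids; `predecessor()` an id
#'   or NA; `detection_status()` a status string.
#' @export
successors <- function(lin, id) {
  r <- lin_row(lin, id)
  s <- c(lin$succ1[r], lin$succ2[r])
  s[!is.na(s)]
}

#' @rdname lineage-accessors
#' @export
predecessor <- function(lin, id) lin$pred[lin_row(lin, id)]

#' @rdname lineage-accessors
#' @export
detection_status <- function(lin, id) lin$status[lin_row(lin, id)]

#' Add a link between consecutive frames
#'
#' Records that `pred_id` (frame t) tracks onto `succ_id` (frame t+1).
#' Violating any structural precondition is a caller bug and signals an
#' error: the link must span exactly one frame, the successor must not
#' already have a predecessor, the predecessor must have fewer than two
#' successors, and neither endpoint may be deleted.
#'
#' @param lin A lineage.
#' @param pred_id,succ_id Detection ids.
#' @return The modified lineage.
#' @export
add_link <- function(lin, pred_id, succ_id) {
  rp <- lin_row(lin, pred_id); rs <- lin_row(lin, succ_id)
  if (lin$det$t[rs] - lin$det$t[rp] != 1L)
    stop("link must span exactly one frame (", lin$det$t[rp], " -> ", lin$det$t[rs], ")")
  if (!is.na(lin$pred[rs]))
    stop("detection ", succ_id, " already has a predecessor")
  if (!is.na(lin$succ1[rp]) && !is.na(lin$succ2[rp]))
    stop("detection ", pred_id, " already has two successors")
  if (lin$status[rp] == "deleted" || lin$status[rs] == "deleted")
    stop("deleted detections participate in no links")
  if (is.na(lin$succ1[rp])) lin$succ1[rp] <- as.integer(succ_id)
  else lin$succ2[rp] <- as.integer(succ_id)
  lin$pred[rs] <- as.integer(pred_id)
  lin
}

#' Remove an existing link
#' @inheritParams add_link
#' @return The modified lineage.
#' @export
remove_link <- function(lin, pred_id, succ_id) {
  rp <- lin_row(lin, pred_id); rs <- lin_row(lin, succ_id)
  if (identical(lin$succ1[rp], as.integer(succ_id))) {
    lin$succ1[rp] <- lin$succ2[rp]; lin$succ2[rp] <- NA_integer_
  } else if (identical(lin$succ2[rp], as.integer(succ_id))) {
    lin$succ2[rp] <- NA_integer_
  } else stop("no link ", pred_id, " -> ", succ_id)
  lin$pred[rs] <- NA_integer_
  lin
}

#' Flag a detection's status
#'
#' Setting status to `deleted` also severs every link touching the
#' detection, preserving the invariant that deleted detections are isolated.
#'
#' @inheritParams add_link
#' @param id Detection id.
#' @param status One of `tracked`, `unexplained_appearance`, `deleted`,
#'   `interpolated`.
#' @return The modified lineage.
#' @export
set_status <- function(lin, id, status) {
  status <- match.arg(status, STATUS_LEVELS)
  r <- lin_row(lin, id)
  if (status == "deleted") {
    p <- lin$pred[r]
    if (!is.na(p)) lin <- remove_link(lin, p, id)
    for (s in successors(lin, id)) lin <- remove_link(lin, id, s)
    r <- lin_row(lin, id)
  }
  lin$status[r] <- status
  lin
}

#' Append a detection (used by gap interpolation)
#' @inheritParams add_link
#' @param t,x,y,z,radius,intensity,eccentricity Detection fields.
#' @param status Initial status flag.
#' @return `list(lineage = <modified>, id = <new id>)`.
#' @export
add_detection <- function(lin, t, x, y, z, radius, intensity,
                          eccentricity = NA_real_, status = "tracked") {
  id <- if (nrow(lin$det)) max(lin$det$id) + 1L else 1L
  row <- data.frame(id = id, t = as.integer(t), x = x, y = y, z = z,
                    radius = radius, intensity = intensity,
                    eccentricity = as.numeric(eccentricity))
  lin$det <- rbind(lin$det, row)
  lin$pred <- c(lin$pred, NA_integer_)
  lin$succ1 <- c(lin$succ1, NA_integer_)
  lin$succ2 <- c(lin$succ2, NA_integer_)
  lin$status <- c(lin$status, match.arg(status, STATUS_LEVELS))
  list(lineage = lin, id = id)
}

#' Check every lineage invariant
#'
#' Verifies: links span exactly one frame, at most one predecessor and two
#' successors per detection, link reciprocity (pred and succ slots agree),
#' and isolation of deleted detections.  Errors on the first violation.
#'
#' @param lin A lineage.
#' @return The lineage, invisibly.
#' @export
validate_lineage <- function(lin) {
  d <- lin$det
  ok <- !is.na(lin$pred)
  if (any(ok)) {
    rp <- match(lin$pred[ok], d$id)
    if (anyNA(rp)) stop("predecessor id not in detection set")
    if (any(d$t[ok] - d$t[rp] != 1L)) stop("link spans != 1 frame")
    # reciprocity: this id must be a successor of its predecessor
    here <- d$id[ok]
    if (!all(lin$succ1[rp] == here | (!is.na(lin$succ2[rp]) & lin$succ2[rp] == here), na.rm = FALSE))
      stop("pred/succ slots disagree")
  }
  for (slot in list(lin$succ1, lin$succ2)) {
    ok <- !is.na(slot)
    if (any(ok)) {
      rs <- match(slot[ok], d$id)
      if (anyNA(rs)) stop("successor id not in detection set")
      if (any(d$t[rs] - d$t[ok] != 1L)) stop("link spans != 1 frame")
      if (!all(lin$pred[rs] == d$id[ok])) stop("succ/pred slots disagree")
    }
  }
  succ_ids <- c(lin$succ1, lin$succ2)
  if (anyDuplicated(succ_ids[!is.na(succ_ids)]))
    stop("a detection has more than one predecessor")
  del <- lin$status == "deleted"
  if (any(del) &&
      (any(!is.na(lin$pred[del])) || any(!is.na(lin$succ1[del])) || any(!is.na(lin$succ2[del]))))
    stop("deleted detections participate in links")
  invisible(lin)
}

#' Partition a lineage into tracks
#'
#' A track is a maximal chain of 1:1 links; boundaries sit exactly at
#' divisions (two successors), appearances (no predecessor) and terminations
#' (no successor).  Every non-deleted detection belongs to exactly one track.
#'
#' @param lin A lineage.
#' @return A list of tracks, each a list with `ids` (ordered detection ids),
#'   `start_t`, `end_t` and `length` (frames).
#' @export
tracks_of <- function(lin) {
  d <- lin$det
  alive <- lin$status != "deleted"
  if (!any(alive)) return(list())
  pred_row <- match(lin$pred, d$id)
  # a detection starts a track if it has no predecessor, or its predecessor divides
  divides <- !is.na(lin$succ1) & !is.na(lin$succ2)
  starts <- d$id[alive & (is.na(lin$pred) | divides[pred_row])]
  lapply(sort(starts), function(s) {
    ids <- s
    cur <- s
    repeat {
      r <- match(cur, d$id)
      if (!is.na(lin$succ2[r]) || is.na(lin$succ1[r])) break
      cur <- lin$succ1[r]
      ids <- c(ids, cur)
    }
    ts <- d$t[match(ids, d$id)]
    list(ids = ids, start_t = ts[1], end_t = ts[length(ts)],
         length = ts[length(ts)] - ts[1] + 1L)
  })
}

#' Forward branch length from a detection
#'
#' Walks 1:1 links forward from `id` until a termination or a division,
#' counting frames (including the starting one), capped at `cap`.  A branch
#' that ends in a division returns `cap`: the cell demonstrably continues,
#' so for false-positive screening (spurious tracks only last a few frames
#' and never divide) it counts as long.
#' @param lin A lineage.
#' @param id Starting detection id.
#' @param cap Maximum count returned.
#' @return Integer length in frames.
#' @export
branch_length <- function(lin, id, cap = 10L) {
  n <- 1L
  cur <- id
  while (n < cap) {
    r <- lin_row(lin, cur)
    if (!is.na(lin$succ2[r])) return(cap)  # divides: not a terminating track
    if (is.na(lin$succ1[r])) break
    cur <- lin$succ1[r]
    n <- n + 1L
  }
  n
}

#' Detections of the branch (track) starting at a detection
#' @keywords internal
branch_ids <- function(lin, id) {
  ids <- id
  cur <- id
  repeat {
    r <- lin_row(lin, cur)
    if (is.na(lin$succ1[r]) || !is.na(lin$succ2[r])) break
    cur <- lin$succ1[r]
    ids <- c(ids, cur)
  }
  ids
}

#' All links of a lineage as a two-column data frame
#' @param lin A lineage.
#' @return data.frame with columns `pred_id`, `succ_id`.
#' @export
links_of <- function(lin) {
  ids <- lin$det$id
  out <- rbind(
    data.frame(pred_id = ids, succ_id = lin$succ1),
    data.frame(pred_id = ids, succ_id = lin$succ2)
  )
  out <- out[!is.na(out$succ_id), , drop = FALSE]
  out <- out[order(out$pred_id, out$succ_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
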