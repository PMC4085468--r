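# Phase 2: tentative bifurcations and their semi-local neighborhoods.
#
# Every local increase in cell count leaves at least one detection without a
# backward link (an orphan).  Each orphan is forced into a tentative 1-to-2
# match with a nearby parent; pairing the bifurcation with a nearby
# terminating track (dangling end) defines the semi-local neighborhood on
# which classification operates.

new_bifurcation <- function(parent_id, child_a_id, child_b_id,
                            division_score = NA_real_, distance = NA_real_,
                            creation_round = 1L) {
  structure(list(parent_id = as.integer(parent_id),
                 child_a_id = as.integer(child_a_id),  # pre-existing successor, NA if none
                 child_b_id = as.integer(child_b_id),  # the orphan
                 division_score = division_score,
                 distance = distance,
                 creation_round = as.integer(creation_round)),
            class = "bifurcation")
}

bif_children <- function(bif) {
  ch <- c(bif$child_a_id, bif$child_b_id)
  ch[!is.na(ch)]
}

#' Find orphan detections
#'
#' Orphans are non-first-frame detections without a predecessor that have
#' not been deleted or already written off as unexplained appearances.
#'
#' @param lin A lineage.
#' @return Sorted integer vector of detection ids.
#' @export
find_orphans <- function(lin) {
  if (nrow(lin$det) == 0) return(integer())
  t0 <- min(lin$det$t)
  sort(lin$det$id[lin$det$t > t0 & is.na(lin$pred) &
                    !(lin$status %in% c("deleted", "unexplained_appearance"))])
}

#' Rank candidate parents for an orphan
#'
#' Candidates are non-deleted detections one frame earlier, within
#' `bifurcation_distance_cutoff` times their own radius of the orphan, and
#' with room for another successor.  Each candidate yields a tentative
#' bifurcation whose first child is the candidate's existing phase-1
#' successor (absent for a parent with none, in which case the bifurcation
#' degenerates to a tentative 1:1 attachment handled by the same machinery).
#'
#' Candidates are ranked by division score, descending: the Naive Bayes
#' division posterior of the candidate's neighborhood when `model` is given
#' (floored at 1e-6 so that vanishing posteriors tie instead of ranking by
#' numerical noise), otherwise negative distance (nearest first).  Ties
#' break toward the nearer, then the lower-id, parent.
#'
#' @param orphan_id Orphan detection id.
#' @param lin A lineage.
#' @param config A [tracking_config()].
#' @param model Optional [nb_model] used for division scoring.
#' @return List of `bifurcation` objects, best first; empty if no candidate
#'   lies within the cutoff.
#' @export
candidate_parents <- function(orphan_id, lin, config, model = NULL) {
  ro <- lin_row(lin, orphan_id)
  t1 <- lin$det$t[ro]
  op <- as.numeric(lin$det[ro, c("x", "y", "z")])
  cand <- which(lin$det$t == t1 - 1L & lin$status != "deleted" &
                  is.na(lin$succ2))
  if (length(cand) == 0) return(list())
  dd <- sqrt(colSums((t(as.matrix(lin$det[cand, c("x", "y", "z")])) - op)^2))
  keep <- dd <= config$bifurcation_distance_cutoff * lin$det$radius[cand]
  cand <- cand[keep]; dd <- dd[keep]
  if (length(cand) == 0) return(list())
  bifs <- lapply(seq_along(cand), function(k) {
    r <- cand[k]
    new_bifurcation(lin$det$id[r], lin$succ1[r], orphan_id,
                    division_score = -dd[k], distance = dd[k])
  })
  if (!is.null(model)) {
    for (k in seq_along(bifs)) {
      nbh <- build_neighborhood(bifs[[k]],
                                find_terminations(lin, bifs[[k]], config), lin)
      fv <- extract_features(nbh, lin, config)
      # floor: posteriors this small carry no ranking information, and
      # letting their noise order the candidates lets arbitrary parents win;
      # sub-floor candidates tie and fall back to proximity
      bifs[[k]]$division_score <- max(nb_posterior(model, fv)["division"], 1e-6)
    }
  }
  sc <- vapply(bifs, function(b) b$division_score, numeric(1))
  dist <- vapply(bifs, function(b) b$distance, numeric(1))
  pid <- vapply(bifs, function(b) b$parent_id, integer(1))
  # rank on a coarsened score: posteriors within a decile (e.g. two adjacent
  # simultaneous divisions both near 1) are not meaningfully ordered, and
  # proximity is the right arbiter between them -- a daughter lies within a
  # fraction of a radius of her own mother
  if (!is.null(model)) sc_rank <- round(sc, 1) else sc_rank <- sc
  bifs[order(-sc_rank, dist, pid)]
}

#' Candidate terminating tracks near a bifurcation
#'
#' Dangling ends (detections with no forward link) in the spatiotemporal
#' window before the bifurcation: at most `termination_window_dt` frames
#' before the parent frame and within `termination_window_dx` times the
#' median same-frame nearest-neighbor distance of the bifurcation centroid.
#'
#' @param lin A lineage.
#' @param bif A bifurcation.
#' @param config A [tracking_config()].
#' @return data.frame with columns `id`, `t`, `gap_frames`, `dist`, ordered
#'   by increasing distance (ties toward the lower id).
#' @export
find_terminations <- function(lin, bif, config) {
  rp <- lin_row(lin, bif$parent_id)
  t_par <- lin$det$t[rp]
  members <- c(bif$parent_id, bif_children(bif))
  ends <- which(is.na(lin$succ1) & lin$status != "deleted" &
                  lin$det$t >= t_par - config$termination_window_dt &
                  lin$det$t <= t_par & !(lin$det$id %in% members))
  out <- data.frame(id = integer(), t = integer(), gap_frames = integer(),
                    dist = numeric())
  if (length(ends) == 0) return(out)
  pts <- lin$det[c(rp, match(bif_children(bif), lin$det$id)), c("x", "y", "z")]
  centroid <- colMeans(as.matrix(pts))
  dd <- sqrt(colSums((t(as.matrix(lin$det[ends, c("x", "y", "z")])) - centroid)^2))
  mnn <- median_nn_dist(lin$det[lin$det$t == t_par & lin$status != "deleted", , drop = FALSE])
  lim <- if (is.na(mnn)) Inf else config$termination_window_dx * mnn
  keep <- dd <= lim
  ends <- ends[keep]; dd <- dd[keep]
  if (length(ends) == 0) return(out)
  out <- data.frame(id = lin$det$id[ends], t = lin$det$t[ends],
                    gap_frames = t_par - lin$det$t[ends], dist = dd)
  out <- out[order(out$dist, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a semi-local neighborhood around a bifurcation
#'
#' Enumerates every pairing of a candidate terminating end with an
#' assignment of the bifurcation children to the parent- and
#' termination-continuations, and keeps the pairing with minimal total
#' Euclidean displacement of the matched endpoints (detections inside a
#' proposed false-negative gap are ignored, as they are unreliable if a gap
#' is real).  With no candidate termination the hypothesis is simply parent
#' to nearest child.
#'
#' @param bif A bifurcation.
#' @param terminations data.frame from [find_terminations()].
#' @param lin A lineage.
#' @return A `neighborhood` list: `bifurcation`, `termination_id` (NA if
#'   none used), `gap_frames`, `hypothesis` (`parent_child`, `term_child`),
#'   and `pairings`, the full enumeration with displacements (audit trail
#'   for the minimality invariant).
#' @export
build_neighborhood <- function(bif, terminations, lin) {
  pos <- function(id) as.numeric(lin$det[lin_row(lin, id), c("x", "y", "z")])
  p <- pos(bif$parent_id)
  ch <- bif_children(bif)
  dp <- vapply(ch, function(c) sqrt(sum((pos(c) - p)^2)), numeric(1))

  pairings <- data.frame(term_id = integer(), parent_child = integer(),
                         term_child = integer(), gap_frames = integer(),
                         displacement = numeric())
  if (nrow(terminations) > 0) {
    for (k in seq_len(nrow(terminations))) {
      e <- pos(terminations$id[k])
      de <- vapply(ch, function(c) sqrt(sum((pos(c) - e)^2)), numeric(1))
      if (length(ch) == 2) {
        pairings <- rbind(pairings, data.frame(
          term_id = terminations$id[k],
          parent_child = ch, term_child = rev(ch),
          gap_frames = terminations$gap_frames[k],
          displacement = c(dp[1] + de[2], dp[2] + de[1])))
      } else {
        # degenerate bifurcation: the single child continues either the
        # parent or the terminating track
        pairings <- rbind(pairings, data.frame(
          term_id = c(NA_integer_, terminations$id[k]),
          parent_child = c(ch, NA_integer_),
          term_child = c(NA_integer_, ch),
          gap_frames = c(0L, terminations$gap_frames[k]),
          displacement = c(dp[1], de[1])))
      }
    }
    pairings <- unique(pairings)
    best <- pairings[order(pairings$displacement, pairings$term_id,
                           pairings$parent_child, na.last = TRUE), ][1, ]
    hyp <- list(parent_child = best$parent_child, term_child = best$term_child)
    term_id <- best$term_id
    gap <- if (is.na(term_id)) 0L else as.integer(best$gap_frames)
  } else {
    hyp <- list(parent_child = ch[which.min(dp)], term_child = NA_integer_)
    term_id <- NA_integer_
    gap <- 0L
  }
  structure(list(bifurcation = bif, termination_id = term_id,
                 gap_frames = gap, hypothesis = hyp, pairings = pairings),
            class = "neighborhood")
}
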