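# Phase 3/4: class-specific tracking actions and the orchestration loop.
#
# One action per class: divisions are accepted; two-cell (movement / FN)
# neighborhoods are dissolved into the minimal-displacement 1:1 chains with
# linear interpolation across detection gaps; FP branches are deleted;
# "other" bifurcations trigger reassignment of the worse-matching child to
# its next best parent.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Continuation score of a child as the 1:1 successor of a parent
#'
#' Symmetric appearance-and-motion score; higher is a better non-dividing
#' continuation.  Used to pick the worse match in "other" bifurcations.
#' `-(displacement/parent radius)^2 - log(size ratio)^2 - log(intensity
#' ratio)^2`.
#'
#' @param lin A lineage.
#' @param parent_id,child_id Detection ids one frame apart.
#' @return Numeric score (<= 0).
#' @export
continuation_score <- function(lin, parent_id, child_id) {
  rp <- lin_row(lin, parent_id); rc <- lin_row(lin, child_id)
  d <- sqrt(sum((as.numeric(lin$det[rc, c("x", "y", "z")]) -
                   as.numeric(lin$det[rp, c("x", "y", "z")]))^2))
  sz <- log(lin$det$radius[rc] / lin$det$radius[rp])
  it <- log(pmax(lin$det$intensity[rc], 1e-12) / pmax(lin$det$intensity[rp], 1e-12))
  -((d / lin$det$radius[rp])^2 + sz^2 + it^2)
}

#' Accept a bifurcation as a cell division
#'
#' Links the parent to the orphan child (the other child, when present, is
#' already linked).  Re-applying is a structural error: the child would
#' already have a predecessor.
#'
#' @param nbh A neighborhood.
#' @param lin A lineage.
#' @return The modified lineage.
#' @export
apply_division <- function(nbh, lin) {
  bif <- nbh$bifurcation
  add_link(lin, bif$parent_id, bif$child_b_id)
}

# insert linearly interpolated detections between two endpoint detections
# (exclusive) and chain links from `from_id` to `to_id`.
interpolate_gap <- function(lin, from_id, to_id) {
  rf <- lin_row(lin, from_id); rt <- lin_row(lin, to_id)
  t0 <- lin$det$t[rf]; t1 <- lin$det$t[rt]
  steps <- t1 - t0
  stopifnot(steps >= 1)
  prev <- from_id
  if (steps > 1) {
    a <- lin$det[rf, ]; b <- lin$det[rt, ]
    for (k in seq_len(steps - 1)) {
      w <- k / steps
      res <- add_detection(lin,
        t = t0 + k,
        x = (1 - w) * a$x + w * b$x,
        y = (1 - w) * a$y + w * b$y,
        z = (1 - w) * a$z + w * b$z,
        radius = (1 - w) * a$radius + w * b$radius,
        intensity = (1 - w) * a$intensity + w * b$intensity,
        status = "interpolated")
      lin <- res$lineage
      lin <- add_link(lin, prev, res$id)
      prev <- res$id
    }
  }
  add_link(lin, prev, to_id)
}

#' Resolve a bifurcation as two non-dividing cells
#'
#' Dissolves the bifurcation into the 1:1 chains chosen by the
#' minimal-displacement hypothesis.  When the matched terminating track ends
#' more than one frame before the bifurcation children, the detection gap is
#' filled with linearly interpolated synthetic detections (position, radius
#' and intensity all linear), flagged `interpolated`.  A phase-1 link that
#' contradicts the hypothesis (the parent's successor being reassigned to
#' the terminating track) is rewired.
#'
#' Without a termination in the neighborhood the action falls back to a
#' plain 1:1 re-match: the child with the better continuation score keeps
#' the parent and the other is re-queued as an orphan.
#'
#' @param nbh A neighborhood.
#' @param lin A lineage.
#' @param config A [tracking_config()].
#' @return `list(lineage = <modified>, requeue = <ids to re-process>)`.
#' @export
apply_two_cell <- function(nbh, lin, config) {
  bif <- nbh$bifurcation
  p <- bif$parent_id; a <- bif$child_a_id; o <- bif$child_b_id
  requeue <- integer()
  if (!is.na(nbh$termination_id)) {
    pc <- nbh$hypothesis$parent_child
    ec <- nbh$hypothesis$term_child
    # free the child claimed by the terminating track if phase 1 gave it to
    # the parent
    if (!is.na(ec) && !is.na(a) && ec == a) lin <- remove_link(lin, p, a)
    if (!is.na(ec)) lin <- interpolate_gap(lin, nbh$termination_id, ec)
    if (!is.na(pc) && pc == o) lin <- add_link(lin, p, o)
  } else if (is.na(a)) {
    # degenerate bifurcation, no termination: plain 1:1 attachment
    lin <- add_link(lin, p, o)
  } else {
    sa <- continuation_score(lin, p, a)
    so <- continuation_score(lin, p, o)
    if (so > sa) {
      lin <- remove_link(lin, p, a)
      lin <- add_link(lin, p, o)
      requeue <- a
    } else {
      requeue <- o
    }
  }
  list(lineage = lin, requeue = requeue)
}

#' Delete the false-positive branch of a bifurcation
#'
#' Of the two branch tracks through the bifurcation children, the one
#' deemed the FP is deleted: its detections are flagged `deleted` and all
#' their links removed.  Spurious tracks only last a few frames and never
#' divide, so a branch that divides or outlives `fp_max_track_length`
#' frames is never deleted in favor of one that does not.  When both
#' branches are within the FP-length regime (links around a fresh FP are
#' often conflicted, making raw track length unreliable) the branch with
#' the worse appearance-and-motion [continuation_score()] against the
#' parent is deleted; exact ties break toward the lower summed intensity
#' (dimmer objects are likelier optical artifacts), then toward the orphan
#' branch.  If the surviving branch was the orphan, it inherits the parent
#' link.
#'
#' @param nbh A neighborhood.
#' @param lin A lineage.
#' @param config A [tracking_config()].
#' @return The modified lineage.
#' @export
apply_fp <- function(nbh, lin, config = tracking_config()) {
  bif <- nbh$bifurcation
  p <- bif$parent_id; a <- bif$child_a_id; o <- bif$child_b_id
  ob <- branch_ids(lin, o)
  if (is.na(a)) {
    del <- ob; survivor <- NA_integer_
  } else {
    ab <- branch_ids(lin, a)
    # a branch ending in a division demonstrably continues: never the FP
    blen <- function(ids) {
      last <- lin_row(lin, ids[length(ids)])
      if (!is.na(lin$succ2[last])) Inf else length(ids)
    }
    la <- blen(ab); lo <- blen(ob)
    cap <- config$fp_max_track_length
    if (xor(la > cap, lo > cap)) {
      del_o <- lo <= cap
    } else {
      sa <- continuation_score(lin, p, a)
      so <- continuation_score(lin, p, o)
      if (so != sa) del_o <- so < sa
      else {
        ia <- sum(lin$det$intensity[match(ab, lin$det$id)])
        io <- sum(lin$det$intensity[match(ob, lin$det$id)])
        del_o <- io <= ia
      }
    }
    if (del_o) { del <- ob; survivor <- NA_integer_ }
    else { del <- ab; survivor <- o }
  }
  for (id in del) lin <- set_status(lin, id, "deleted")
  if (!is.na(survivor)) lin <- add_link(lin, p, survivor)
  lin
}

#' Reassign the worse match of an "other" bifurcation
#'
#' The child with the worse continuation score is detached and attached to
#' its next best bifurcation, which is rebuilt and reclassified; iterates up
#' to `max_other_iterations` times over remaining candidates.  When all
#' acceptable bifurcations are exhausted the cell is left as an unexplained
#' appearance.
#'
#' @param nbh A neighborhood classified as "other".
#' @param lin A lineage.
#' @param model An `nb_model` used for reclassification and candidate
#'   ranking.
#' @param config A [tracking_config()].
#' @return `list(lineage, log)` where `log` records each retried
#'   bifurcation.
#' @export
apply_other <- function(nbh, lin, model, config) {
  classify_fun <- function(nb, li) nb_classify(model, nb, li, config)
  st <- resolve_other(nbh, lin, config, classify_fun, model,
                      tried = nbh$bifurcation$parent_id)
  list(lineage = st$lineage, log = st$log)
}

# one "other" resolution: detach the worse child and walk its remaining
# candidate parents until some class other than "other" resolves it.
resolve_other <- function(nbh, lin, config, classify_fun, rank_model, tried) {
  bif <- nbh$bifurcation
  log <- list()
  if (!is.na(bif$child_a_id)) {
    sa <- continuation_score(lin, bif$parent_id, bif$child_a_id)
    so <- continuation_score(lin, bif$parent_id, bif$child_b_id)
    if (sa < so) {
      lin <- remove_link(lin, bif$parent_id, bif$child_a_id)
      lin <- add_link(lin, bif$parent_id, bif$child_b_id)
      mover <- bif$child_a_id
    } else mover <- bif$child_b_id
  } else mover <- bif$child_b_id

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > config$max_other_iterations) {
      lin <- set_status(lin, mover, "unexplained_appearance")
      break
    }
    cands <- candidate_parents(mover, lin, config, rank_model)
    cands <- Filter(function(b) !(b$parent_id %in% tried), cands)
    if (!length(cands)) {
      lin <- set_status(lin, mover, "unexplained_appearance")
      break
    }
    b2 <- cands[[1]]
    tried <- c(tried, b2$parent_id)
    nb2 <- build_neighborhood(b2, find_terminations(lin, b2, config), lin)
    res <- classify_fun(nb2, lin)
    log[[length(log) + 1L]] <- list(bifurcation = b2, class = res$class,
                                    posterior = res$posterior)
    if (res$class == "division") {
      lin <- apply_division(nb2, lin); break
    } else if (res$class == "two_cell") {
      r <- apply_two_cell(nb2, lin, config)
      lin <- r$lineage
      if (length(r$requeue) && r$requeue != mover) {
        mover <- r$requeue; next
      } else if (length(r$requeue)) next  # mover itself re-queued: try next candidate
      break
    } else if (res$class == "fp") {
      lin <- apply_fp(nb2, lin, config); break
    } else {
      if (!is.na(b2$child_a_id)) {
        sa <- continuation_score(lin, b2$parent_id, b2$child_a_id)
        so <- continuation_score(lin, b2$parent_id, mover)
        if (sa < so) {
          lin <- remove_link(lin, b2$parent_id, b2$child_a_id)
          lin <- add_link(lin, b2$parent_id, mover)
          mover <- b2$child_a_id
        }
      }
    }
  }
  list(lineage = lin, log = log, mover = mover)
}

#' Trace a full lineage from detections
#'
#' Runs phase-1 conservative linking, then sweeps frames chronologically:
#' every orphan is forced into its best tentative bifurcation, the
#' bifurcation's semi-local neighborhood is classified, and the
#' class-specific action applied, until no orphan is actionable.  The
#' tracing itself is deterministic: identical inputs give identical output.
#'
#' @param det Detection table (all frames).
#' @param model A fitted `nb_model`.
#' @param config A [tracking_config()].
#' @param classify_fun Optional override of the classifier: a
#'   `function(neighborhood, lineage)` returning `list(class, posterior)`
#'   (used for truth-guided training).
#' @param rank_model Model used to rank candidate parents; defaults to
#'   `model`; NULL ranks by distance.
#' @param candidate_hook Optional `function(orphan_id, candidates, lineage)`
#'   called before each selection (training-set harvesting).
#' @return `list(lineage, log)`; `log` is a data.frame with one row per
#'   classified bifurcation (frame, ids, class, action, posterior) plus a
#'   `features` matrix attribute — the machine-readable bookkeeping of every
#'   decision.
#' @export
trace_lineage <- function(det, model, config,
                          classify_fun = NULL, rank_model = model,
                          candidate_hook = NULL) {
  if (is.null(classify_fun)) {
    stopifnot(inherits(model, "nb_model"))
    classify_fun <- function(nb, li) nb_classify(model, nb, li, config)
  }
  lin <- link_all(det, config)
  entries <- list()
  if (nrow(lin$det) == 0) return(list(lineage = lin, log = empty_log()))
  frames <- sort(unique(lin$det$t))
  for (tt in frames[-1]) {
    orph <- find_orphans(lin)
    queue <- sort(orph[lin$det$t[match(orph, lin$det$id)] == tt])
    tried <- list()
    iters <- list()
    guard <- 0L
    while (length(queue)) {
      guard <- guard + 1L
      if (guard > 20L * nrow(lin$det)) stop("resolution loop failed to terminate")
      o <- queue[1]; queue <- queue[-1]
      ro <- lin_row(lin, o)
      if (!is.na(lin$pred[ro]) ||
          lin$status[ro] %in% c("deleted", "unexplained_appearance")) next
      key <- as.character(o)
      if ((iters[[key]] %||% 0L) >= config$max_other_iterations) {
        lin <- set_status(lin, o, "unexplained_appearance")
        entries[[length(entries) + 1L]] <- log_entry(tt, o, NA, NA, NA, NA,
                                                     "none", "unexplained", NULL, NULL)
        next
      }
      cands <- candidate_parents(o, lin, config, rank_model)
      if (!is.null(candidate_hook)) candidate_hook(o, cands, lin)
      cands <- Filter(function(b) !(b$parent_id %in% tried[[key]]), cands)
      if (!length(cands)) {
        lin <- set_status(lin, o, "unexplained_appearance")
        entries[[length(entries) + 1L]] <- log_entry(tt, o, NA, NA, NA, NA,
                                                     "none", "unexplained", NULL, NULL)
        next
      }
      bif <- cands[[1]]
      tried[[key]] <- c(tried[[key]], bif$parent_id)
      nbh <- build_neighborhood(bif, find_terminations(lin, bif, config), lin)
      res <- classify_fun(nbh, lin)
      action <- res$class
      if (res$class == "division") {
        lin <- apply_division(nbh, lin)
        action <- "accept_division"
      } else if (res$class == "two_cell") {
        r <- apply_two_cell(nbh, lin, config)
        lin <- r$lineage
        action <- if (!is.na(nbh$termination_id)) "rewire_interpolate" else "rematch"
        if (length(r$requeue)) {
          rq <- r$requeue
          iters[[as.character(rq)]] <- (iters[[as.character(rq)]] %||% 0L) + 1L
          if (rq == o) tried[[as.character(rq)]] <- tried[[key]]
          queue <- c(queue, rq)
        }
      } else if (res$class == "fp") {
        lin <- apply_fp(nbh, lin, config)
        action <- "delete_fp"
      } else {
        # other: worse match detached and re-queued toward its next candidate
        if (!is.na(bif$child_a_id)) {
          sa <- continuation_score(lin, bif$parent_id, bif$child_a_id)
          so <- continuation_score(lin, bif$parent_id, o)
          if (sa < so) {
            lin <- remove_link(lin, bif$parent_id, bif$child_a_id)
            lin <- add_link(lin, bif$parent_id, o)
            mover <- bif$child_a_id
            tried[[as.character(mover)]] <-
              c(tried[[as.character(mover)]], bif$parent_id)
            action <- "swap_reassign"
          } else {
            mover <- o
            action <- "reassign"
          }
        } else {
          mover <- o
          action <- "reassign"
        }
        iters[[as.character(mover)]] <- (iters[[as.character(mover)]] %||% 0L) + 1L
        queue <- c(queue, mover)
      }
      entries[[length(entries) + 1L]] <-
        log_entry(tt, o, bif$parent_id, bif$child_a_id, nbh$termination_id,
                  nbh$gap_frames, res$class, action, res$posterior, res$features)
    }
  }
  list(lineage = lin, log = build_log(entries))
}

log_entry <- function(frame, orphan, parent, child_a, termination, gap,
                      class, action, posterior, features) {
  list(frame = frame, orphan = orphan, parent = parent, child_a = child_a,
       termination = termination, gap = gap, class = class, action = action,
       posterior = posterior, features = features)
}

empty_log <- function() {
  data.frame(frame = integer(), orphan = integer(), parent = integer(),
             child_a = integer(), termination = integer(), gap = integer(),
             class = character(), action = character(),
             p_division = numeric(), p_two_cell = numeric(),
             p_fp = numeric(), p_other = numeric())
}

build_log <- function(entries) {
  if (!length(entries)) return(empty_log())
  getp <- function(e, cl) if (is.null(e$posterior)) NA_real_ else unname(e$posterior[cl])
  out <- data.frame(
    frame = vapply(entries, function(e) as.integer(e$frame), integer(1)),
    orphan = vapply(entries, function(e) as.integer(e$orphan), integer(1)),
    parent = vapply(entries, function(e) as.integer(e$parent %||% NA), integer(1)),
    child_a = vapply(entries, function(e) as.integer(e$child_a %||% NA), integer(1)),
    termination = vapply(entries, function(e) as.integer(e$termination %||% NA), integer(1)),
    gap = vapply(entries, function(e) as.integer(e$gap %||% NA), integer(1)),
    class = vapply(entries, function(e) e$class, character(1)),
    action = vapply(entries, function(e) e$action, character(1)),
    p_division = vapply(entries, getp, numeric(1), "division"),
    p_two_cell = vapply(entries, getp, numeric(1), "two_cell"),
    p_fp = vapply(entries, getp, numeric(1), "fp"),
    p_other = vapply(entries, getp, numeric(1), "other")
  )
  feats <- lapply(entries, function(e) e$features)
  keep <- !vapply(feats, is.null, logical(1))
  if (any(keep)) {
    fm <- matrix(NA_real_, nrow(out), length(FEATURE_NAMES),
                 dimnames = list(NULL, FEATURE_NAMES))
    fm[keep, ] <- do.call(rbind, feats[keep])
    attr(out, "features") <- fm
  }
  out
}
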