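# Lineage-vs-truth scoring: instantaneous and cumulative accuracy, division
# PPV/sensitivity, local density, density-stratified error counts, and the
# bifurcation confusion matrix.

#' Local nuclear density
#'
#' `(radius(c) + radius(NN(c))) / distance(c, NN(c))` with the nearest
#' neighbor taken in the same frame.  A density of one means the two nuclear
#' shells touch; values above one mean overlap.  NA for a lone detection.
#'
#' @param frame_det Detection table of one frame.
#' @param id Detection id within that frame.
#' @return Numeric density, or NA.
#' @export
density_of <- function(frame_det, id) {
  if (nrow(frame_det) < 2) return(NA_real_)
  nn <- same_frame_nn(frame_det)
  k <- match(id, nn$id)
  if (is.na(k)) stop("id not in frame")
  r1 <- frame_det$radius[match(id, frame_det$id)]
  r2 <- frame_det$radius[match(nn$nn_id[k], frame_det$id)]
  (r1 + r2) / nn$nn_dist[k]
}

# Map predicted detections to truth detections.  Ids shared with the truth
# are matched by identity (the simulator preserves ids of real detections);
# remaining predicted detections (interpolations, uncorrected FPs) are
# greedily matched by position to unclaimed truth detections in the same
# frame within 0.5 x the truth radius.
match_to_truth <- function(pred_lin, true_lin) {
  pid <- pred_lin$det$id
  tid <- true_lin$det$id
  map <- ifelse(pid %in% tid, pid, NA_integer_)
  claimed <- tid %in% map
  for (k in which(is.na(map))) {
    t <- pred_lin$det$t[k]
    cand <- which(true_lin$det$t == t & !claimed)
    if (!length(cand)) next
    dd <- sqrt(colSums((t(as.matrix(true_lin$det[cand, c("x", "y", "z")])) -
                          as.numeric(pred_lin$det[k, c("x", "y", "z")]))^2))
    j <- which.min(dd)
    if (dd[j] <= 0.5 * true_lin$det$radius[cand[j]]) {
      map[k] <- tid[cand[j]]
      claimed[cand[j]] <- TRUE
    }
  }
  map  # truth id (or NA) per predicted detection row
}

# Per-truth-detection instantaneous error indicator plus the spurious
# (unmatched, undeleted) predicted detection count.
instantaneous_errors <- function(pred_lin, true_lin) {
  map <- match_to_truth(pred_lin, true_lin)
  tid <- true_lin$det$id
  # pred row for each truth detection (NA if absent from prediction)
  back <- match(tid, map)
  err <- logical(nrow(true_lin$det))
  deleted <- !is.na(back) & pred_lin$status[ifelse(is.na(back), 1L, back)] == "deleted"
  present <- !is.na(back) & !deleted
  err[!present] <- TRUE  # missing (unrepaired FN) or wrongly deleted true cell
  # predecessor agreement, in truth-id space
  pp <- rep(NA_integer_, length(tid))
  ok <- which(present)
  pred_of_pred <- pred_lin$pred[back[ok]]              # predicted predecessor (pred ids)
  pp[ok] <- map[match(pred_of_pred, pred_lin$det$id)]  # mapped to truth ids
  tp <- true_lin$pred                                   # truth predecessor
  mismatch <- (is.na(pp) != is.na(tp)) | (!is.na(pp) & !is.na(tp) & pp != tp)
  err[present & mismatch] <- TRUE
  spurious <- sum(is.na(map) & pred_lin$status != "deleted")
  list(err = err, spurious = spurious, map = map)
}

#' Instantaneous tracking accuracy
#'
#' One minus the total number of instantaneous errors over all frames
#' divided by the number of (true) cells over all frames.  An instantaneous
#' error is a cell-frame whose backward history step is wrong: wrong,
#' missing or spurious predecessor; a true cell missing or wrongly deleted;
#' or an undeleted spurious detection.
#'
#' @param pred_lin,true_lin Predicted and ground-truth lineages.
#' @return Fraction in \[0, 1\].
#' @export
instantaneous_accuracy <- function(pred_lin, true_lin) {
  e <- instantaneous_errors(pred_lin, true_lin)
  n <- nrow(true_lin$det)
  if (n == 0) return(1)
  1 - (sum(e$err) + e$spurious) / n
}

# generation (number of divisions since the first frame) per truth detection
truth_generations <- function(true_lin) {
  d <- true_lin$det
  gen <- rep(NA_integer_, nrow(d))
  divides <- !is.na(true_lin$succ1) & !is.na(true_lin$succ2)
  for (r in order(d$t)) {
    p <- true_lin$pred[r]
    if (is.na(p)) gen[r] <- 0L
    else {
      rp <- match(p, d$id)
      gen[r] <- gen[rp] + if (divides[rp]) 1L else 0L
    }
  }
  gen
}

#' Cumulative track accuracy per generation
#'
#' A cell is correct through generation g iff every backward history step
#' from its last frame in that generation to the first frame matches the
#' truth.  Evaluated at each cell's final detection within the generation
#' (the detection that divides or terminates).
#'
#' @param pred_lin,true_lin Predicted and ground-truth lineages.
#' @return data.frame with columns `generation`, `n`, `fraction`.
#' @export
cumulative_accuracy <- function(pred_lin, true_lin) {
  e <- instantaneous_errors(pred_lin, true_lin)
  d <- true_lin$det
  gen <- truth_generations(true_lin)
  clean <- rep(NA, nrow(d))
  for (r in order(d$t)) {
    p <- true_lin$pred[r]
    clean[r] <- !e$err[r] && (is.na(p) || clean[match(p, d$id)])
  }
  last <- is.na(true_lin$succ1) | (!is.na(true_lin$succ1) & !is.na(true_lin$succ2))
  out <- do.call(rbind, lapply(sort(unique(gen)), function(g) {
    sel <- last & gen == g
    data.frame(generation = g, n = sum(sel), fraction = mean(clean[sel]))
  }))
  rownames(out) <- NULL
  out
}

#' Division positive predictive value and sensitivity
#'
#' A predicted division (a parent with two successors) is a true positive
#' iff the truth divides the matched parent at that frame into the matched
#' children.  PPV = TP / predicted divisions; sensitivity = TP / real
#' divisions.
#'
#' @param pred_lin,true_lin Predicted and ground-truth lineages.
#' @return list with `ppv`, `sensitivity`, `tp`, `n_pred`, `n_true`.
#' @export
division_scores <- function(pred_lin, true_lin) {
  map <- match_to_truth(pred_lin, true_lin)
  pdiv <- which(!is.na(pred_lin$succ1) & !is.na(pred_lin$succ2) &
                  pred_lin$status != "deleted")
  tdiv_rows <- which(!is.na(true_lin$succ1) & !is.na(true_lin$succ2))
  tp <- 0L
  for (r in pdiv) {
    tpar <- map[r]
    if (is.na(tpar)) next
    rt <- match(tpar, true_lin$det$id)
    tch <- c(true_lin$succ1[rt], true_lin$succ2[rt])
    if (anyNA(tch)) next
    pch <- c(pred_lin$succ1[r], pred_lin$succ2[r])
    mch <- map[match(pch, pred_lin$det$id)]
    if (!anyNA(mch) && setequal(mch, tch)) tp <- tp + 1L
  }
  list(ppv = if (length(pdiv)) tp / length(pdiv) else NA_real_,
       sensitivity = if (length(tdiv_rows)) tp / length(tdiv_rows) else NA_real_,
       tp = tp, n_pred = length(pdiv), n_true = length(tdiv_rows))
}

#' Error counts stratified by local density
#'
#' Bins the per-cell-frame instantaneous errors (on true detections) by the
#' truth-side local density.  Bin totals partition the global error count on
#' true detections.
#'
#' @param pred_lin,true_lin Predicted and ground-truth lineages.
#' @param breaks Numeric bin breaks for density (lone cells go to the first
#'   bin).
#' @return data.frame with `bin`, `n`, `errors`.
#' @export
errors_by_density <- function(pred_lin, true_lin,
                              breaks = c(0, 0.5, 0.75, 1, 1.25, Inf)) {
  e <- instantaneous_errors(pred_lin, true_lin)
  d <- true_lin$det
  dens <- rep(NA_real_, nrow(d))
  for (t in unique(d$t)) {
    sel <- d$t == t
    fd <- d[sel, , drop = FALSE]
    nn <- same_frame_nn(fd)
    r2 <- fd$radius[match(nn$nn_id, fd$id)]
    dens[sel] <- (fd$radius + r2) / nn$nn_dist
  }
  dens[is.na(dens)] <- breaks[1]
  bin <- cut(dens, breaks, include.lowest = TRUE)
  out <- data.frame(bin = levels(bin),
                    n = as.integer(table(bin)),
                    errors = as.integer(tapply(e$err, bin, sum, default = 0L)))
  rownames(out) <- NULL
  out
}

#' 4x4 bifurcation confusion matrix
#'
#' Rows are the true classes, columns the predicted ones.
#'
#' @param truth,predicted Character vectors of classes.
#' @param classes Class order.
#' @return Integer matrix with row sums equal to true class counts.
#' @export
confusion_matrix <- function(truth, predicted, classes = NB_CLASSES) {
  table(factor(truth, classes), factor(predicted, classes))
}

#' Full evaluation report
#'
#' @param pred_lin,true_lin Predicted and ground-truth lineages.
#' @param bif_truth,bif_pred Optional class vectors for logged bifurcations.
#' @return list mirroring the standard report: instantaneous accuracy,
#'   per-generation cumulative accuracy, division PPV/sensitivity,
#'   density-stratified errors, repair counts and, when labels are given,
#'   the confusion matrix.
#' @export
eval_report <- function(pred_lin, true_lin, bif_truth = NULL, bif_pred = NULL) {
  rep <- list(
    instantaneous_accuracy = instantaneous_accuracy(pred_lin, true_lin),
    cumulative_accuracy = cumulative_accuracy(pred_lin, true_lin),
    division = division_scores(pred_lin, true_lin),
    errors_by_density = errors_by_density(pred_lin, true_lin),
    n_deleted = sum(pred_lin$status == "deleted"),
    n_interpolated = sum(pred_lin$status == "interpolated"),
    n_unexplained = sum(pred_lin$status == "unexplained_appearance")
  )
  if (!is.null(bif_truth))
    rep$confusion <- confusion_matrix(bif_truth, bif_pred)
  rep
}
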