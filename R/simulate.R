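# Synthetic dividing-embryo generator with ground truth, detection-error
# injection, truth-guided training-set harvesting, and the cumulative-error
# lineage simulation.
#
# The motion model is a bounded random walk inside an ellipsoidal arena with
# soft repulsion, not a biophysical model: the tracker only assumes the
# limited-displacement regime (per-frame movement well below half the
# same-frame nearest-neighbor distance), so realism beyond nearest-neighbor
# statistics is unnecessary.  Divisions carry the canonical morphological
# signature: the parent's eccentricity ramps up just before division (a
# metaphase-plate proxy), the daughters appear symmetrically about the
# parent with condensed (smaller, dimmer) nuclei whose radius shrink factor
# of 2^(-1/3) keeps total nuclear volume roughly constant across rounds.

#' Simulator configuration
#'
#' Defaults describe a single founder cell dividing every ~18 frames for 120
#' frames (six rounds, 1 to 64 cells) inside a C. elegans-sized ellipsoid,
#' with per-frame motion at 20% of the local nearest-neighbor distance and
#' no detection errors; error rates are opted into explicitly.
#'
#' @param n_start_cells Founder cells at frame 1.
#' @param n_frames Number of frames.
#' @param cell_cycle_mean,cell_cycle_sd Cell-cycle length (frames).
#' @param motion_step Per-frame step size as a fraction of the same-frame
#'   nearest-neighbor distance; must stay below 0.5 to keep the safe-link
#'   displacement condition satisfiable.
#' @param arena Ellipsoid semi-axes in microns.
#' @param start_radius Founder nuclear radius (microns).
#' @param child_separation_radii Distance between daughter centers at birth,
#'   in units of the parent radius.
#' @param child_radius_shrink Daughter radius / parent radius.
#' @param child_intensity_factor Daughter intensity / parent intensity.
#' @param ecc_baseline,ecc_sd,ecc_division,ecc_ramp_frames Interphase
#'   eccentricity level and noise; pre-division eccentricity plateau and the
#'   number of frames before division over which it applies.
#' @param intensity_mean,intensity_sd Founder intensity distribution (a.u.).
#' @param fp_rate,fn_rate Per-detection, per-frame error rates in \[0, 1).
#' @param jitter_sd Gaussian position jitter (microns) applied to observed
#'   detections.
#' @param fp_radius_factor,fp_intensity_factor,fp_max_frames Morphology and
#'   maximal lifetime of injected false-positive tracks.
#' @param rng_seed Integer seed; a simulation is a deterministic function of
#'   the config (single global stream, no per-module seeds).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_start_cells = 1L,
                       n_frames = 120L,
                       cell_cycle_mean = 19,
                       cell_cycle_sd = 1.5,
                       motion_step = 0.2,
                       arena = c(25, 15, 15),
                       start_radius = 11,
                       child_separation_radii = 1.4,
                       child_radius_shrink = 2^(-1 / 3),
                       child_intensity_factor = 0.55,
                       ecc_baseline = 0.15,
                       ecc_sd = 0.04,
                       ecc_division = 0.85,
                       ecc_ramp_frames = 2L,
                       intensity_mean = 1000,
                       intensity_sd = 100,
                       fp_rate = 0,
                       fn_rate = 0,
                       jitter_sd = 0,
                       fp_radius_factor = 0.5,
                       fp_intensity_factor = 0.3,
                       fp_max_frames = 3L,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_start_cells <- as.integer(n_start_cells)
  cfg$n_frames <- as.integer(n_frames)
  cfg$rng_seed <- as.integer(rng_seed)
  stopifnot(
    cfg$n_start_cells >= 1, cfg$n_frames >= 1,
    cfg$motion_step > 0, cfg$motion_step < 0.5,
    length(cfg$arena) == 3, all(cfg$arena > 0),
    cfg$fp_rate >= 0, cfg$fp_rate < 1,
    cfg$fn_rate >= 0, cfg$fn_rate < 1,
    cfg$jitter_sd >= 0, cfg$start_radius > 0
  )
  structure(cfg, class = "sim_config")
}

unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / pmax(sqrt(rowSums(v^2)), 1e-12)
}

clip_to_arena <- function(P, radius, arena) {
  for (i in seq_len(nrow(P))) {
    margin <- pmax(arena - radius[i], 0.5 * arena)
    v <- sum((P[i, ] / margin)^2)
    if (v > 1) P[i, ] <- P[i, ] / sqrt(v)
  }
  P
}

#' Generate a synthetic dividing embryo with ground truth
#'
#' Cells random-walk with a reflecting ellipsoid boundary and soft pairwise
#' repulsion; divisions follow each cell's sampled cycle length with the
#' parametrized morphological signature.  The ground-truth lineage (all
#' links, including divisions) is recorded alongside the per-detection cell
#' identity.
#'
#' @param cfg A [sim_config()].
#' @return A `synthetic_embryo` list: `truth` (ground-truth [lineage()]),
#'   `cell_of` (true cell id per detection id), `cells` (per-cell metadata)
#'   and `config`.
#' @export
generate_embryo <- function(cfg) {
  set.seed(cfg$rng_seed)
  arena <- cfg$arena
  vol_arena <- 4 / 3 * pi * prod(arena)
  # founders
  k <- cfg$n_start_cells
  P <- matrix(0, k, 3)
  if (k > 1) {
    tries <- 0
    repeat {
      P <- unit_vectors(k) * stats::runif(k, 0, 0.7)^(1 / 3) *
        matrix(arena, k, 3, byrow = TRUE)
      if (min(stats::dist(P)) > 2.0 * cfg$start_radius) break
      tries <- tries + 1
      if (tries > 500) stop("infeasible packing: too many start cells for the arena")
    }
  }
  cycle_len <- function(n) pmax(3L, as.integer(round(stats::rnorm(n, cfg$cell_cycle_mean, cfg$cell_cycle_sd))))
  cells <- data.frame(cell = seq_len(k), parent_cell = NA_integer_,
                      birth_t = 1L, last_t = 1L + cycle_len(k) - 1L,
                      radius = cfg$start_radius,
                      base_intensity = stats::rnorm(k, cfg$intensity_mean, cfg$intensity_sd))
  pos <- P
  alive <- seq_len(k)       # rows into `cells` of currently alive cells
  det <- list()
  cell_of <- integer()
  links <- list()
  last_det_of <- integer()  # detection id of each cell's previous-frame record
  next_id <- 1L

  for (tt in seq_len(cfg$n_frames)) {
    nal <- length(alive)
    if (nal * 4 / 3 * pi * max(cells$radius[alive])^3 > 0.7 * vol_arena)
      stop("infeasible packing: too many cells for the arena at frame ", tt)
    # record detections
    to_div <- cells$last_t[alive] - tt
    ecc <- ifelse(to_div < cfg$ecc_ramp_frames & cells$last_t[alive] < cfg$n_frames,
                  pmin(1, cfg$ecc_division + stats::rnorm(nal, 0, cfg$ecc_sd / 2)),
                  pmin(1, pmax(0, cfg$ecc_baseline + stats::rnorm(nal, 0, cfg$ecc_sd))))
    ids <- next_id:(next_id + nal - 1L)
    next_id <- next_id + nal
    det[[tt]] <- data.frame(
      id = ids, t = tt,
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      radius = cells$radius[alive] * (1 + stats::rnorm(nal, 0, 0.02)),
      intensity = pmax(cells$base_intensity[alive] * (1 + stats::rnorm(nal, 0, 0.03)), 1),
      eccentricity = ecc
    )
    cell_of <- c(cell_of, cells$cell[alive])
    prev <- last_det_of[as.character(cells$cell[alive])]
    has_prev <- !is.na(prev) & tt > 1
    if (any(has_prev))
      links[[tt]] <- data.frame(pred_id = unname(prev[has_prev]),
                                succ_id = ids[has_prev])
    last_det_of[as.character(cells$cell[alive])] <- ids

    if (tt == cfg$n_frames) break

    # divisions scheduled between tt and tt+1
    dividing <- alive[cells$last_t[alive] == tt]
    new_rows <- integer()
    for (r in dividing) {
      u <- unit_vectors(1)
      rpar <- cells$radius[r]
      off <- (cfg$child_separation_radii / 2) * rpar * as.numeric(u)
      p0 <- pos[match(r, alive), ]
      chpos <- rbind(p0 + off, p0 - off)
      nch <- nrow(cells) + 1:2
      cells <- rbind(cells, data.frame(
        cell = nch, parent_cell = cells$cell[r], birth_t = tt + 1L,
        last_t = tt + cycle_len(2),
        radius = cfg$child_radius_shrink * rpar,
        base_intensity = cells$base_intensity[r] * cfg$child_intensity_factor *
          (1 + stats::rnorm(2, 0, 0.05))))
      # daughters inherit the parent's detection as predecessor
      last_det_of[as.character(nch)] <- NA_integer_
      pos <- rbind(pos, chpos)   # appended; reconciled below
      new_rows <- c(new_rows, nch)
    }
    # truth division links are added when daughters are first recorded; mark
    # their predecessor as the parent's current detection
    if (length(dividing)) {
      for (r in dividing) {
        nch <- cells$cell[cells$parent_cell == cells$cell[r] &
                            cells$birth_t == tt + 1L]
        # store parent's det id so the daughters' first record links back
        last_det_of[as.character(nch)] <- last_det_of[as.character(cells$cell[r])]
      }
    }
    keep <- which(cells$last_t[alive] > tt)
    alive_next <- c(alive[keep], new_rows)
    pos <- rbind(pos[keep, , drop = FALSE],
                 pos[length(alive) + seq_len(length(new_rows)), , drop = FALSE])
    alive <- alive_next

    # movement; daughters born this transition already moved by the division
    # placement itself and take no extra step
    n <- length(alive)
    if (n > 1) {
      S <- pairwise_dist(pos, pos); diag(S) <- Inf
      nnd <- apply(S, 1, min)
    } else nnd <- 2 * cells$radius[alive]
    mag <- abs(stats::rnorm(n, cfg$motion_step * nnd, 0.25 * cfg$motion_step * nnd))
    mag[cells$birth_t[alive] > tt] <- 0
    pos <- pos + unit_vectors(n) * mag
    # soft repulsion: push overlapping pairs apart
    if (n > 1) {
      for (rep_it in 1:2) {
        S <- pairwise_dist(pos, pos); diag(S) <- Inf
        rr <- outer(cells$radius[alive], cells$radius[alive], "+")
        ov <- which(S < 0.95 * rr & upper.tri(S), arr.ind = TRUE)
        if (!nrow(ov)) break
        for (q in seq_len(nrow(ov))) {
          i <- ov[q, 1]; j <- ov[q, 2]
          d <- pos[j, ] - pos[i, ]
          nd <- sqrt(sum(d^2))
          u <- if (nd > 1e-9) d / nd else as.numeric(unit_vectors(1))
          push <- (0.95 * rr[i, j] - nd) / 2
          pos[i, ] <- pos[i, ] - u * push
          pos[j, ] <- pos[j, ] + u * push
        }
      }
    }
    pos <- clip_to_arena(pos, cells$radius[alive], arena)
  }

  dd <- do.call(rbind, det)
  truth <- lineage(detections(dd$id, dd$t, dd$x, dd$y, dd$z,
                              dd$radius, dd$intensity, dd$eccentricity))
  lk <- do.call(rbind, links[!vapply(links, is.null, logical(1))])
  if (!is.null(lk) && nrow(lk)) {
    # a parent of a division contributes two successor rows in lk
    for (q in seq_len(nrow(lk))) truth <- add_link(truth, lk$pred_id[q], lk$succ_id[q])
  }
  names(cell_of) <- dd$id
  structure(list(truth = truth, cell_of = cell_of, cells = cells, config = cfg),
            class = "synthetic_embryo")
}

#' @export
print.synthetic_embryo <- function(x, ...) {
  cat(sprintf("<synthetic_embryo> %d detections, %d cells, %d frames, %d divisions\n",
              nrow(x$truth$det), nrow(x$cells), x$config$n_frames,
              sum(!is.na(x$cells$parent_cell)) / 2))
  invisible(x)
}

#' Inject detection errors into an embryo's true detections
#'
#' Each true detection is dropped independently with probability `fn_rate`;
#' false-positive tracks are spawned next to existing nuclei with
#' per-detection probability `fp_rate`, persist 1 to `fp_max_frames` frames
#' with reduced radius and intensity, and drift like real nuclei; Gaussian
#' position jitter of `jitter_sd` microns is applied to all observed
#' positions.  Annotations exactly reconcile true and observed counts.
#'
#' Continues the RNG stream of [generate_embryo()]: the pair of calls is a
#' deterministic function of the config.
#'
#' @param embryo A `synthetic_embryo`.
#' @param cfg A [sim_config()] carrying the error rates.
#' @return list with `det` (observed detection table), `fn_ids` (dropped
#'   true detection ids), `fp_ids` (spurious detection ids) and `fp_source`
#'   (the true detection each FP track spawned from).
#' @export
inject_errors <- function(embryo, cfg) {
  td <- embryo$truth$det
  n <- nrow(td)
  drop <- stats::runif(n) < cfg$fn_rate
  fn_ids <- td$id[drop]
  obs <- td[!drop, , drop = FALSE]

  fp_rows <- list()
  fp_source <- integer()
  next_id <- max(td$id) + 1L
  spawn <- which(stats::runif(n) < cfg$fp_rate)
  for (k in spawn) {
    L <- sample.int(cfg$fp_max_frames, 1)
    t0 <- td$t[k]
    frames <- t0:min(t0 + L - 1L, max(td$t))
    u <- as.numeric(unit_vectors(1))
    r0 <- td$radius[k]
    p <- c(td$x[k], td$y[k], td$z[k]) + u * stats::runif(1, 1.0, 1.6) * r0
    for (ti in frames) {
      fp_rows[[length(fp_rows) + 1L]] <- data.frame(
        id = next_id, t = ti, x = p[1], y = p[2], z = p[3],
        radius = cfg$fp_radius_factor * r0 * (1 + stats::rnorm(1, 0, 0.1)),
        intensity = max(cfg$fp_intensity_factor * td$intensity[k] *
                          (1 + stats::rnorm(1, 0, 0.1)), 1),
        eccentricity = stats::runif(1, 0.2, 0.6))
      fp_source[as.character(next_id)] <- td$id[k]
      next_id <- next_id + 1L
      p <- p + as.numeric(unit_vectors(1)) * 0.15 * r0
    }
  }
  fp <- if (length(fp_rows)) do.call(rbind, fp_rows) else NULL
  obs <- rbind(obs, fp)
  if (cfg$jitter_sd > 0) {
    m <- nrow(obs)
    obs$x <- obs$x + stats::rnorm(m, 0, cfg$jitter_sd)
    obs$y <- obs$y + stats::rnorm(m, 0, cfg$jitter_sd)
    obs$z <- obs$z + stats::rnorm(m, 0, cfg$jitter_sd)
  }
  obs <- obs[order(obs$id), , drop = FALSE]
  rownames(obs) <- NULL
  list(det = obs, fn_ids = fn_ids,
       fp_ids = if (is.null(fp)) integer() else unique(fp$id),
       fp_source = fp_source)
}

#' Generate an embryo and its observed (error-injected) detections
#'
#' Convenience wrapper: [generate_embryo()] followed by [inject_errors()]
#' under one seed, so the whole dataset is reproducible from the config.
#'
#' @param cfg A [sim_config()].
#' @return The `synthetic_embryo` with an `observed` element added
#'   (the [inject_errors()] result).
#' @export
simulate_dataset <- function(cfg) {
  emb <- generate_embryo(cfg)
  emb$observed <- inject_errors(emb, cfg)
  emb
}

#' Ground-truth class of a tentative bifurcation
#'
#' Labels a neighborhood from the simulator's ground truth: `fp` when the
#' orphan is an injected false positive; `division` when the chosen parent
#' is the orphan's true mother at a true division; `two_cell` when the
#' orphan truly continues either the chosen parent (excessive movement) or
#' the matched terminating track (detection gap); `other` otherwise.
#'
#' @param nbh A neighborhood.
#' @param lin The working lineage (unused, kept for signature symmetry).
#' @param embryo A `synthetic_embryo`.
#' @param fp_ids Injected false-positive detection ids.
#' @return One of `division`, `two_cell`, `fp`, `other`.
#' @export
oracle_label <- function(nbh, lin, embryo, fp_ids) {
  bif <- nbh$bifurcation
  o <- bif$child_b_id
  if (o %in% fp_ids) return("fp")
  truth <- embryo$truth
  ro <- match(o, truth$det$id)
  if (is.na(ro)) return("other")  # not a true detection (defensive)
  tp <- truth$pred[ro]
  if (is.na(tp)) return("other")
  rp <- match(tp, truth$det$id)
  divides <- !is.na(truth$succ2[rp])
  if (tp == bif$parent_id) return(if (divides) "division" else "two_cell")
  # does the matched terminating track truly continue into the orphan?
  if (!is.na(nbh$termination_id) && !(nbh$termination_id %in% fp_ids)) {
    re <- match(nbh$termination_id, truth$det$id)
    if (!is.na(re)) {
      steps <- truth$det$t[ro] - truth$det$t[re]
      cur <- ro
      ok <- steps >= 1
      for (s in seq_len(max(steps, 0))) {
        p <- truth$pred[cur]
        if (is.na(p)) { ok <- FALSE; break }
        cur <- match(p, truth$det$id)
      }
      if (ok && cur == re) return("two_cell")
    }
  }
  "other"
}

#' Harvest a labeled training set from simulated embryos
#'
#' Runs the full tracing engine with a truth-guided oracle in place of the
#' classifier (so the neighborhoods seen match the deployment distribution),
#' harvesting the feature vector and true class of every bifurcation
#' considered, plus each orphan's runner-up candidate (a rich source of
#' wrongly-parented "other" examples).  Embryos are simulated at the given
#' config with seeds `seed, seed+1, ...` until every class has
#' `n_per_class` examples; the returned set is balanced.
#'
#' @param n_per_class Examples per class.
#' @param config A [tracking_config()].
#' @param sim_cfg A [sim_config()]; error rates should be positive so the
#'   fp/two_cell classes occur.
#' @param seed Base seed.
#' @param max_embryos Safety cap.
#' @return list with `x` (feature matrix), `labels`.
#' @export
make_training_data <- function(n_per_class = 500L,
                               config = tracking_config(),
                               sim_cfg = sim_config(fn_rate = 0.02, fp_rate = 0.02),
                               seed = 1L, max_embryos = 60L) {
  feats <- list(); labs <- character()
  counts <- stats::setNames(integer(4), NB_CLASSES)
  for (k in seq_len(max_embryos)) {
    cfg <- sim_cfg
    cfg$rng_seed <- as.integer((seed + k - 1L) %% .Machine$integer.max)
    emb <- simulate_dataset(cfg)
    fp_ids <- emb$observed$fp_ids
    collect <- function(nbh, li) {
      lab <- oracle_label(nbh, li, emb, fp_ids)
      feats[[length(feats) + 1L]] <<- extract_features(nbh, li, config)
      labs[length(labs) + 1L] <<- lab
      lab
    }
    oracle_classify <- function(nbh, li) {
      lab <- collect(nbh, li)
      post <- stats::setNames(as.numeric(NB_CLASSES == lab), NB_CLASSES)
      list(class = lab, posterior = post, features = feats[[length(feats)]])
    }
    hook <- function(o, cands, li) {
      if (length(cands) >= 2) {
        b2 <- cands[[2]]
        nb2 <- build_neighborhood(b2, find_terminations(li, b2, config), li)
        collect(nb2, li)
      }
      invisible(NULL)
    }
    trace_lineage(emb$observed$det, model = NULL, config = config,
                  classify_fun = oracle_classify, rank_model = NULL,
                  candidate_hook = hook)
    counts <- table(factor(labs, NB_CLASSES))
    if (all(counts >= n_per_class)) break
  }
  if (!all(counts >= n_per_class))
    warning("training classes not filled: ",
            paste(sprintf("%s=%d", NB_CLASSES, counts), collapse = ", "))
  x <- do.call(rbind, feats)
  keep <- unlist(lapply(NB_CLASSES, function(cl) {
    idx <- which(labs == cl)
    utils::head(idx, n_per_class)
  }))
  keep <- sort(keep)
  list(x = x[keep, , drop = FALSE], labels = labs[keep])
}

#' Train the bifurcation classifier on simulated embryos
#'
#' @inheritParams make_training_data
#' @return An `nb_model`.
#' @export
train_model <- function(n_per_class = 500L, config = tracking_config(),
                        sim_cfg = sim_config(fn_rate = 0.02, fp_rate = 0.02),
                        seed = 1L, max_embryos = 60L) {
  tr <- make_training_data(n_per_class, config, sim_cfg, seed, max_embryos)
  nb_fit(tr$x, tr$labels)
}

#' Cumulative-error simulation on an idealized lineage
#'
#' Builds a perfect binary-tree lineage with uniform cycle length, flips an
#' independent error at each (cell, frame) at the instantaneous error rate,
#' and calls a cell wrong if any error occurred anywhere in its history.
#' Returns the mean fraction of correct cells at the end of each generation
#' over `n_reps` replicates.
#'
#' @param error_rate Instantaneous per-cell, per-frame error probability.
#' @param n_frames Total frames simulated.
#' @param cycle_frames Uniform cell-cycle length (>= `n_frames` means a
#'   single non-dividing generation).
#' @param n_reps Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return data.frame with `generation`, `frames` (frames lived within the
#'   generation), `fraction` (mean fraction of error-free cells at the end
#'   of the generation).
#' @export
simulate_cumulative_accuracy <- function(error_rate, n_frames, cycle_frames,
                                         n_reps = 1000L, seed = 1L) {
  set.seed(as.integer(seed))
  gens <- ceiling(n_frames / cycle_frames)
  out <- data.frame(generation = seq_len(gens), frames = NA_integer_,
                    fraction = NA_real_)
  # ok[r, c]: cell c of the current generation in replicate r is error-free
  ok <- matrix(TRUE, n_reps, 1)
  for (g in seq_len(gens)) {
    ncell <- 2^(g - 1)
    frames_g <- min(cycle_frames, n_frames - (g - 1) * cycle_frames)
    if (ncol(ok) < ncell) ok <- ok[, rep(seq_len(ncol(ok)), each = 2), drop = FALSE]
    flips <- matrix(stats::rbinom(n_reps * ncell, frames_g, error_rate),
                    n_reps, ncell)
    ok <- ok & (flips == 0)
    out$frames[g] <- frames_g
    out$fraction[g] <- mean(ok)
  }
  out
}
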