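# Feature measurement on semi-local neighborhoods and Naive Bayes posterior
# over the four bifurcation classes.  Class order is fixed and doubles as
# the deterministic tie-break (division > two_cell > fp > other).

#' Bifurcation classes, in fixed (tie-break) order
#' @export
NB_CLASSES <- c("division", "two_cell", "fp", "other")

#' Registry of neighborhood feature names, in measurement order
#' @export
FEATURE_NAMES <- c(
  "child_radius_ratio",        # min/max of the children's radii, (0,1]
  "child_intensity_ratio",     # min/max of the children's intensities
  "parent_eccentricity",       # metaphase-plate proxy (NA if unreported)
  "child_separation",          # child-child distance / parent diameter
  "child_angle",               # angle at parent between the two children, rad
  "mean_child_displacement",   # mean parent->child distance / parent radius
  "child_parent_radius_ratio", # mean child radius / parent radius
  "shorter_branch_length",     # frames, forward-looking, capped
  "termination_gap",           # frames between dangling end and bifurcation
  "termination_distance",      # end-to-centroid distance / median NN distance
  "parent_density",            # (r_p + r_nn) / same-frame NN distance
  "parent_relative_intensity"  # parent intensity / frame median intensity
)

BRANCH_LENGTH_CAP <- 10L
TERMINATION_DISTANCE_SENTINEL <- 10

#' Measure the feature vector of a neighborhood
#'
#' Twelve fixed-order measurements capturing the morphological and kinematic
#' cues that distinguish the four bifurcation origins: symmetric condensed
#' daughters and a metaphase-plate-like elongated parent for divisions;
#' a nearby dangling end for movement / false-negative pairs; small, dim,
#' short-lived branches for detection false positives.  Degenerate
#' bifurcations (a single child) use the conventions noted per feature.
#'
#' @param nbh A neighborhood from [build_neighborhood()].
#' @param lin A lineage.
#' @param config A [tracking_config()].
#' @return Named numeric vector of length 12.  `parent_eccentricity` may be
#'   NA when the detector reports no shape; [nb_fit()] learns an imputation
#'   median and [nb_posterior()] applies it.
#' @export
extract_features <- function(nbh, lin, config) {
  bif <- nbh$bifurcation
  rp <- lin_row(lin, bif$parent_id)
  p <- as.numeric(lin$det[rp, c("x", "y", "z")])
  rpar <- lin$det$radius[rp]
  ch <- bif_children(bif)
  rc <- match(ch, lin$det$id)
  cpos <- as.matrix(lin$det[rc, c("x", "y", "z")])
  cr <- lin$det$radius[rc]
  ci <- lin$det$intensity[rc]

  two <- length(ch) == 2
  f1 <- if (two) min(cr) / max(cr) else 1
  f2 <- if (two) min(ci) / max(ci) else 1
  f3 <- lin$det$eccentricity[rp]
  f4 <- if (two) sqrt(sum((cpos[1, ] - cpos[2, ])^2)) / (2 * rpar) else 0
  if (two) {
    v1 <- cpos[1, ] - p; v2 <- cpos[2, ] - p
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    f5 <- if (n1 > 0 && n2 > 0)
      acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) else 0
  } else f5 <- 0
  disp <- sqrt(rowSums((cpos - matrix(p, nrow(cpos), 3, byrow = TRUE))^2))
  f6 <- mean(disp) / rpar
  f7 <- mean(cr) / rpar
  f8 <- min(vapply(ch, function(id) branch_length(lin, id, BRANCH_LENGTH_CAP),
                   integer(1)))

  frame_par <- lin$det[lin$det$t == lin$det$t[rp] & lin$status != "deleted", , drop = FALSE]
  mnn <- median_nn_dist(frame_par)
  scale <- if (is.na(mnn)) 2 * rpar else mnn
  if (!is.na(nbh$termination_id)) {
    f9 <- min(nbh$gap_frames, config$termination_window_dt)
    e <- as.numeric(lin$det[lin_row(lin, nbh$termination_id), c("x", "y", "z")])
    centroid <- colMeans(rbind(p, cpos))
    f10 <- min(sqrt(sum((e - centroid)^2)) / scale, TERMINATION_DISTANCE_SENTINEL)
  } else {
    f9 <- 0
    f10 <- TERMINATION_DISTANCE_SENTINEL
  }
  f11 <- density_of(frame_par, bif$parent_id)
  if (is.na(f11)) f11 <- 0
  f12 <- lin$det$intensity[rp] / max(stats::median(frame_par$intensity), 1e-12)

  out <- c(f1, f2, f3, f4, f5, f6, f7, as.numeric(f8), as.numeric(f9),
           f10, f11, f12)
  names(out) <- FEATURE_NAMES
  out
}

#' Fit a Naive Bayes bifurcation classifier
#'
#' Priors are empirical class frequencies; each feature gets one Gaussian
#' per class (sample mean and sd, sd floored at 1e-6 of the feature's range
#' over the training set).  Features with missing values (optional shape
#' descriptors) are imputed with the training median, which is stored in the
#' model so prediction imputes identically.
#'
#' @param x Numeric matrix or data.frame of feature vectors (rows =
#'   examples, columns in [FEATURE_NAMES] order or any fixed order).
#' @param labels Character/factor vector of classes, one per row.
#' @param classes Required class set; an absent class is an error naming it.
#' @return An object of class `nb_model`.
#' @export
nb_fit <- function(x, labels, classes = NB_CLASSES) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  missing_cls <- setdiff(classes, unique(labels))
  if (length(missing_cls))
    stop("no training examples for class(es): ", paste(missing_cls, collapse = ", "))
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2))
    stop("need >= 2 examples per class; short: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  impute <- apply(x, 2, stats::median, na.rm = TRUE)
  impute[is.na(impute)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- impute[j]
  rng <- apply(x, 2, function(v) diff(range(v)))
  floor_sd <- pmax(1e-6 * rng, 1e-9)
  mu <- sdm <- matrix(NA_real_, length(classes), ncol(x),
                      dimnames = list(classes, colnames(x)))
  for (cl in classes) {
    xc <- x[labels == cl, , drop = FALSE]
    mu[cl, ] <- colMeans(xc)
    sdm[cl, ] <- pmax(apply(xc, 2, stats::sd), floor_sd)
  }
  priors <- as.numeric(counts) / sum(counts)
  names(priors) <- classes
  structure(list(classes = classes, priors = priors, mean = mu, sd = sdm,
                 feature_names = colnames(x), impute = impute,
                 n_train = nrow(x)),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("<nb_model> %d classes x %d features, fit on %d examples\n",
              length(x$classes), ncol(x$mean), x$n_train))
  cat("priors:", paste(sprintf("%s=%.3f", names(x$priors), x$priors),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Posterior class probabilities for a feature vector
#'
#' Computed in log space with a max shift, so extreme feature values cannot
#' underflow the normalization.
#'
#' @param model An `nb_model`.
#' @param m Numeric feature vector (NAs imputed with training medians).
#' @return Named probability vector over the model's classes, summing to 1.
#' @export
nb_posterior <- function(model, m) {
  m <- as.numeric(m)
  stopifnot(length(m) == ncol(model$mean))
  m[is.na(m)] <- model$impute[is.na(m)]
  ll <- vapply(model$classes, function(cl) {
    sum(stats::dnorm(m, model$mean[cl, ], model$sd[cl, ], log = TRUE))
  }, numeric(1)) + log(model$priors)
  ll <- ll - max(ll)
  p <- exp(ll)
  p / sum(p)
}

#' Classify a neighborhood
#'
#' Argmax of the posterior; exact ties resolve in fixed class order
#' (division, two_cell, fp, other).
#'
#' @param model An `nb_model`.
#' @param nbh A neighborhood.
#' @param lin A lineage.
#' @param config A [tracking_config()].
#' @return `list(class, posterior, features)`.
#' @export
nb_classify <- function(model, nbh, lin, config) {
  fv <- extract_features(nbh, lin, config)
  post <- nb_posterior(model, fv)
  list(class = model$classes[which.max(post)], posterior = post, features = fv)
}
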