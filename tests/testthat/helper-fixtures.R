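# Shared fixtures.  The trained classifier is expensive (~1 min), so it is
# built lazily once per test run and reused everywhere a fitted model is
# needed, including the acceptance suite (500 neighborhoods per class, as
# the acceptance criteria state).

.fixture_cache <- new.env(parent = emptyenv())

shared_model <- function() {
  if (is.null(.fixture_cache$model)) {
    .fixture_cache$model <- train_model(n_per_class = 500L, seed = 100L,
                                        max_embryos = 60L)
  }
  .fixture_cache$model
}

# quick detection-table builder with sensible defaults
dets <- function(id, t, x, y = 0, z = 0, radius = 1, intensity = 100,
                 ecc = NA_real_) {
  detections(id, t, x, y, z, radius, intensity, ecc)
}

# a single 1:1 chain of n detections over frames 1..n at unit spacing
chain_lineage <- function(n, x0 = 0) {
  lin <- lineage(dets(seq_len(n), seq_len(n), x = rep(x0, n)))
  for (k in seq_len(n - 1)) lin <- add_link(lin, k, k + 1)
  lin
}

# independent brute-force re-statement of the three link conditions, used as
# the oracle for link_frames (kept deliberately loop-based and literal)
oracle_link_frames <- function(ft, f1, factor = 0.5) {
  ft <- ft[order(ft$id), , drop = FALSE]
  f1 <- f1[order(f1$id), , drop = FALSE]
  pt <- function(d, k) c(d$x[k], d$y[k], d$z[k])
  nn_of <- function(p, d, excl = NULL) {
    best <- NULL; bd <- Inf
    for (k in seq_len(nrow(d))) {
      if (!is.null(excl) && d$id[k] %in% excl) next
      dd <- sqrt(sum((pt(d, k) - p)^2))
      if (dd < bd) { bd <- dd; best <- d$id[k] }  # id order => lowest-id tie
    }
    list(id = best, dist = bd)
  }
  out <- data.frame(pred_id = integer(), succ_id = integer())
  if (nrow(ft) == 0 || nrow(f1) == 0) return(out)
  for (i in seq_len(nrow(ft))) {
    fw <- nn_of(pt(ft, i), f1)
    same <- nn_of(pt(ft, i), ft, excl = ft$id[i])
    safe <- is.null(same$id) || fw$dist < factor * same$dist
    if (!safe) next
    j <- match(fw$id, f1$id)
    if (nn_of(pt(f1, j), ft)$id != ft$id[i]) next              # mutual
    conflict <- FALSE
    for (k in seq_len(nrow(f1)))                               # others at t+1
      if (k != j && identical(nn_of(pt(f1, k), ft)$id, ft$id[i])) conflict <- TRUE
    for (k in seq_len(nrow(ft)))                               # others at t
      if (k != i && identical(nn_of(pt(ft, k), f1)$id, f1$id[j])) conflict <- TRUE
    if (conflict) next
    out <- rbind(out, data.frame(pred_id = ft$id[i], succ_id = f1$id[j]))
  }
  out[order(out$pred_id), , drop = FALSE]
}

random_frame <- function(n, t, id0 = 1L, box = 10) {
  dets(id0 + seq_len(n) - 1L, rep(t, n),
       x = stats::runif(n, 0, box), y = stats::runif(n, 0, box),
       z = stats::runif(n, 0, box))
}
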