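# Phase 1: conservative 1:1 linking.
#
# A nearest-neighbor link from frame t to t+1 is emitted only when three
# conditions all hold:
#   safe      : dist(c, NN(c, t+1)) < safe_link_factor * dist(c, NN(c, t))
#   mutual    : the two detections are each other's nearest neighbors
#   unanimous : no third detection claims either endpoint as its NN
# Equidistant neighbors are broken toward the lowest detection id, in every
# NN query, so the link set is a deterministic function of the geometry.

pairwise_dist <- function(A, B) {
  A <- matrix(as.numeric(A), ncol = 3)
  B <- matrix(as.numeric(B), ncol = 3)
  M <- -2 * (A %*% t(B))
  M <- M + rowSums(A^2)
  M <- sweep(M, 2, rowSums(B^2), "+")
  sqrt(pmax(M, 0))
}

xyz <- function(d) as.matrix(d[, c("x", "y", "z"), drop = FALSE])

#' Nearest neighbor within one frame's detections
#'
#' @param frame_det Detection table restricted to one frame (may be empty).
#' @param query_point Numeric length-3 vector (microns).
#' @param exclude_id Optional id to exclude (e.g. the query detection
#'   itself for same-frame queries).
#' @return A one-row detection data.frame, or `NULL` when no detection is
#'   eligible.  Ties go to the lowest id.
#' @export
nearest_neighbor <- function(frame_det, query_point, exclude_id = NULL) {
  d <- frame_det[order(frame_det$id), , drop = FALSE]
  if (!is.null(exclude_id)) d <- d[!(d$id %in% exclude_id), , drop = FALSE]
  if (nrow(d) == 0) return(NULL)
  dist <- sqrt(colSums((t(xyz(d)) - as.numeric(query_point))^2))
  d[which.min(dist), , drop = FALSE]
}

#' Same-frame nearest-neighbor distances
#'
#' For every detection in a frame, the distance to (and id of) its closest
#' same-frame neighbor; `Inf`/`NA` for a lone detection.
#' @param frame_det Detection table of one frame.
#' @return data.frame with columns `id`, `nn_id`, `nn_dist`, aligned to
#'   `frame_det` order.
#' @export
same_frame_nn <- function(frame_det) {
  n <- nrow(frame_det)
  if (n == 0) return(data.frame(id = integer(), nn_id = integer(), nn_dist = numeric()))
  if (n == 1) return(data.frame(id = frame_det$id, nn_id = NA_integer_, nn_dist = Inf))
  o <- order(frame_det$id)
  d <- frame_det[o, , drop = FALSE]
  S <- pairwise_dist(xyz(d), xyz(d))
  diag(S) <- Inf
  j <- max.col(-S, ties.method = "first")
  out <- data.frame(id = d$id, nn_id = d$id[j], nn_dist = S[cbind(seq_len(n), j)])
  out[match(frame_det$id, out$id), , drop = FALSE]
}

median_nn_dist <- function(frame_det) {
  nn <- same_frame_nn(frame_det)
  v <- nn$nn_dist[is.finite(nn$nn_dist)]
  if (length(v) == 0) return(NA_real_)
  stats::median(v)
}

#' Safe-link displacement condition
#'
#' TRUE iff the distance from detection `id` (frame t) to its nearest
#' neighbor at t+1 is strictly below `safe_link_factor` times its distance to
#' its nearest same-frame neighbor.  A lone detection in frame t has no
#' same-frame neighbor; the condition is then vacuously true (no crowding,
#' so the forward NN is reliable).
#'
#' @param id Detection id, present in `frame_t`.
#' @param frame_t,frame_t1 Detection tables of frames t and t+1.
#' @param config A [tracking_config()].
#' @return Logical.
#' @export
is_safe_link <- function(id, frame_t, frame_t1, config) {
  me <- frame_t[frame_t$id == id, , drop = FALSE]
  if (nrow(me) != 1) stop("id not in frame_t")
  fwd <- nearest_neighbor(frame_t1, as.numeric(xyz(me)))
  if (is.null(fwd)) return(FALSE)
  fwd_d <- sqrt(sum((xyz(fwd) - xyz(me))^2))
  same <- nearest_neighbor(frame_t, as.numeric(xyz(me)), exclude_id = id)
  if (is.null(same)) return(TRUE)
  same_d <- sqrt(sum((xyz(same) - xyz(me))^2))
  fwd_d < config$safe_link_factor * same_d
}

#' Link two consecutive frames
#'
#' Emits every 1:1 link satisfying the safe, mutual and non-conflicting
#' nearest-neighbor conditions.  Each detection appears in at most one link.
#'
#' @param frame_t,frame_t1 Detection tables of frames t and t+1.
#' @param config A [tracking_config()].
#' @return data.frame with columns `pred_id`, `succ_id`.
#' @export
link_frames <- function(frame_t, frame_t1, config) {
  empty <- data.frame(pred_id = integer(), succ_id = integer())
  if (nrow(frame_t) == 0 || nrow(frame_t1) == 0) return(empty)
  ft <- frame_t[order(frame_t$id), , drop = FALSE]
  f1 <- frame_t1[order(frame_t1$id), , drop = FALSE]
  D <- pairwise_dist(xyz(ft), xyz(f1))
  n <- nrow(ft); m <- nrow(f1)
  fwd <- max.col(-D, ties.method = "first")          # NN at t+1 of each i at t
  fwd_d <- D[cbind(seq_len(n), fwd)]
  back <- max.col(-t(D), ties.method = "first")      # NN at t of each j at t+1
  if (n >= 2) {
    S <- pairwise_dist(xyz(ft), xyz(ft))
    diag(S) <- Inf
    same_d <- apply(S, 1, min)
  } else same_d <- rep(Inf, n)
  safe <- fwd_d < config$safe_link_factor * same_d
  claims_on_j <- tabulate(fwd, nbins = m)   # detections at t whose forward NN is j
  claims_on_i <- tabulate(back, nbins = n)  # detections at t+1 whose backward NN is i
  i <- seq_len(n); j <- fwd
  ok <- safe & (back[j] == i) & (claims_on_i[i] == 1L) & (claims_on_j[j] == 1L)
  out <- data.frame(pred_id = ft$id[i[ok]], succ_id = f1$id[j[ok]])
  out[order(out$pred_id), , drop = FALSE]
}

#' Phase-1 linking over a whole dataset
#'
#' Applies [link_frames()] to every consecutive frame pair; detections left
#' unlinked backward become the orphans handled by the bifurcation phase.
#'
#' @param det Detection table (all frames) as from [detections()].
#' @param config A [tracking_config()].
#' @return A [lineage()] containing all phase-1 links.
#' @export
link_all <- function(det, config) {
  lin <- lineage(det)
  if (nrow(det) == 0) return(lin)
  ts <- sort(unique(det$t))
  by_t <- split(seq_len(nrow(lin$det)), lin$det$t)
  for (k in seq_len(length(ts) - 1)) {
    if (ts[k + 1] - ts[k] != 1L) next
    ft <- lin$det[by_t[[as.character(ts[k])]], , drop = FALSE]
    f1 <- lin$det[by_t[[as.character(ts[k + 1])]], , drop = FALSE]
    lk <- link_frames(ft, f1, config)
    if (nrow(lk)) {
      rp <- match(lk$pred_id, lin$det$id)
      rs <- match(lk$succ_id, lin$det$id)
      lin$succ1[rp] <- lk$succ_id
      lin$pred[rs] <- lk$pred_id
    }
  }
  lin
}
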