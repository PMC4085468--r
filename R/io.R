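# Readers/writers: detection CSV, lineage CSV, Newick export, classifier
# model JSON, tracking-config JSON, and an optional reader for AceTree-style
# per-timepoint "nuclei" files.  All writers are deterministic: fixed column
# order and 6-significant-digit float formatting, so identical inputs give
# byte-identical files.

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.6g", x))
  out
}

#' Read a detection table from CSV
#'
#' Expects header columns `t,x,y,z,radius,intensity` (plus optional
#' `eccentricity`), all in voxel units.  Coordinates are scaled to microns
#' once here: x, y and radius by `xy_resolution`, z by `z_resolution`.
#' Detection ids are assigned deterministically in file order.
#'
#' @param path CSV path.
#' @param config A [tracking_config()] carrying the voxel resolutions.
#' @return Detection table as from [detections()].
#' @export
read_detections <- function(path, config = tracking_config()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "x", "y", "z", "radius", "intensity")
  for (col in need)
    if (!col %in% names(raw)) stop("detection file lacks required column '", col, "'")
  if (nrow(raw) == 0)
    return(detections(integer(), integer(), numeric(), numeric(), numeric(),
                      numeric(), numeric()))
  for (col in c(need, intersect("eccentricity", names(raw)))) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric value in column '", col, "' at data row ",
           if (length(bad)) bad[1] else "?", " of ", path)
    }
  }
  ecc <- if ("eccentricity" %in% names(raw)) raw$eccentricity else NA_real_
  detections(seq_len(nrow(raw)), raw$t,
             raw$x * config$xy_resolution, raw$y * config$xy_resolution,
             raw$z * config$z_resolution,
             raw$radius * config$xy_resolution, raw$intensity, ecc)
}

#' Write a lineage to CSV
#'
#' One row per detection (deleted ones included, for provenance):
#' `id,t,x,y,z,radius,intensity,eccentricity,pred_id,succ1_id,succ2_id,status`
#' with -1 for absent links.  Positions are written in microns.
#' [read_lineage()] inverts this exactly.
#'
#' @param lin A lineage.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage <- function(lin, path) {
  d <- lin$det
  enc <- function(v) ifelse(is.na(v), -1L, v)
  lines <- c(
    "id,t,x,y,z,radius,intensity,eccentricity,pred_id,succ1_id,succ2_id,status",
    sprintf("%d,%d,%s,%s,%s,%s,%s,%s,%d,%d,%d,%s",
            d$id, d$t, fmt_num(d$x), fmt_num(d$y), fmt_num(d$z),
            fmt_num(d$radius), fmt_num(d$intensity), fmt_num(d$eccentricity),
            enc(lin$pred), enc(lin$succ1), enc(lin$succ2), lin$status)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a lineage written by [write_lineage()]
#' @param path CSV path.
#' @return A lineage.
#' @export
read_lineage <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  lin <- lineage(detections(raw$id, raw$t, raw$x, raw$y, raw$z,
                            raw$radius, raw$intensity, raw$eccentricity))
  o <- match(lin$det$id, raw$id)
  dec <- function(v) { v <- as.integer(v); v[v == -1L] <- NA_integer_; v }
  lin$pred <- dec(raw$pred_id[o])
  lin$succ1 <- dec(raw$succ1_id[o])
  lin$succ2 <- dec(raw$succ2_id[o])
  lin$status <- raw$status[o]
  validate_lineage(lin)
  lin
}

#' Export a lineage tree as Newick text
#'
#' Tracks become edges whose branch lengths are track durations in frames;
#' terminal tracks become leaves.  Node labels are `n<first detection id>`.
#'
#' @param lin A lineage.
#' @param root_id Detection id starting the root track.
#' @return Newick string (terminated by `;`).
#' @export
export_newick <- function(lin, root_id) {
  if (!root_id %in% lin$det$id) stop("root id ", root_id, " not found")
  rec <- function(id) {
    ids <- branch_ids(lin, id)
    last <- ids[length(ids)]
    ts <- lin$det$t[match(c(ids[1], last), lin$det$id)]
    len <- ts[2] - ts[1] + 1L
    kids <- successors(lin, last)
    lab <- paste0("n", ids[1])
    if (length(kids) == 0) sprintf("%s:%d", lab, len)
    else sprintf("(%s)%s:%d", paste(vapply(kids, rec, character(1)),
                                    collapse = ","), lab, len)
  }
  paste0(rec(root_id), ";")
}

#' Serialize / load a Naive Bayes model as JSON
#'
#' Class priors plus per-class, per-feature Gaussian (mean, sd) and the
#' imputation medians: human-auditable and diffable.
#'
#' @param model An `nb_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_model()` returns the `nb_model`.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(
    classes = model$classes,
    priors = as.list(model$priors),
    mean = apply(model$mean, 1, as.list, simplify = FALSE),
    sd = apply(model$sd, 1, as.list, simplify = FALSE),
    feature_names = model$feature_names,
    impute = as.list(model$impute),
    n_train = model$n_train
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  classes <- j$classes
  fn <- j$feature_names
  tomat <- function(x) {
    m <- do.call(rbind, lapply(classes, function(cl) unlist(x[[cl]])[fn]))
    dimnames(m) <- list(classes, fn)
    m
  }
  structure(list(classes = classes,
                 priors = unlist(j$priors)[classes],
                 mean = tomat(j$mean), sd = tomat(j$sd),
                 feature_names = fn, impute = unlist(j$impute)[fn],
                 n_train = j$n_train),
            class = "nb_model")
}

#' Read a tracking config from JSON (fields merge over defaults)
#' @param path JSON path.
#' @return A [tracking_config()].
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(tracking_config, j[intersect(names(j), names(formals(tracking_config)))])
}

#' Read AceTree-style per-timepoint "nuclei" files
#'
#' Reads a directory of plain-text files named like `t001-nuclei`, one per
#' frame, comma-separated with the historical column layout (only the
#' minimal shared fields are used: index, forward/backward indices,
#' position, diameter, and a weight column taken as intensity).  Positions
#' are voxel-scaled like [read_detections()]; within-file indices are mapped
#' to globally unique detection ids and the recorded forward links are
#' installed.
#'
#' @param dir Directory containing `t*-nuclei` files.
#' @param config A [tracking_config()].
#' @return A lineage with the files' links.
#' @export
read_nuclei_dir <- function(dir, config = tracking_config()) {
  files <- sort(list.files(dir, pattern = "^t\\d+-nuclei$", full.names = TRUE))
  if (!length(files)) stop("no t*-nuclei files in ", dir)
  frames <- as.integer(sub("^t(\\d+)-nuclei$", "\\1", basename(files)))
  rows <- list(); id_of <- list()
  next_id <- 1L
  for (k in seq_along(files)) {
    raw <- utils::read.csv(files[k], header = FALSE, strip.white = TRUE,
                           stringsAsFactors = FALSE)
    raw <- raw[raw[[2]] != 0, , drop = FALSE]  # valid flag
    n <- nrow(raw)
    if (!n) { id_of[[k]] <- integer(); next }
    ids <- next_id:(next_id + n - 1L)
    next_id <- next_id + n
    id_of[[k]] <- stats::setNames(ids, raw[[1]])
    rows[[k]] <- data.frame(
      id = ids, t = frames[k],
      x = raw[[6]] * config$xy_resolution,
      y = raw[[7]] * config$xy_resolution,
      z = raw[[8]] * config$z_resolution,
      radius = raw[[9]] / 2 * config$xy_resolution,
      intensity = if (ncol(raw) >= 11) as.numeric(raw[[11]]) else 0,
      eccentricity = NA_real_,
      succ1_local = as.integer(raw[[4]]), succ2_local = as.integer(raw[[5]])
    )
  }
  all <- do.call(rbind, rows)
  lin <- lineage(detections(all$id, all$t, all$x, all$y, all$z,
                            all$radius, all$intensity, all$eccentricity))
  for (k in seq_len(length(files) - 1L)) {
    if (is.null(rows[[k]])) next
    for (q in seq_len(nrow(rows[[k]]))) {
      for (s in c(rows[[k]]$succ1_local[q], rows[[k]]$succ2_local[q])) {
        if (!is.na(s) && s > 0 && as.character(s) %in% names(id_of[[k + 1]]))
          lin <- add_link(lin, rows[[k]]$id[q], id_of[[k + 1]][[as.character(s)]])
      }
    }
  }
  lin
}

#' Write simulator output as the standard CSV dialects
#'
#' `detections.csv` (observed detections, micron units, resolution 1.0),
#' `truth_lineage.csv` (ground-truth lineage) and `annotations.csv` (one row
#' per injected error).
#'
#' @param sim A `synthetic_embryo` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- sim$observed$det
  lines <- c("t,x,y,z,radius,intensity,eccentricity",
             sprintf("%d,%s,%s,%s,%s,%s,%s", d$t, fmt_num(d$x), fmt_num(d$y),
                     fmt_num(d$z), fmt_num(d$radius), fmt_num(d$intensity),
                     fmt_num(d$eccentricity)))
  writeLines(lines, file.path(dir, "detections.csv"))
  write_lineage(sim$truth, file.path(dir, "truth_lineage.csv"))
  ann <- rbind(
    if (length(sim$observed$fn_ids))
      data.frame(kind = "fn", id = sim$observed$fn_ids, source = NA_integer_),
    if (length(sim$observed$fp_ids))
      data.frame(kind = "fp", id = sim$observed$fp_ids,
                 source = unname(sim$observed$fp_source[as.character(sim$observed$fp_ids)]))
  )
  if (is.null(ann)) ann <- data.frame(kind = character(), id = integer(),
                                      source = integer())
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  invisible(dir)
}
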