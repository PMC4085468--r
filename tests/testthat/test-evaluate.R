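cfg <- tracking_config()

test_that("density follows the shell formula", {
  # touching nuclei, radii 1 and 1, centers 2 apart -> 1
  fd <- dets(1:2, 1, x = c(0, 2), radius = 1)
  expect_equal(density_of(fd, 1), 1)
  # centers 4 apart -> 0.5
  fd <- dets(1:2, 1, x = c(0, 4), radius = 1)
  expect_equal(density_of(fd, 1), 0.5)
  # overlapping, centers 1 apart -> 2 (values above one permitted)
  fd <- dets(1:2, 1, x = c(0, 1), radius = 1)
  expect_equal(density_of(fd, 2), 2)
  # lone cell -> NA
  expect_true(is.na(density_of(dets(1L, 1, x = 0), 1)))
})

test_that("instantaneous accuracy counts exactly the wrong cell-frames", {
  truth <- chain_lineage(10)
  expect_identical(instantaneous_accuracy(truth, truth), 1)
  # one missing link -> one error
  pred <- remove_link(truth, 5, 6)
  expect_equal(instantaneous_accuracy(pred, truth), 1 - 1 / 10)
  # an undeleted spurious detection is one more error
  pred2 <- add_detection(pred, t = 3, x = 50, y = 0, z = 0, radius = 1,
                         intensity = 5)$lineage
  expect_equal(instantaneous_accuracy(pred2, truth), 1 - 2 / 10)
  # deleting the spurious detection repairs that error
  pred3 <- set_status(pred2, 11, "deleted")
  expect_equal(instantaneous_accuracy(pred3, truth), 1 - 1 / 10)
  # wrongly deleting a true cell is an error even though links stay right
  pred4 <- set_status(truth, 10, "deleted")
  expect_equal(instantaneous_accuracy(pred4, truth), 1 - 1 / 10)
})

test_that("random link perturbations match a per-cell oracle recount", {
  set.seed(14)
  emb <- generate_embryo(sim_config(n_frames = 40L, cell_cycle_mean = 12,
                                    cell_cycle_sd = 1, rng_seed = 14L))
  truth <- emb$truth
  pred <- truth
  lk <- links_of(truth)
  kill <- lk[sample(nrow(lk), 25), ]
  for (q in seq_len(nrow(kill)))
    pred <- remove_link(pred, kill$pred_id[q], kill$succ_id[q])
  acc <- instantaneous_accuracy(pred, truth)
  # oracle: walk every truth detection and compare its predecessor by hand
  errs <- 0L
  for (r in seq_len(nrow(truth$det))) {
    id <- truth$det$id[r]
    if (!identical(predecessor(pred, id), predecessor(truth, id)))
      errs <- errs + 1L
  }
  expect_equal(acc, 1 - errs / nrow(truth$det))
  expect_identical(errs, 25L)   # each removed link wrongs exactly one cell
})

test_that("an early error wrongs the whole subtree in cumulative accuracy", {
  # synchronous tree: 1 -> 2 -> 4 cells over 15 frames
  emb <- generate_embryo(sim_config(n_start_cells = 1L, n_frames = 15L,
                                    cell_cycle_mean = 5, cell_cycle_sd = 0,
                                    rng_seed = 6L))
  truth <- emb$truth
  expect_identical(instantaneous_accuracy(truth, truth), 1)
  ca <- cumulative_accuracy(truth, truth)
  expect_true(all(ca$fraction == 1))
  # cut one generation-1 daughter's birth link: half of every later
  # generation carries the error
  div1 <- truth$det$id[which(!is.na(truth$succ2))[1]]
  daughter <- successors(truth, div1)[1]
  pred <- remove_link(truth, div1, daughter)
  ca <- cumulative_accuracy(pred, truth)
  expect_equal(ca$fraction[ca$generation == 0], 1)
  expect_equal(ca$fraction[ca$generation == 1], 0.5)
  expect_equal(ca$fraction[ca$generation == 2], 0.5)
  # cumulative accuracy through generation g never exceeds the instantaneous
  # accuracy over the cell-frames of generations <= g (errors accumulate)
  e <- lineagetracer:::instantaneous_errors(pred, truth)
  gen <- lineagetracer:::truth_generations(truth)
  for (g in ca$generation) {
    inst_g <- 1 - sum(e$err[gen <= g]) / sum(gen <= g)
    expect_lte(ca$fraction[ca$generation == g], inst_g + 1e-12)
  }
})

test_that("link-error injection agrees with the idealized cumulative simulation", {
  # dropping each link independently at rate p makes a terminal cell's
  # history clean with probability (1-p)^L, L = links on its 29-step path;
  # the idealized simulation flips one error per cell-frame (30 of them).
  # Both must match their own closed forms, which pins the two modules to
  # the same error model up to the root-frame convention.
  p <- 0.05
  fracs <- c()
  for (sd in 1:10) {
    emb <- generate_embryo(sim_config(n_start_cells = 1L, n_frames = 30L,
                                      cell_cycle_mean = 10, cell_cycle_sd = 0,
                                      rng_seed = 300L + sd))
    truth <- emb$truth
    set.seed(400L + sd)
    pred <- truth
    lk <- links_of(truth)
    kill <- which(stats::runif(nrow(lk)) < p)
    for (q in kill) pred <- remove_link(pred, lk$pred_id[q], lk$succ_id[q])
    ca <- cumulative_accuracy(pred, truth)
    fracs <- c(fracs, ca$fraction[nrow(ca)])
  }
  want_inj <- (1 - p)^29
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - want_inj), 4 * se + 0.01)
  sim <- simulate_cumulative_accuracy(p, 30, 10, n_reps = 4000L, seed = 8L)
  expect_lt(abs(sim$fraction[3] - (1 - p)^30), 0.03)
  expect_lt(abs(mean(fracs) - sim$fraction[3]),
            4 * se + abs(want_inj - (1 - p)^30) + 0.02)
})

test_that("division PPV and sensitivity follow their definitions", {
  emb <- generate_embryo(sim_config(n_frames = 40L, cell_cycle_mean = 10,
                                    cell_cycle_sd = 1.5, rng_seed = 21L))
  truth <- emb$truth
  ds <- division_scores(truth, truth)
  expect_identical(ds$ppv, 1)
  expect_identical(ds$sensitivity, 1)
  n_div <- ds$n_true
  expect_gt(n_div, 4)

  # un-divide one parent and fabricate one spurious division elsewhere;
  # use a late division so a non-dividing host cell exists in its frame
  divs <- which(!is.na(truth$succ2))
  p1 <- truth$det$id[divs[which.max(truth$det$t[divs])]]
  b1 <- successors(truth, p1)[2]
  pred <- remove_link(truth, p1, b1)
  f <- truth$det$t[match(p1, truth$det$id)]
  cand <- which(truth$det$t == f & !is.na(pred$succ1) & is.na(pred$succ2) &
                  truth$det$id != p1)
  expect_gt(length(cand), 0)
  w <- truth$det$id[cand[1]]
  pred <- add_link(pred, w, b1)   # w now has two successors: spurious division
  ds <- division_scores(pred, truth)
  expect_equal(ds$tp, n_div - 1L)
  expect_equal(ds$ppv, (n_div - 1) / n_div)
  expect_equal(ds$sensitivity, (n_div - 1) / n_div)
})

test_that("density-stratified errors partition the global error count", {
  model <- shared_model()
  sim <- simulate_dataset(sim_config(rng_seed = 71L, fn_rate = 0.01,
                                     fp_rate = 0.01))
  res <- trace_lineage(sim$observed$det, model, cfg)
  bd <- errors_by_density(res$lineage, sim$truth)
  e <- lineagetracer:::instantaneous_errors(res$lineage, sim$truth)
  expect_identical(sum(bd$errors), sum(e$err))
  expect_identical(sum(bd$n), nrow(sim$truth$det))
})

test_that("eval_report assembles all metrics", {
  truth <- chain_lineage(6)
  rep <- eval_report(truth, truth)
  expect_identical(rep$instantaneous_accuracy, 1)
  expect_true(all(rep$cumulative_accuracy$fraction == 1))
  expect_identical(rep$n_deleted, 0L)
  cm <- eval_report(truth, truth, bif_truth = c("division", "fp"),
                    bif_pred = c("division", "other"))$confusion
  expect_identical(dim(cm), c(4L, 4L))
  expect_identical(sum(cm), 2L)
})
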