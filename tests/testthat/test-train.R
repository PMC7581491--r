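make_test_cohort <- function(n = 12, seed = 5, scans = 3,
                             cfg = tiny_phantom_config()) {
  generate_cohort(n, scans_per_volume = scans, config = cfg, rng_seed = seed)
}

test_that("folds rotate validation pairs over balanced groups", {
  co <- make_test_cohort(12)
  folds <- make_folds(co, 6)
  expect_length(folds, 6)
  grp <- setNames(vapply(co$participants, `[[`, character(1), "group"),
                  vapply(co$participants, `[[`, character(1), "id"))
  val_all <- character()
  for (f in folds) {
    expect_length(f$val_participants, 2)
    expect_setequal(unname(grp[f$val_participants]), c("low", "high"))
    expect_length(f$train_participants, 10)
    expect_length(intersect(f$train_participants, f$val_participants), 0)
    # training balance: 5 low + 5 high
    expect_equal(sum(grp[f$train_participants] == "low"), 5)
    val_all <- c(val_all, f$val_participants)
  }
  expect_setequal(val_all, names(grp))            # everyone validates once
  expect_identical(folds, make_folds(co, 6))      # deterministic
})

test_that("degenerate fold requests are rejected", {
  co2 <- make_test_cohort(2)
  expect_error(make_folds(co2, 1), "empty")
  co <- make_test_cohort(4)
  co$participants[[1]]$group <- NULL
  expect_error(make_folds(co, 2), "unlabeled")
})

test_that("majority vote takes the modal class with probability tie-break", {
  m <- function(v) matrix(v, 1, 1)
  # k = 1: identity on the argmax map
  expect_equal(majority_vote(list(m(2L))), m(2L))
  # strict majority {1,1,1,2,2,0} -> 1
  maps <- lapply(c(1, 1, 1, 2, 2, 0), function(v) m(as.integer(v)))
  expect_equal(majority_vote(maps)[1, 1], 1L)
  # tie {1,1,2,2,0,0} with mean probabilities (0.2, 0.45, 0.35) -> class 1
  maps2 <- lapply(c(1, 1, 2, 2, 0, 0), function(v) m(as.integer(v)))
  probs <- lapply(1:6, function(i) array(c(0.2, 0.45, 0.35), c(1, 1, 3)))
  expect_equal(majority_vote(maps2, probs)[1, 1], 1L)
  # without probabilities the lowest tied class wins (documented)
  expect_equal(majority_vote(maps2)[1, 1], 0L)
  expect_error(majority_vote(list(m(1L), matrix(1L, 2, 2))), "shape")
  # agreement with elementwise mode on random stacks
  set.seed(12)
  stack <- lapply(1:5, function(i) matrix(sample(0:2, 36, TRUE), 6, 6))
  mv <- majority_vote(stack)
  for (i in seq_len(36)) {
    votes <- vapply(stack, function(s) s[[i]], integer(1))
    tab <- tabulate(votes + 1L, 3)
    expect_true(tab[mv[[i]] + 1L] == max(tab))
  }
})

test_that("training selects the best validation checkpoint", {
  co <- make_test_cohort(6)
  folds <- make_folds(co, 1)
  nc <- net_config(scse = "none")
  tc <- train_config(epochs = 3, n_folds = 1, n_runs = 1, seed = 2)
  m <- train_fold(co, folds[[1]], nc, tc, seed = 7)
  expect_s3_class(m, "oct_model")
  expect_equal(nrow(m$history), 3)
  expect_equal(m$val_dice, max(m$history$val_dice))
  expect_equal(m$best_epoch, which.max(m$history$val_dice))
  # 1 epoch (and augmentation disabled, the no-augmentation variant):
  # the returned checkpoint is the epoch-1 checkpoint
  m1 <- train_fold(co, folds[[1]], nc,
                   train_config(epochs = 1, n_folds = 1, n_runs = 1,
                                augment = FALSE), seed = 7)
  expect_equal(m1$best_epoch, 1L)
  expect_equal(m1$val_dice, m1$history$val_dice[1])
  # same seed reproduces the epoch-1 loss
  m1b <- train_fold(co, folds[[1]], nc,
                    train_config(epochs = 1, n_folds = 1, n_runs = 1,
                                 augment = FALSE), seed = 7)
  expect_equal(m1$history$train_loss, m1b$history$train_loss)
})

test_that("the network learns an easy phantom problem", {
  cfg <- tiny_phantom_config(speckle_looks = 30, n_flecks = 2,
                             n_shadows = 1)
  co <- generate_cohort(6, scans_per_volume = 3, config = cfg, rng_seed = 5)
  folds <- make_folds(co, 1)
  tc <- train_config(epochs = 10, n_folds = 1, n_runs = 1, seed = 3)
  m <- train_fold(co, folds[[1]], net_config(scse = "none"), tc, seed = 11)
  expect_gt(m$val_dice, 0.85)
  expect_gt(m$val_dice, m$history$val_dice[1])    # it actually improved
  # prediction on a held-out scan returns plausible boundaries
  p <- predict(m, co$participants[[1]]$volumes[[1]]$scans[[1]])
  expect_identical(dim(p$labels), c(64L + 16L, 64L))
  expect_length(p$boundaries$ilm, 64)
})

test_that("experiment seeds derive from run and fold deterministically", {
  co <- make_test_cohort(4)
  nc <- net_config(scse = "none")
  tc <- train_config(epochs = 1, n_folds = 1, n_runs = 1, seed = 50)
  ex <- run_experiment(co, nc, tc)
  expect_s3_class(ex, "oct_experiment")
  expect_equal(nrow(ex$report), 1)
  expect_equal(ex$report$seed, 50 + 1000 + 1)
  expect_equal(ex$aggregate$val_dice, ex$report$val_dice)
  # different runs shuffle in different orders
  tc2 <- train_config(epochs = 1, n_folds = 1, n_runs = 2, seed = 50)
  ex2 <- run_experiment(co, nc, tc2)
  o1 <- ex2$models[[1]][[1]]$batch_orders[[1]]
  o2 <- ex2$models[[2]][[1]]$batch_orders[[1]]
  expect_false(identical(o1, o2))
})

test_that("voting identical fold maps reduces to single-map delineation", {
  co <- make_test_cohort(4)
  folds <- make_folds(co, 1)
  tc <- train_config(epochs = 2, n_folds = 1, n_runs = 1, seed = 9)
  m <- train_fold(co, folds[[1]], net_config(scse = "none"), tc, seed = 31)
  sc <- co$participants[[1]]$volumes[[1]]$scans[[1]]
  # duplicate the same model: all "folds" agree exactly, so the voted map is
  # the single model's label map and the ensemble boundaries are those of
  # the label map delineated once
  ens <- predict_ensemble(list(m, m, m), sc)
  single_labels <- predict(m, sc)$labels
  expect_identical(ens$labels, single_labels)
  direct <- extract_boundaries(single_labels, pad_rows = tc$pad_rows)
  expect_equal(ens$boundaries$ilm, direct$ilm)
  expect_equal(ens$boundaries$rpe, direct$rpe)
})
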