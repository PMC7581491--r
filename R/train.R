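#' Training configuration
#'
#' @param epochs training epochs (default 100).
#' @param batch_size samples per optimisation step (default 3).
#' @param n_runs repeated runs per experiment (default 5); run/fold seeds are
#'   derived as `seed + 1000 * run + fold`.
#' @param n_folds participant-balanced folds (default 6).
#' @param seed base seed.
#' @param shuffle reshuffle the sample order every epoch.
#' @param augment apply training-time augmentation ([augment()]); disabling
#'   reproduces the no-augmentation variant.
#' @param augment_cfg an [augment_config()].
#' @param contrast_enhance apply [enhance_contrast()] as a dataset-level
#'   preprocess before training and prediction.
#' @param energy_exponent exponent of the contrast enhancement.
#' @param noise_on whether augmentation noise is added to the `"enhanced"`
#'   intensities (default: enhancement is a dataset-level preprocess,
#'   augmentation a presentation-time transform) or to the `"raw"` image,
#'   which is then re-enhanced.
#' @param pad_rows zero rows added at the top of every image (default 16).
#' @param lr,beta1,beta2,adam_eps Adam hyperparameters (library defaults).
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 3L, n_runs = 5L,
                         n_folds = 6L, seed = 1L, shuffle = TRUE,
                         augment = TRUE, augment_cfg = augment_config(),
                         contrast_enhance = TRUE, energy_exponent = 2,
                         noise_on = c("enhanced", "raw"),
                         pad_rows = 16L, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, adam_eps = 1e-8) {
  if (epochs < 1 || batch_size < 1) stop("epochs and batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 n_runs = as.integer(n_runs), n_folds = as.integer(n_folds),
                 seed = as.integer(seed), shuffle = isTRUE(shuffle),
                 augment = isTRUE(augment), augment_cfg = augment_cfg,
                 contrast_enhance = isTRUE(contrast_enhance),
                 energy_exponent = energy_exponent,
                 noise_on = match.arg(noise_on), pad_rows = as.integer(pad_rows),
                 lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps),
            class = "train_config")
}

#' Participant-balanced k-fold splits
#'
#' Validation pairs rotate deterministically over the group-sorted
#' participant ids: fold `k` validates the `k`-th low-volume and the `k`-th
#' high-volume participant (wrapping around), so with one fold per
#' participant pair every participant validates exactly once.  All remaining
#' participants train; a participant's volumes are never split between train
#' and validation within a fold.
#'
#' @param cohort an `oct_cohort` with group labels.
#' @param n_folds number of folds (default 6).
#' @return list of fold splits: `fold_index`, `train_participants`,
#'   `val_participants` (one low, one high).
#' @export
make_folds <- function(cohort, n_folds = 6L) {
  ids <- vapply(cohort$participants, `[[`, character(1), "id")
  grp <- vapply(cohort$participants, function(p) p$group %||% NA_character_, character(1))
  if (anyNA(grp)) stop("cohort has unlabeled participants")
  low <- sort(ids[grp == "low"]); high <- sort(ids[grp == "high"])
  if (length(low) == 0 || length(high) == 0)
    stop("need both low- and high-volume participants")
  if (length(ids) <= 2)
    stop("cannot form folds: training set would be empty")
  lapply(seq_len(n_folds), function(k) {
    val <- c(low[(k - 1L) %% length(low) + 1L],
             high[(k - 1L) %% length(high) + 1L])
    list(fold_index = k,
         train_participants = setdiff(ids, val),
         val_participants = val)
  })
}

# collect preprocessed training samples for a set of participants:
# each sample: raw padded image, enhanced padded image, padded boundaries
prepare_samples <- function(cohort, participant_ids, train_cfg) {
  samples <- list()
  for (p in cohort$participants) {
    if (!p$id %in% participant_ids) next
    for (v in p$volumes)
      for (s in seq_along(v$scans)) {
        img <- v$scans[[s]]$pixels
        enh <- if (train_cfg$contrast_enhance)
          enhance_contrast(img, train_cfg$energy_exponent) else img
        pb <- pad_top(enh, train_cfg$pad_rows, v$boundaries[[s]])
        raw_p <- pad_top(img, train_cfg$pad_rows)
        samples[[length(samples) + 1L]] <- list(
          x = pb$image, raw = raw_p, boundaries = pb$boundaries,
          participant = p$id,
          scan_id = sprintf("%s_v%d_s%03d", p$id, v$visit, s - 1L))
      }
  }
  samples
}

# presentation-time augmentation of one prepared sample -> list(x, regions)
present_sample <- function(sm, train_cfg, n_classes = 3L) {
  h <- nrow(sm$x); w <- ncol(sm$x)
  if (!train_cfg$augment)
    return(list(x = sm$x,
                regions = boundaries_to_regions(sm$boundaries, h, w)))
  if (train_cfg$noise_on == "enhanced" || !train_cfg$contrast_enhance) {
    a <- augment(sm$x, sm$boundaries, train_cfg$augment_cfg)
    x <- a$image
  } else {
    a <- augment(sm$raw, sm$boundaries, train_cfg$augment_cfg)
    x <- pad_top(enhance_contrast(
      a$image[-seq_len(train_cfg$pad_rows), , drop = FALSE],
      train_cfg$energy_exponent), train_cfg$pad_rows)
  }
  list(x = x, regions = boundaries_to_regions(a$boundaries, h, w))
}

argmax_labels <- function(probs) {
  p1 <- probs[, , 1, 1]; p2 <- probs[, , 2, 1]; p3 <- probs[, , 3, 1]
  lab <- matrix(0L, nrow(p1), ncol(p1))
  lab[p2 > p1] <- 1L
  lab[p3 > pmax(p1, p2)] <- 2L
  lab
}

# mean hard Dice (fraction, not percent) of a model on prepared samples
validation_dice <- function(net, samples, train_cfg) {
  d <- vapply(samples, function(sm) {
    x <- array(sm$x / 255, c(nrow(sm$x), ncol(sm$x), 1, 1))
    fw <- network_forward(net, x, training = FALSE)
    truth <- boundaries_to_regions(sm$boundaries, nrow(sm$x), ncol(sm$x))
    unname(dice_overlap(argmax_labels(fw$probs), truth)["overall"]) / 100
  }, numeric(1))
  mean(d)
}

#' Train the network on one fold
#'
#' Minimises the soft Dice loss with Adam over the fold's training
#' participants, evaluating hard Dice overlap on the validation pair after
#' every epoch and returning the checkpoint with the highest validation
#' Dice.  All randomness (weight initialisation, shuffling, augmentation,
#' dropout) derives from `seed`.
#'
#' @param cohort an `oct_cohort`.
#' @param fold one element of [make_folds()].
#' @param net_cfg a [net_config()].
#' @param train_cfg a [train_config()].
#' @param seed integer seed for this fold.
#' @return an object of class `oct_model`: the selected network, the
#'   per-epoch history (`epoch`, `train_loss`, `val_dice`), the best epoch,
#'   and the configurations.
#' @export
train_fold <- function(cohort, fold, net_cfg, train_cfg, seed = train_cfg$seed) {
  train_s <- prepare_samples(cohort, fold$train_participants, train_cfg)
  val_s <- prepare_samples(cohort, fold$val_participants, train_cfg)
  if (length(train_s) == 0) stop("empty training set")
  ns <- length(train_s)

  with_seed(seed, {
    net <- build_network(net_cfg)
    state <- adam_init()
    best <- list(net = net, val_dice = -Inf, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_dice = numeric())
    batch_orders <- vector("list", train_cfg$epochs)
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- if (train_cfg$shuffle) sample.int(ns) else seq_len(ns)
      batch_orders[[ep]] <- ord
      losses <- numeric()
      for (b0 in seq(1, ns, by = train_cfg$batch_size)) {
        idx <- ord[b0:min(b0 + train_cfg$batch_size - 1L, ns)]
        pres <- lapply(train_s[idx], present_sample, train_cfg = train_cfg)
        h <- nrow(pres[[1]]$x); w <- ncol(pres[[1]]$x)
        nb <- length(pres)
        x <- array(0, c(h, w, 1, nb))
        t <- array(0, c(h, w, net_cfg$n_classes, nb))
        for (i in seq_len(nb)) {
          x[, , 1, i] <- pres[[i]]$x / 255
          t[, , , i] <- one_hot_regions(pres[[i]]$regions, net_cfg$n_classes)
        }
        fw <- network_forward(net, x, training = TRUE)
        net <- fw$net
        dl <- dice_loss(fw$probs, t, gradient = TRUE)
        if (!is.finite(dl$loss))
          stop(sprintf("NaN/Inf Dice loss at epoch %d (seed %d): aborting run",
                       ep, seed))
        losses <- c(losses, dl$loss)
        g <- network_backward(net, fw$cache, dl$grad)
        st <- adam_step(net, g, state, lr = train_cfg$lr,
                        beta1 = train_cfg$beta1, beta2 = train_cfg$beta2,
                        eps = train_cfg$adam_eps)
        net <- st$net; state <- st$state
      }
      vd <- validation_dice(net, val_s, train_cfg)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                     val_dice = vd))
      if (vd > best$val_dice) best <- list(net = net, val_dice = vd, epoch = ep)
    }
  })

  structure(list(net = best$net, val_dice = best$val_dice,
                 best_epoch = best$epoch, history = hist,
                 batch_orders = batch_orders,
                 fold = fold, net_cfg = net_cfg, train_cfg = train_cfg,
                 seed = as.integer(seed)),
            class = "oct_model")
}

#' @export
print.oct_model <- function(x, ...) {
  cat(sprintf("<oct_model: fold %d, best epoch %d/%d, validation Dice %.4f>\n",
              x$fold$fold_index, x$best_epoch, nrow(x$history), x$val_dice))
  invisible(x)
}

#' @export
summary.oct_model <- function(object, ...) {
  cat("Semantic segmentation model\n")
  cat(sprintf("  architecture: %d pools, filters %s, scSE=%s, ERF %d px\n",
              object$net_cfg$n_pool,
              paste(level_filters(object$net_cfg), collapse = "/"),
              object$net_cfg$scse, receptive_field(object$net_cfg)))
  cat(sprintf("  fold %d: train %s | val %s\n", object$fold$fold_index,
              paste(object$fold$train_participants, collapse = ","),
              paste(object$fold$val_participants, collapse = ",")))
  cat(sprintf("  best epoch %d/%d, validation Dice %.4f (seed %d)\n",
              object$best_epoch, nrow(object$history), object$val_dice,
              object$seed))
  invisible(object)
}

#' Segment a B-scan with a trained model
#'
#' Applies the model's own preprocessing (contrast enhancement if it was
#' trained with it, top padding), runs the network, and extracts both
#' boundaries by graph search on the probability map.
#'
#' @param object an `oct_model`.
#' @param newdata a [bscan()] or numeric pixel matrix.
#' @param ... unused.
#' @return `list(probs, labels, boundaries)`; `boundaries` is a
#'   [boundary_set()] on the original (unpadded) image grid.
#' @export
predict.oct_model <- function(object, newdata, ...) {
  img <- as_pixel_matrix(newdata)
  tc <- object$train_cfg
  enh <- if (tc$contrast_enhance)
    enhance_contrast(img, tc$energy_exponent) else img
  x <- pad_top(enh, tc$pad_rows)
  arr <- array(x / 255, c(nrow(x), ncol(x), 1, 1))
  fw <- network_forward(object$net, arr, training = FALSE)
  labels <- argmax_labels(fw$probs)
  list(probs = fw$probs, labels = labels,
       boundaries = extract_boundaries(array(fw$probs, dim(fw$probs)[1:3]),
                                       pad_rows = tc$pad_rows))
}

#' Majority vote over label maps from several networks
#'
#' Per pixel, the modal argmax class across the `k` networks; ties are
#' broken by the highest mean class probability across networks (or, when no
#' probability maps are supplied, by the lowest class index).
#'
#' @param label_maps list of integer label matrices of identical shape.
#' @param prob_maps optional list of `(H, W, C)` probability arrays.
#' @return a single integer label matrix.
#' @export
majority_vote <- function(label_maps, prob_maps = NULL) {
  if (length(label_maps) < 1) stop("need at least one label map")
  d <- dim(label_maps[[1]])
  if (!all(vapply(label_maps, function(m) identical(dim(m), d), logical(1))))
    stop("label maps have mismatched shapes")
  classes <- 0:2
  mean_p <- if (!is.null(prob_maps))
    Reduce(`+`, prob_maps) / length(prob_maps) else NULL
  score <- lapply(classes, function(cl) {
    cnt <- Reduce(`+`, lapply(label_maps, function(m) (m == cl) + 0))
    tie <- if (!is.null(mean_p)) 0.5 * mean_p[, , cl + 1L] else -1e-6 * cl
    cnt + tie
  })
  lab <- matrix(0L, d[1], d[2])
  lab[score[[2]] > score[[1]]] <- 1L
  lab[score[[3]] > pmax(score[[1]], score[[2]])] <- 2L
  lab
}

#' Ensemble prediction: vote the fold maps, then delineate once
#'
#' @param models list of `oct_model`s (e.g. one per fold).
#' @param newdata a [bscan()] or pixel matrix.
#' @return as [predict.oct_model()], computed on the voted label map.
#' @export
predict_ensemble <- function(models, newdata) {
  preds <- lapply(models, predict, newdata = newdata)
  labels <- majority_vote(lapply(preds, `[[`, "labels"),
                          lapply(preds, function(p)
                            array(p$probs, dim(p$probs)[1:3])))
  list(labels = labels,
       boundaries = extract_boundaries(labels,
                                       pad_rows = models[[1]]$train_cfg$pad_rows))
}

#' Evaluate boundary errors of fold models on chosen participants
#'
#' Runs every scan of the selected participants through either the
#' "average" path (each fold model delineates independently; the per-fold
#' error tables are averaged) or the "ensemble" path (the fold label maps
#' are majority-voted and delineated once).
#'
#' @param models list of `oct_model`s.
#' @param cohort an `oct_cohort`.
#' @param participant_ids participants to evaluate (default: all).
#' @param method `"average"` or `"ensemble"`.
#' @return aggregated [boundary_errors()] table (mean over scans), with the
#'   per-scan tables as attribute `per_scan`.
#' @export
evaluate_boundaries <- function(models, cohort, participant_ids = NULL,
                                method = c("average", "ensemble")) {
  method <- match.arg(method)
  ids <- participant_ids %||%
    vapply(cohort$participants, `[[`, character(1), "id")
  per_scan <- list()
  for (p in cohort$participants) {
    if (!p$id %in% ids) next
    for (v in p$volumes)
      for (s in seq_along(v$scans)) {
        truth <- v$boundaries[[s]]
        tab <- if (method == "average") {
          average_fold_errors(lapply(models, function(m)
            boundary_errors(predict(m, v$scans[[s]])$boundaries, truth)))
        } else {
          boundary_errors(predict_ensemble(models, v$scans[[s]])$boundaries,
                          truth)
        }
        per_scan[[sprintf("%s_v%d_s%03d", p$id, v$visit, s - 1L)]] <- tab
      }
  }
  out <- average_fold_errors(per_scan)
  attr(out, "per_scan") <- per_scan
  out
}

#' Run the full repeated k-fold experiment
#'
#' Trains `n_runs x n_folds` models with seeds derived deterministically as
#' `base seed + 1000 * run + fold`, and aggregates the per-fold validation
#' metrics per run and across runs.
#'
#' @param cohort an `oct_cohort`.
#' @param net_cfg a [net_config()].
#' @param train_cfg a [train_config()] (its `n_runs`, `n_folds`, `seed` are
#'   used).
#' @return an object of class `oct_experiment`: `models[[run]][[fold]]`, a
#'   per-cell `report` data.frame and the across-run `aggregate`.
#' @export
run_experiment <- function(cohort, net_cfg, train_cfg) {
  folds <- make_folds(cohort, train_cfg$n_folds)
  models <- vector("list", train_cfg$n_runs)
  report <- list()
  for (run in seq_len(train_cfg$n_runs)) {
    models[[run]] <- vector("list", length(folds))
    for (f in seq_along(folds)) {
      seed <- train_cfg$seed + 1000L * run + f
      m <- tryCatch(train_fold(cohort, folds[[f]], net_cfg, train_cfg, seed),
                    error = function(e) e)
      if (inherits(m, "error")) {
        warning(sprintf("run %d fold %d failed: %s", run, f,
                        conditionMessage(m)))
        report[[length(report) + 1L]] <- data.frame(
          run = run, fold = f, seed = seed, best_epoch = NA_integer_,
          val_dice = NA_real_, failed = TRUE)
        next
      }
      models[[run]][[f]] <- m
      report[[length(report) + 1L]] <- data.frame(
        run = run, fold = f, seed = seed, best_epoch = m$best_epoch,
        val_dice = m$val_dice, failed = FALSE)
    }
  }
  report <- do.call(rbind, report)
  agg <- stats::aggregate(val_dice ~ fold, data = report, FUN = mean,
                          na.action = stats::na.omit)
  structure(list(models = models, folds = folds, report = report,
                 aggregate = agg, net_cfg = net_cfg, train_cfg = train_cfg),
            class = "oct_experiment")
}

#' @export
print.oct_experiment <- function(x, ...) {
  ok <- !x$report$failed
  cat(sprintf("<oct_experiment: %d run(s) x %d fold(s), mean validation Dice %.4f>\n",
              x$train_cfg$n_runs, length(x$folds),
              mean(x$report$val_dice[ok])))
  invisible(x)
}

#' @export
summary.oct_experiment <- function(object, ...) {
  cat("Repeated k-fold semantic segmentation experiment\n")
  cat(sprintf("  runs: %d, folds: %d, epochs: %d\n", object$train_cfg$n_runs,
              length(object$folds), object$train_cfg$epochs))
  print(object$report)
  cat("Across-run mean validation Dice per fold:\n")
  print(object$aggregate)
  invisible(object)
}
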