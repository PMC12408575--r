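## Evaluation protocol: train/test splits, leave-one-subject-out
## authentication with aggregated-impostor labels, FRR/FAR threshold sweeps,
## EER, balanced accuracy, F1 and identification accuracy, with single-beat
## and five-beat majority-voted variants.

#' Split a recording into train and test portions
#'
#' The first `train_s` seconds become the training recording and the next
#' `test_s` seconds the test recording. Beat annotations are partitioned by
#' their peak index with a half-open `[0, train_s)` convention, so a peak
#' falling exactly on the boundary belongs to the test portion.
#'
#' @param recording a `doppler_recording`.
#' @param train_s,test_s split durations in seconds (default 48/12).
#' @return list with `train` and `test` recordings (test peak indices are
#'   relative to the test portion's start).
#' @export
split_train_test <- function(recording, train_s = 48, test_s = 12) {
  fs <- recording$fs
  n <- length(recording$samples)
  if ((train_s + test_s) * fs > n)
    stop_beat("recording too short for a %g + %g s split", train_s, test_s)
  nt <- as.integer(round(train_s * fs))
  ne <- as.integer(round(test_s * fs))
  train <- recording
  train$samples <- recording$samples[seq_len(nt)]
  test <- recording
  test$samples <- recording$samples[(nt + 1L):(nt + ne)]
  if (!is.null(recording$rpeaks)) {
    in_train <- (recording$rpeaks - 1L) < nt       # 0-based half-open
    train$rpeaks <- recording$rpeaks[in_train]
    tp <- recording$rpeaks[!in_train] - nt
    test$rpeaks <- tp[tp >= 1L & tp <= ne]
  }
  train$beat_only <- test$beat_only <- NULL
  list(train = train, test = test)
}

#' Build one LOOCV authentication task
#'
#' Training labels: the target subject is label 1; an aggregated "others"
#' class (label 0) is built by sampling a `1/(K - 2)` fraction (without
#' replacement, seeded) of each non-target, non-held-out subject's training
#' spectrograms, mirroring the 1/11 balancing used with 13 subjects. The
#' held-out subject never appears in training; their test data joins the
#' impostor probe set, exercising rejection of unregistered individuals.
#'
#' @param features per-subject feature list as returned by
#'   [extract_features()]: names are subject ids, each with `train` and
#'   `test` spectrogram arrays.
#' @param held_out,target distinct subject ids.
#' @param seed subsampling seed.
#' @return list with `values`/`labels` (training set), `genuine` (target's
#'   test array) and `impostors` (named list of test arrays, held-out
#'   included).
#' @export
build_loocv_task <- function(features, held_out, target, seed = 1L) {
  ids <- names(features)
  held_out <- as.character(held_out); target <- as.character(target)
  if (!held_out %in% ids || !target %in% ids)
    stop_beat("held_out/target id missing from the dataset")
  if (held_out == target) stop_beat("held_out and target must differ")
  K <- length(ids)
  if (K < 3L) stop_beat("need at least 3 subjects")
  frac <- 1 / (K - 2)
  others <- setdiff(ids, c(held_out, target))
  with_seed(seed, {
    other_vals <- lapply(others, function(id) {
      v <- features[[id]]$train
      n_i <- dim(v)[3]
      take <- floor(n_i * frac)
      if (take < 1L) take <- min(1L, n_i)
      v[, , sample.int(n_i, take), drop = FALSE]
    })
    tv <- features[[target]]$train
    vals <- simplify2array(c(
      unlist(lapply(other_vals, function(v) lapply(seq_len(dim(v)[3]), function(i) v[, , i])),
             recursive = FALSE),
      lapply(seq_len(dim(tv)[3]), function(i) tv[, , i])))
    labels <- c(rep(0L, sum(vapply(other_vals, function(v) dim(v)[3], 0L))),
                rep(1L, dim(tv)[3]))
    list(values = vals, labels = labels,
         genuine = features[[target]]$test,
         impostors = features[setdiff(ids, target)] |>
           lapply(function(f) f$test))
  })
}

#' FRR/FAR threshold sweep
#'
#' Candidate thresholds are the sorted unique distances, bracketed by finite
#' sentinels below the minimum (reject-all: FRR 1, FAR 0) and above the
#' maximum (accept-all: FRR 0, FAR 1). At each threshold tau a probe is
#' accepted iff its distance is strictly below tau; FRR is the fraction of
#' genuine probes rejected and FAR the fraction of impostor probes accepted.
#'
#' @param distances numeric distances.
#' @param is_genuine logical, same length (TRUE = genuine trial).
#' @return list of class `frr_far_curves` with `thresholds`, `frr`, `far`.
#' @export
sweep_frr_far <- function(distances, is_genuine) {
  if (!any(is_genuine) || !any(!is_genuine))
    stop_beat("need at least one genuine and one impostor trial")
  u <- sort(unique(distances))
  thr <- c(u[1] - 1, u, u[length(u)] + 1)
  g <- distances[is_genuine]; i <- distances[!is_genuine]
  frr <- vapply(thr, function(t) mean(g >= t), 0)
  far <- vapply(thr, function(t) mean(i < t), 0)
  structure(list(thresholds = thr, frr = frr, far = far),
            class = "frr_far_curves")
}

#' Equal error rate from FRR/FAR curves
#'
#' Returns the exact grid point where FRR equals FAR when one exists;
#' otherwise interpolates both curves linearly between the adjacent
#' thresholds where `FRR - FAR` changes sign and returns the common rate and
#' the interpolated threshold.
#'
#' @param curves an `frr_far_curves` object.
#' @return list with `eer` and `threshold`.
#' @export
compute_eer <- function(curves) {
  d <- curves$frr - curves$far
  hit <- which(d == 0)
  if (length(hit))
    return(list(eer = curves$frr[hit[1]], threshold = curves$thresholds[hit[1]]))
  k <- which(d[-length(d)] > 0 & d[-1] < 0)[1]
  u <- d[k] / (d[k] - d[k + 1])
  list(eer = curves$frr[k] + u * (curves$frr[k + 1] - curves$frr[k]),
       threshold = curves$thresholds[k] +
         u * (curves$thresholds[k + 1] - curves$thresholds[k]))
}

#' Verification metrics from accept/reject decisions
#'
#' @param accept logical decisions.
#' @param is_genuine logical truth (TRUE = the claimed identity was real).
#' @return list with `bac` (mean of TPR and TNR), `f1` and the confusion
#'   counts `tp`, `fp`, `tn`, `fn`.
#' @export
verification_metrics <- function(accept, is_genuine) {
  if (!any(is_genuine) || !any(!is_genuine))
    stop_beat("need both genuine and impostor decisions")
  tp <- sum(accept & is_genuine); fn <- sum(!accept & is_genuine)
  tn <- sum(!accept & !is_genuine); fp <- sum(accept & !is_genuine)
  tpr <- tp / (tp + fn); tnr <- tn / (tn + fp)
  list(bac = (tpr + tnr) / 2,
       f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Identification accuracy
#'
#' @param predictions,truths equal-length vectors of subject ids.
#' @return list with `acc` (overall fraction correct), `macro_acc` (mean of
#'   per-subject accuracies) and `per_subject`.
#' @export
identification_metrics <- function(predictions, truths) {
  if (length(predictions) != length(truths)) stop_beat("length mismatch")
  correct <- as.character(predictions) == as.character(truths)
  per <- c(tapply(correct, as.character(truths), mean))
  list(acc = mean(correct), macro_acc = mean(per),
       per_subject = per)
}

## ---- feature extraction ---------------------------------------------------

#' Extract gated beat spectrograms from a recording
#'
#' The preprocessing chain: zero-phase 15-50 Hz band-pass, peak detection
#' with the trained conformer (or ground-truth annotations), decimation to
#' 125 Hz, fixed-window segmentation around each peak, SNR gating at the
#' split-specific threshold, then Morlet-CWT magnitude spectrograms.
#'
#' @param recording a 250 Hz `doppler_recording`.
#' @param split_tag `"train"` or `"test"` (selects the SNR gate).
#' @param detector a trained `peaknet`, or `NULL` to use
#'   `recording$rpeaks` as an annotation-import path.
#' @param grid a [cwt_grid()].
#' @param spec a [filter_spec()].
#' @param window_len beat window length at 125 Hz.
#' @return 3-d spectrogram array `n_freq x n_time x n` (beats in time order).
#' @export
beat_spectrograms <- function(recording, split_tag, detector = NULL,
                              grid = cwt_grid(), spec = filter_spec(),
                              window_len = 64L) {
  filt <- bandpass(recording, spec)
  peaks <- if (is.null(detector)) recording$rpeaks else
    detect_peaks(detector, filt)
  filt$rpeaks <- peaks
  ds <- downsample_to_125(filt)
  seg <- segment_beats(ds, window_len = window_len)
  seg <- gate_segments(seg, split_tag)
  n <- nrow(seg$x)
  out <- array(0, c(grid$n_freq, grid$n_freq, n))
  for (k in seq_len(n))
    out[, , k] <- to_spectrogram(cwt_morlet(seg$x[k, ], grid))
  out
}

#' Per-subject train/test features for a dataset
#'
#' Applies [split_train_test()] and [beat_spectrograms()] to every
#' recording.
#'
#' @param recordings list of `doppler_recording`s (one per subject).
#' @param detector trained `peaknet` or `NULL` for ground-truth peaks.
#' @param grid,spec,window_len passed to [beat_spectrograms()].
#' @param train_s,test_s split durations.
#' @return named list (subject id -> list(train, test) arrays).
#' @export
extract_features <- function(recordings, detector = NULL, grid = cwt_grid(),
                             spec = filter_spec(), window_len = 64L,
                             train_s = 48, test_s = 12) {
  out <- lapply(recordings, function(rec) {
    sp <- split_train_test(rec, train_s, test_s)
    list(train = beat_spectrograms(sp$train, "train", detector, grid, spec,
                                   window_len),
         test = beat_spectrograms(sp$test, "test", detector, grid, spec,
                                  window_len))
  })
  names(out) <- vapply(recordings, function(r) as.character(r$subject_id), "")
  out
}

## ---- full protocol ---------------------------------------------------------

disjoint_groups_of_5 <- function(n) {
  k <- n %/% 5L
  lapply(seq_len(k), function(i) ((i - 1L) * 5L + 1L):(i * 5L))
}

# Median of 5 distances == the 3rd order statistic, so "median < tau" is
# exactly the 3-of-5 majority vote at threshold tau.
voted_scores <- function(d) {
  vapply(disjoint_groups_of_5(length(d)), function(ix) stats::median(d[ix]), 0)
}

auth_task_metrics <- function(model, task, target) {
  enc_g <- cvae_encode(model, task$genuine)$mean
  imp <- Filter(function(v) dim(v)[3] > 0, task$impostors)
  enc_i <- lapply(imp, function(v) cvae_encode(model, v)$mean)
  tr_ix <- task$labels == 1L
  gal <- enroll(stats::setNames(
    list(cvae_encode(model, task$values[, , tr_ix, drop = FALSE])$mean),
    target))
  dg <- mahalanobis_dist(enc_g, gal, target)
  di <- unlist(lapply(enc_i, function(z) mahalanobis_dist(z, gal, target)))
  single <- sweep_frr_far(c(dg, di), c(rep(TRUE, length(dg)), rep(FALSE, length(di))))
  eer_s <- compute_eer(single)
  vm_s <- verification_metrics(c(dg, di) < eer_s$threshold,
                               c(rep(TRUE, length(dg)), rep(FALSE, length(di))))
  vg <- voted_scores(dg)
  vi <- unlist(lapply(enc_i, function(z)
    voted_scores(mahalanobis_dist(z, gal, target))))
  out <- list(eer_single = eer_s$eer, bac_single = vm_s$bac, f1_single = vm_s$f1,
              threshold = eer_s$threshold)
  if (length(vg) && length(vi)) {
    voted <- sweep_frr_far(c(vg, vi), c(rep(TRUE, length(vg)), rep(FALSE, length(vi))))
    eer_v <- compute_eer(voted)
    vm_v <- verification_metrics(c(vg, vi) < eer_v$threshold,
                                 c(rep(TRUE, length(vg)), rep(FALSE, length(vi))))
    out$eer_voted <- eer_v$eer; out$bac_voted <- vm_v$bac; out$f1_voted <- vm_v$f1
  } else {
    out$eer_voted <- NA_real_; out$bac_voted <- NA_real_; out$f1_voted <- NA_real_
  }
  out
}

#' Run the full authentication + identification evaluation
#'
#' The complete protocol on a (typically synthetic) dataset:
#' \enumerate{
#'   \item train the conformer peak detector on recordings simulated
#'     separately from the evaluation subjects (no leakage into the
#'     authentication data);
#'   \item extract gated beat spectrograms per subject with a 48/12 s split;
#'   \item authentication: for every held-out subject h and every target
#'     subject s != h, train a two-label CVAE (target vs aggregated others),
#'     enroll the target, sweep FRR/FAR over Mahalanobis distances, compute
#'     EER and the BAC/F1 at the EER threshold, in single-beat and
#'     five-beat-voted variants (impostor probes include the held-out
#'     subject);
#'   \item identification: train one K-label CVAE on all subjects, enroll
#'     everyone, and classify test beats by nearest center, single and
#'     voted.
#' }
#'
#' A subject whose test beats are all rejected by the SNR gate remains
#' enrolled but is excluded from the probe sets (there is nothing to score);
#' macro averages cover the evaluable subjects.
#'
#' @param dataset list with `recordings` (and optionally `profiles`), as from
#'   [simulate_dataset()].
#' @param config a [pipeline_config()].
#' @param seed global seed; all stage seeds derive from it.
#' @return object of class `metrics_report`.
#' @export
run_full_evaluation <- function(dataset, config = pipeline_config(), seed = 1L) {
  recs <- dataset$recordings
  K <- length(recs)
  if (K < 3L) stop_beat("need at least 3 subjects")
  ids <- vapply(recs, function(r) as.character(r$subject_id), "")

  detector <- train_detector_corpus(config, seed)
  grid <- do.call(cwt_grid, config$grid)
  features <- extract_features(recs, detector, grid,
                               do.call(filter_spec, config$filter),
                               config$window_len, config$train_s, config$test_s)
  n_tr <- vapply(features, function(f) dim(f$train)[3], 0L)
  n_te <- vapply(features, function(f) dim(f$test)[3], 0L)
  if (any(n_tr < 2L))
    stop_beat("a subject has too few gated training beats (%s)",
              paste(n_tr, collapse = ","))
  # a subject whose test beats are all rejected by the SNR gate stays
  # enrolled but cannot be probed; macro metrics cover evaluable subjects
  eval_ids <- ids[n_te > 0L]
  if (length(eval_ids) < 2L)
    stop_beat("fewer than 2 subjects have gated test beats")

  ## identification: one K-label CVAE over all subjects
  id_vals <- simplify2array(unlist(lapply(ids, function(id) {
    v <- features[[id]]$train
    lapply(seq_len(dim(v)[3]), function(i) v[, , i])
  }), recursive = FALSE))
  id_labels <- rep(seq_along(ids) - 1L, times = n_tr)
  if (isTRUE(config$augment)) {
    aug <- augment(id_vals, id_labels, seed = stage_seed(seed, "augment_id"))
    id_vals <- aug$values; id_labels <- aug$labels
  }
  id_cfg <- do.call(cvae_config, c(config$cvae, list(n_labels = K)))
  id_model <- train_cvae(id_vals, id_labels, id_cfg,
                         seed = stage_seed(seed, "cvae_id"))
  gal <- enroll(stats::setNames(lapply(ids, function(id)
    cvae_encode(id_model, features[[id]]$train)$mean), ids))
  pred_s <- c(); truth_s <- c(); pred_v <- c(); truth_v <- c()
  for (id in eval_ids) {
    z <- cvae_encode(id_model, features[[id]]$test)$mean
    pred_s <- c(pred_s, apply(z, 1L, identify_beat, gallery = gal))
    truth_s <- c(truth_s, rep(id, nrow(z)))
    for (ix in disjoint_groups_of_5(nrow(z))) {
      pred_v <- c(pred_v, identify_voted(z[ix, , drop = FALSE], gal))
      truth_v <- c(truth_v, id)
    }
  }
  ident <- list(single = identification_metrics(pred_s, truth_s),
                voted = identification_metrics(pred_v, truth_v))

  ## authentication LOOCV (binary tasks may use their own training batch
  ## size etc. via the auth_cvae override section)
  auth_cvae <- merge_config(config$cvae, config$auth_cvae %||% list(), "cvae.")
  auth_cfg <- do.call(cvae_config, c(auth_cvae, list(n_labels = 2L)))
  tasks <- list()
  for (h in ids) for (s in setdiff(eval_ids, h)) {
    task <- build_loocv_task(features, h, s,
                             seed = stage_seed(seed, paste0("task_", h, "_", s)))
    tv <- task$values; tl <- task$labels
    if (isTRUE(config$augment)) {
      aug <- augment(tv, tl, seed = stage_seed(seed, paste0("aug_", h, "_", s)))
      tv <- aug$values; tl <- aug$labels
    }
    model <- train_cvae(tv, tl, auth_cfg,
                        seed = stage_seed(seed, paste0("cvae_", h, "_", s)))
    m <- auth_task_metrics(model, task, s)
    tasks[[length(tasks) + 1L]] <-
      c(list(held_out = h, target = s), m)
  }
  auth <- do.call(rbind, lapply(tasks, function(t) as.data.frame(t)))

  structure(list(
    identification = ident,
    authentication = auth,
    summary = list(
      acc_single = ident$single$macro_acc,
      acc_voted = ident$voted$macro_acc,
      bac_single = mean(auth$bac_single),
      bac_voted = mean(auth$bac_voted, na.rm = TRUE),
      eer_single = mean(auth$eer_single),
      eer_voted = mean(auth$eer_voted, na.rm = TRUE),
      f1_single = mean(auth$f1_single),
      f1_voted = mean(auth$f1_voted, na.rm = TRUE)),
    n_subjects = K, seed = seed,
    config_hash = object_hash(config)),
    class = "metrics_report")
}

# Detector training on recordings simulated apart from the evaluation
# subjects, mirroring the protocol of training the peak extractor on
# separately measured data.
train_detector_corpus <- function(config, seed) {
  det_seed <- stage_seed(seed, "detector_corpus")
  corpus <- simulate_dataset(config$detector_subjects, det_seed,
                             duration = config$detector_duration,
                             noise_sd = config$detector_noise_sd)
  pk_cfg <- do.call(peaknet_config, config$peaknet)
  xs <- list(); ys <- list()
  for (rec in corpus$recordings) {
    filt <- bandpass(rec, do.call(filter_spec, config$filter))
    tgt <- encode_triangular(rec$rpeaks, length(filt$samples),
                             pk_cfg$half_width)
    w <- make_training_windows(filt$samples, tgt, pk_cfg$window_len,
                               pk_cfg$overlap_fraction)
    xs[[length(xs) + 1L]] <- w$x; ys[[length(ys) + 1L]] <- w$y
  }
  X <- do.call(rbind, xs); Y <- do.call(rbind, ys)
  nmax <- config$detector_max_windows
  if (nrow(X) > nmax) {
    keep <- with_seed(stage_seed(seed, "detector_windows"),
                      sample.int(nrow(X), nmax))
    X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
  }
  train_peaknet(list(x = X, y = Y), pk_cfg, seed = stage_seed(seed, "peaknet"))
}

#' @export
print.metrics_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<metrics_report> %d subjects (seed %d)\n", x$n_subjects, x$seed))
  cat(sprintf("  identification macro ACC: %.3f single / %.3f voted\n",
              s$acc_single, s$acc_voted))
  cat(sprintf("  authentication macro BAC: %.3f single / %.3f voted\n",
              s$bac_single, s$bac_voted))
  cat(sprintf("  authentication macro EER: %.3f single / %.3f voted\n",
              s$eer_single, s$eer_voted))
  cat(sprintf("  %d LOOCV tasks\n", nrow(x$authentication)))
  invisible(x)
}
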