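# End-to-end experiment driver: simulate a cohort, label and window the
# recordings, extract and normalize features, train both deep modules,
# calibrate per age group, and run the stratified bootstrap evaluation.
# This is the reference protocol at desk scale; every step is an exported
# building block that can also be run on its own.

#' Configuration of the end-to-end desk-scale experiment
#'
#' Defaults define the package's reference study conditions: a 1,380
#' subject simulated cohort at AF prevalence 20% (with slack above the
#' 600/300/300 split so that recordings unable to contribute an AF-free
#' hour do not starve the splits), 3-hour recordings at 100 Hz, AF-free
#' input intervals of 1 hour (six 10-minute windows), a tiny window
#' encoder at 25 Hz, and a pooled (single-age-group) sequence model with
#' per-age-group isotonic calibration.
#'
#' @param n_subjects simulated subjects.
#' @param af_prevalence fraction of AF-prone subjects.
#' @param burden_mix weights over burden strata.
#' @param duration,fs recording duration (s) and sampling rate (Hz).
#' @param interval_len AF-free input interval length, seconds.
#' @param n_train,n_calibration,n_test split sizes (subjects).
#' @param train_af_extra additional AF-positive training draw (two-stage
#'   enrichment; 0 keeps the training split at natural prevalence).
#' @param encoder an [encoder_config()].
#' @param windows_per_subject_a windows per training subject for module A.
#' @param epochs_a,epochs_b maximum training epochs for the two modules.
#' @param hidden module-B LSTM width per direction.
#' @param feature_sets feature-set configurations to train and compare.
#' @param eval_lengths input lengths (in 10-min windows) scored at test
#'   time.
#' @param B_boot bootstrap iterations for CIs and paired tests.
#' @return list of class `af_pipeline_config`.
#' @export
af_pipeline_config <- function(n_subjects = 1380, af_prevalence = 0.2,
                               burden_mix = c(low = 1 / 3, medium = 1 / 3, high = 1 / 3),
                               duration = 10800, fs = 100,
                               interval_len = 3600,
                               n_train = 600, n_calibration = 300, n_test = 300,
                               train_af_extra = 0,
                               encoder = encoder_config(),
                               windows_per_subject_a = 1,
                               epochs_a = 8, epochs_b = 30, hidden = 16,
                               feature_sets = c("AG", "All Features"),
                               eval_lengths = c(1, 6),
                               B_boot = 2000) {
  structure(as.list(environment()), class = "af_pipeline_config")
}

# Render one window directly at the encoder's input rate.
window_signal_for_encoder <- function(timeline, profile, start, enc) {
  synthesize_signal(timeline, profile, start, start + WINDOW_SEC * timeline$fs,
    out_fs = enc$input_fs)
}

#' Run the full AF-prediction experiment on a synthetic cohort
#'
#' Executes the complete protocol and returns raw/calibrated scores,
#' trained models, calibration maps and the stratified bootstrap report.
#' Deterministic given `seed`.
#'
#' @param seed integer master seed.
#' @param config an [af_pipeline_config()].
#' @param verbose print progress messages.
#' @return list of class `af_experiment`; see elements `report`,
#'   `metrics`, `manifest`, `models`, `encoder`, `calibration`.
#' @export
run_af_pipeline <- function(seed = 7, config = af_pipeline_config(),
                            verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()
  enc_cfg <- config$encoder

  say("simulating cohort of %d subjects (prevalence %.0f%%) ...",
    config$n_subjects, 100 * config$af_prevalence)
  cohort <- simulate_cohort(config$n_subjects, config$af_prevalence,
    config$burden_mix, seed = af_subseed(seed, "cohort"),
    duration = config$duration, fs = config$fs)
  manifest <- cohort$manifest

  say("selecting AF-free intervals and extracting window features ...")
  n_win <- config$interval_len %/% WINDOW_SEC
  feats <- vector("list", config$n_subjects)
  interval_start <- rep(NA_integer_, config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    if (manifest$excluded_persistent[i]) next
    tl <- cohort_timeline(cohort, i)
    sel <- select_af_free_interval(tl, config$interval_len)
    if (is.null(sel)) next
    interval_start[i] <- sel$start
    fmat <- t(vapply(sel$windows$start, function(s) {
      window_features(tl$episodes, tl$beats, s, tl$fs)
    }, numeric(length(HANDCRAFTED_FEATURES))))
    colnames(fmat) <- HANDCRAFTED_FEATURES
    feats[[i]] <- fmat
  }
  manifest$analyzed <- !is.na(interval_start)
  say("  %d/%d recordings contribute an AF-free %d-min interval",
    sum(manifest$analyzed), config$n_subjects, config$interval_len %/% 60)

  usable <- manifest[manifest$analyzed, , drop = FALSE]
  splits <- assemble_cohorts(usable,
    per_group_random = config$n_train,
    per_group_af_extra = config$train_af_extra,
    calib_per_group = config$n_calibration,
    test_total = config$n_test,
    seed = af_subseed(seed, "splits"), pool_groups = TRUE
  )
  manifest$split <- "UNUSED"
  manifest$split[match(splits$subject, manifest$subject)] <- splits$split
  manifest$age_group <- age_group(manifest$age)
  in_split <- manifest$split %in% c("TRAIN", "CALIBRATION", "TEST")
  say("  splits: %d train / %d calibration / %d test",
    sum(manifest$split == "TRAIN"), sum(manifest$split == "CALIBRATION"),
    sum(manifest$split == "TEST"))

  # ---- module A: weakly labelled window encoder ---------------------------
  say("synthesizing module-A training windows ...")
  tr_idx <- which(manifest$split == "TRAIN")
  a_rows <- list()
  a_labels <- numeric(0)
  for (i in tr_idx) {
    tl <- cohort_timeline(cohort, i)
    pick <- with_seed(af_subseed(seed, "awin", i),
      sample.int(n_win, min(config$windows_per_subject_a, n_win)))
    for (k in pick) {
      s <- interval_start[i] + (k - 1) * WINDOW_SEC * config$fs
      a_rows[[length(a_rows) + 1]] <- window_signal_for_encoder(tl, cohort$profiles[[i]], s, enc_cfg)
      a_labels <- c(a_labels, as.numeric(manifest$af_positive[i]))
    }
  }
  A <- do.call(rbind, a_rows)
  say("training module A on %d windows ...", nrow(A))
  encoder <- train_module_a(A, a_labels, enc_cfg,
    seed = af_subseed(seed, "enc"),
    epochs = config$epochs_a, verbose = verbose)
  checksum_before <- encoder_checksum(encoder)
  rm(A, a_rows)

  # ---- embeddings + held-out window AUC of the encoder --------------------
  say("encoding %d windows for %d recordings ...",
    n_win * sum(in_split), sum(in_split))
  emb <- list()
  a_val_scores <- numeric(0)
  a_val_labels <- numeric(0)
  for (i in which(in_split)) {
    tl <- cohort_timeline(cohort, i)
    em <- matrix(0, n_win, enc_cfg$embed_dim)
    for (k in seq_len(n_win)) {
      s <- interval_start[i] + (k - 1) * WINDOW_SEC * config$fs
      x <- window_signal_for_encoder(tl, cohort$profiles[[i]], s, enc_cfg)
      fw <- encoder_forward(encoder$weights, enc_cfg, x)
      em[k, ] <- fw$embedding
      if (k == 1 && manifest$split[i] == "TEST") {
        a_val_scores <- c(a_val_scores, sigmoid(fw$logit))
        a_val_labels <- c(a_val_labels, as.numeric(manifest$af_positive[i]))
      }
    }
    emb[[i]] <- em
  }
  module_a_auc <- roc_auc(a_val_scores, a_val_labels)
  say("  module A held-out window AUC: %.3f", module_a_auc)

  # ---- feature table + normalization --------------------------------------
  say("fitting and applying feature transforms ...")
  sub_idx <- which(in_split)
  tab <- do.call(rbind, lapply(sub_idx, function(i) {
    cbind(feats[[i]], emb[[i]])
  }))
  colnames(tab) <- c(HANDCRAFTED_FEATURES,
    paste0("emb_", seq_len(enc_cfg$embed_dim)))
  tab <- as.data.frame(tab)
  tab$age <- rep(manifest$age[sub_idx], each = n_win)
  tab$sex <- rep(as.numeric(manifest$sex[sub_idx] == "M"), each = n_win)
  row_subject <- rep(sub_idx, each = n_win)
  train_rows <- row_subject %in% which(manifest$split == "TRAIN")
  transforms <- fit_transforms(tab[train_rows, , drop = FALSE])
  tab_t <- apply_transforms(tab, transforms)

  seq_cols_all <- setdiff(colnames(tab_t), c("age", "sex"))
  sequences <- lapply(seq_along(sub_idx), function(j) {
    as.matrix(tab_t[row_subject == sub_idx[j], seq_cols_all, drop = FALSE])
  })
  demo_all <- t(vapply(seq_along(sub_idx), function(j) {
    r <- which(row_subject == sub_idx[j])[1]
    c(age = tab_t$age[r], sex = tab_t$sex[r])
  }, numeric(2)))
  labels_all <- as.numeric(manifest$af_positive[sub_idx])
  split_all <- manifest$split[sub_idx]
  is_tr <- split_all == "TRAIN"
  is_cal <- split_all == "CALIBRATION"
  is_te <- split_all == "TEST"

  # ---- module B per feature-set configuration -----------------------------
  models <- list()
  raw_scores <- list() # [[fset]][[split]] and per eval length
  for (fs_name in config$feature_sets) {
    fset <- af_feature_set(fs_name)
    cols <- feature_set_columns(fset, seq_cols_all)
    say("training module B [%s] (%d sequence features) ...", fs_name, length(cols))
    seqs_tr <- if (length(cols)) {
      lapply(sequences[is_tr], function(m) m[, cols, drop = FALSE])
    } else {
      NULL
    }
    demo_tr <- if (fset$use_demo) demo_all[is_tr, , drop = FALSE] else
      matrix(numeric(0), sum(is_tr), 0)
    model <- train_module_b(seqs_tr, demo_tr, labels_all[is_tr],
      hidden = config$hidden, seed = af_subseed(seed, "b", fs_name),
      epochs = config$epochs_b, verbose = FALSE)
    models[[fs_name]] <- model

    score_subject <- function(j, L) {
      sq <- if (length(cols)) sequences[[j]][, cols, drop = FALSE] else NULL
      dm <- if (fset$use_demo) demo_all[j, ] else numeric(0)
      predict_risk(model, sq, dm, n_windows = L)
    }
    raw_scores[[fs_name]] <- list(
      calibration = vapply(which(is_cal), score_subject, numeric(1), L = n_win),
      test = lapply(config$eval_lengths, function(L) {
        vapply(which(is_te), score_subject, numeric(1), L = L)
      })
    )
    names(raw_scores[[fs_name]]$test) <- paste0("L", config$eval_lengths)
  }
  checksum_after <- encoder_checksum(encoder)

  # ---- per-age-group isotonic calibration ---------------------------------
  say("fitting per-age-group isotonic calibration ...")
  grp_cal <- as.character(manifest$age_group[sub_idx][is_cal])
  grp_te <- as.character(manifest$age_group[sub_idx][is_te])
  y_cal <- labels_all[is_cal]
  y_te <- labels_all[is_te]
  Lmain <- paste0("L", max(config$eval_lengths))
  calibration <- list()
  cal_scores <- list()
  for (fs_name in config$feature_sets) {
    maps <- list()
    for (g in unique(grp_cal)) {
      sel <- grp_cal == g
      maps[[g]] <- suppressWarnings(
        fit_calibration(raw_scores[[fs_name]]$calibration[sel], y_cal[sel], g)
      )
    }
    calibration[[fs_name]] <- maps
    cal_scores[[fs_name]] <- calibrate_by_group(
      raw_scores[[fs_name]]$test[[Lmain]], grp_te, maps
    )
  }

  # ---- evaluation ----------------------------------------------------------
  say("bootstrap evaluation (B = %d) ...", config$B_boot)
  age_te <- manifest$age[sub_idx][is_te]
  burden_te <- manifest$af_burden[sub_idx][is_te]
  test_raw_main <- lapply(raw_scores, function(r) r$test[[Lmain]])
  report <- stratified_report(test_raw_main, y_te,
    age = age_te, burden = burden_te,
    B = config$B_boot, seed = af_subseed(seed, "report"))

  metrics <- list(module_a_window_auc = module_a_auc)
  for (fs_name in config$feature_sets) {
    for (L in config$eval_lengths) {
      key <- sprintf("auc_%s_L%d", gsub("[^A-Za-z]+", "_", tolower(fs_name)), L)
      metrics[[key]] <- roc_auc(raw_scores[[fs_name]]$test[[paste0("L", L)]], y_te)
    }
    op <- operating_point_at_sensitivity(test_raw_main[[fs_name]], y_te, 0.80)
    metrics[[sprintf("op80_%s", gsub("[^A-Za-z]+", "_", tolower(fs_name)))]] <- op
  }
  if (all(c("AG", "All Features") %in% config$feature_sets)) {
    metrics$paired_all_vs_ag <- paired_bootstrap_test(
      roc_auc, test_raw_main[["All Features"]], test_raw_main[["AG"]], y_te,
      B = config$B_boot, seed = af_subseed(seed, "paired")
    )
  }
  # decile reliability of the calibrated probabilities (last feature set)
  fs_last <- config$feature_sets[length(config$feature_sets)]
  metrics$reliability <- reliability_by_decile(cal_scores[[fs_last]], y_te)

  say("done in %.1f min", as.numeric(difftime(Sys.time(), t_start, units = "mins")))
  structure(list(
    manifest = manifest, interval_start = interval_start,
    encoder = encoder, models = models,
    checksum_before = checksum_before, checksum_after = checksum_after,
    transforms = transforms, calibration = calibration,
    raw_scores = raw_scores, calibrated_test = cal_scores,
    labels_test = y_te, age_test = age_te, burden_test = burden_te,
    groups_test = grp_te,
    report = report, metrics = metrics, config = config, seed = seed
  ), class = "af_experiment")
}

#' Decile reliability of calibrated probabilities
#'
#' Splits predictions into deciles of predicted probability and compares
#' the mean prediction with the observed event frequency per decile.
#'
#' @param prob calibrated probabilities.
#' @param labels 0/1 labels.
#' @return data.frame per decile (`n`, `mean_pred`, `obs_freq`, `gap`)
#'   with attribute `max_gap`.
#' @export
reliability_by_decile <- function(prob, labels) {
  labels <- as.numeric(labels)
  br <- unique(stats::quantile(prob, seq(0, 1, 0.1)))
  dec <- cut(prob, breaks = br, include.lowest = TRUE)
  rows <- do.call(rbind, lapply(levels(dec), function(l) {
    sel <- dec == l
    data.frame(
      decile = l, n = sum(sel),
      mean_pred = mean(prob[sel]), obs_freq = mean(labels[sel])
    )
  }))
  rows$gap <- abs(rows$mean_pred - rows$obs_freq)
  attr(rows, "max_gap") <- max(rows$gap)
  rows
}

#' @export
print.af_experiment <- function(x, ...) {
  cat("AF prediction experiment (seed", x$seed, ")\n")
  cat(sprintf("  analyzed recordings: %d of %d\n",
    sum(x$manifest$analyzed), nrow(x$manifest)))
  cat(sprintf("  module A held-out window AUC: %.3f\n",
    x$metrics$module_a_window_auc))
  ov <- x$report[x$report$stratum == "overall" & x$report$metric == "AUC", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  AUC [%s]: %.3f (95%% CI %.3f-%.3f)\n",
      ov$feature_set[i], ov$point[i], ov$ci_low[i], ov$ci_high[i]))
  }
  if (!is.null(x$metrics$paired_all_vs_ag)) {
    pt <- x$metrics$paired_all_vs_ag
    cat(sprintf("  paired All Features vs AG: dAUC %.3f (p = %.4f)\n",
      pt$delta, pt$p_value))
  }
  invisible(x)
}
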