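#' Default end-to-end run configuration
#'
#' One nested list drives the whole pipeline: sensor settings, cohort
#' simulation, windowing, feature selection and classifier options. A
#' single global seed fans out to per-stage seeds by fixed offsets so every
#' stage is independently reproducible from one knob.
#'
#' @return Named nested list; see the fields in the source and the methods
#'   vignette.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1,
    sensor = list(fs = 25, accel_scale = 4, gyro_scale = 500,
                  nodding_axis = "y"),
    cohort = list(n_calves = 48, day_length_s = 7200,
                  cough_rate_per_hour = 6),
    windowing = list(window_s = 10, overlap = 0.5,
                     peak_threshold = 1.3, peak_min_separation_s = 1.0),
    features = list(cor_threshold = 0.9),
    classify = list(n_test = 6, val_fraction = 0.2, k_folds = 5,
                    smote_k = 5, tune = FALSE, n_trials = 10,
                    hyper = list())
  )
}

#' Read a run configuration from YAML
#'
#' Values given in the file override the defaults of
#' \code{\link{defaultRunConfig}}; everything else keeps its default.
#'
#' @param path path to a YAML configuration file.
#' @return A validated configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultRunConfig(), user)
  stopifnot(is.numeric(cfg$seed), cfg$sensor$fs > 0,
            cfg$cohort$n_calves >= 2,
            cfg$windowing$overlap >= 0, cfg$windowing$overlap < 1,
            cfg$classify$n_test >= 1)
  cfg
}

.sensor_from_config <- function(cfg)
  sensorConfig(fs = cfg$sensor$fs, accelScale = cfg$sensor$accel_scale,
               gyroScale = cfg$sensor$gyro_scale,
               noddingAxis = cfg$sensor$nodding_axis)

.bind_feature_tables <- function(fts) {
  stopifnot(length(fts) >= 1)
  fn <- featureNames(fts[[1]])
  featureTable(do.call(rbind, lapply(fts, tableData)), fn, modelTag(fts[[1]]))
}

.retag <- function(ft, tag) featureTable(ft@data, ft@featureNames, tag)

.apply_feature_subset <- function(ft, keep) {
  meta <- setdiff(names(ft@data), ft@featureNames)
  featureTable(ft@data[c(meta, keep)], keep, ft@modelTag)
}

# correlation filter + tree-importance selection, fitted on training rows
# only, then applied to the whole table
.select_features <- function(ft, train_rows, labcol, cor_threshold, seed) {
  trft <- .subset_ft(ft, train_rows)
  dc <- dropCorrelated(trft, threshold = cor_threshold)
  si <- selectByImportance(dc$table, labcol, seed = seed)
  list(table = .apply_feature_subset(ft, si$report$surviving),
       correlation = dc$report, importance = si$report)
}

#' Simulate a cohort and write it to disk
#'
#' Writes one recording CSV and one annotation CSV per calf plus a JSON
#' manifest (seeds, configuration, package and R versions) sufficient to
#' re-execute the run.
#'
#' @param config configuration list, see \code{\link{defaultRunConfig}}.
#' @param outDir output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
runSimulate <- function(config = defaultRunConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  scfg <- .sensor_from_config(config)
  cohort <- simulateCohort(config$cohort$n_calves, config$cohort$day_length_s,
                           seed = config$seed,
                           coughRatePerHour = config$cohort$cough_rate_per_hour,
                           config = scfg)
  files <- lapply(cohort, function(cc) {
    id <- calfId(cc$recording)
    rf <- file.path(outDir, paste0(id, "_recording.csv"))
    af <- file.path(outDir, paste0(id, "_annotations.csv"))
    writeRecording(cc$recording, rf)
    writeAnnotations(cc$track, af)
    c(recording = rf, annotations = af)
  })
  manifest <- list(seed = config$seed, config = config,
                   n_calves = length(cohort),
                   files = lapply(files, as.list),
                   package_version = as.character(utils::packageVersion("calfIMU")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the full pipeline end to end
#'
#' Simulate (or accept) an annotated cohort, then: attach magnitude
#' channels; segment and label 10 s analysis windows; extract and select
#' features; split train/test by individual calf; train the three
#' classifiers (actions, postures, cough events — the last with SMOTE
#' balancing and stratified cross-validation); predict the held-out
#' calves; and evaluate confusion metrics, ROC AUC, daily time budgets and
#' cough-frequency correlations. Every stage logs row counts; the whole
#' run is reproducible from the configuration seed.
#'
#' @param config configuration list, see \code{\link{defaultRunConfig}}.
#' @param outDir optional directory for report JSON, metric/prediction CSVs
#'   and a manifest.
#' @param cohort optionally, a pre-built cohort (as from
#'   \code{\link{simulateCohort}}) to use instead of simulating.
#' @param quiet suppress progress messages.
#' @return A report list with per-model metrics, AUCs, selection reports,
#'   time budgets and correlations.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = NULL,
                        cohort = NULL, quiet = FALSE) {
  say <- if (quiet) function(...) invisible(NULL) else
    function(...) message("[calfIMU] ", ...)
  seed <- config$seed
  scfg <- .sensor_from_config(config)
  fs <- scfg@fs
  wcfg <- config$windowing
  pk <- peakConfig(wcfg$peak_threshold, wcfg$peak_min_separation_s)

  if (is.null(cohort)) {
    say("simulating cohort: ", config$cohort$n_calves, " calves x ",
        config$cohort$day_length_s, " s")
    cohort <- simulateCohort(config$cohort$n_calves,
                             config$cohort$day_length_s, seed = seed,
                             coughRatePerHour = config$cohort$cough_rate_per_hour,
                             config = scfg)
  }
  recs <- lapply(cohort, function(cc) attachMagnitudes(cc$recording))
  tracks <- lapply(cohort, `[[`, "track")
  names(recs) <- names(tracks) <- vapply(recs, calfId, character(1))

  say("segmenting ", wcfg$window_s, " s windows at ", wcfg$overlap * 100,
      "% overlap")
  ft1 <- .bind_feature_tables(lapply(names(recs), function(id) {
    w <- segmentWindows(recs[[id]], wcfg$window_s, wcfg$overlap)
    w <- labelWindows(w, tracks[[id]], fs)
    extractFeatures(recs[[id]], w, "model1")
  }))
  say(nrow(tableData(ft1)), " labelled analysis windows, ",
      length(featureNames(ft1)), " raw features")

  plan <- splitByIndividual(ft1, config$classify$n_test,
                            config$classify$val_fraction, seed + 101)
  say("split: ", length(plan$train_ids), " train calves / ",
      length(plan$test_ids), " test calves")
  trainv <- c(plan$train_rows, plan$val_rows)

  fit_windows_model <- function(ft, tag, stage_seed) {
    labcol <- .model_label_col(tag)
    sel <- .select_features(.retag(ft, tag), trainv, labcol,
                            config$features$cor_threshold, stage_seed)
    tab <- sel$table
    say(tag, ": ", length(featureNames(tab)), " features after selection")
    hyper <- config$classify$hyper[[tag]]
    if (is.null(hyper)) hyper <- list()
    if (isTRUE(config$classify$tune)) {
      tuned <- tuneHyperparameters(.subset_ft(tab, plan$train_rows),
                                   .subset_ft(tab, plan$val_rows),
                                   tuningSpec(nTrials = config$classify$n_trials,
                                              seed = stage_seed), tag)
      hyper <- utils::modifyList(hyper, tuned$best)
    }
    model <- trainModel(.subset_ft(tab, plan$train_rows),
                        .subset_ft(tab, plan$val_rows), tag, hyper,
                        seed = stage_seed)
    testFt <- .subset_ft(tab, plan$test_rows)
    pred <- predictModel(model, testFt)
    rep <- evaluationReport(tableData(testFt)[[labcol]], pred$label,
                            .model_classes(tag), pred)
    list(model = model, selection = sel[c("correlation", "importance")],
         predictions = cbind(tableData(testFt)[c("calf_id", "start_s")], pred),
         report = rep)
  }
  m1 <- fit_windows_model(ft1, "model1", seed + 201)
  m2 <- fit_windows_model(ft1, "model2", seed + 202)

  # Model 3: peak-anchored event windows
  say("detecting acceleration-magnitude peaks (threshold ", pk$threshold,
      " g)")
  ev_fts <- lapply(names(recs), function(id) {
    peaks <- detectPeaks(recs[[id]]@data$am, pk, fs)
    ew <- extractEventWindows(recs[[id]], peaks, tracks[[id]])
    if (!nrow(ew)) return(NULL)
    extractFeatures(recs[[id]], ew, "model3")
  })
  ft3 <- .bind_feature_tables(Filter(Negate(is.null), ev_fts))
  d3 <- tableData(ft3)
  say(nrow(d3), " event windows (",
      sum(d3$label == "coughing"), " coughing / ",
      sum(d3$label == "non_coughing"), " non-coughing)")

  tr3 <- which(d3$calf_id %in% plan$train_ids)
  te3 <- which(d3$calf_id %in% plan$test_ids)
  set.seed(seed + 301)
  val3 <- sort(sample(tr3, round(config$classify$val_fraction * length(tr3))))
  tr3 <- setdiff(tr3, val3)
  sel3 <- .select_features(ft3, c(tr3, val3), "label",
                           config$features$cor_threshold, seed + 302)
  tab3 <- sel3$table
  say("model3: ", length(featureNames(tab3)), " features after selection")

  # SMOTE on the training rows only
  os <- oversampleMinority(featureMatrix(tab3)[tr3, , drop = FALSE],
                           tableData(tab3)$label[tr3], seed = seed + 303,
                           kNeighbors = config$classify$smote_k)
  osft <- featureTable(
    cbind(data.frame(calf_id = "train", label = os$labels),
          as.data.frame(os$x)),
    featureNames(tab3), "model3")
  m3_model <- trainModel(osft, .subset_ft(tab3, val3), "model3",
                         seed = seed + 304)
  te3ft <- .subset_ft(tab3, te3)
  pred3 <- predictModel(m3_model, te3ft)
  rep3 <- evaluationReport(tableData(te3ft)$label, pred3$label,
                           EVENT_CLASSES, pred3)
  cv3 <- NULL
  trcv <- .subset_ft(ft3, which(d3$calf_id %in% plan$train_ids))
  if (all(table(tableData(trcv)$label) >= config$classify$k_folds))
    cv3 <- crossValidate(.apply_feature_subset(trcv, featureNames(tab3)),
                         "model3", k = config$classify$k_folds,
                         seed = seed + 305, oversample = TRUE)

  # daily time budgets on the held-out calves (non-overlapping windows)
  say("computing daily time budgets on test calves")
  infer <- lapply(plan$test_ids, function(id) {
    w <- segmentWindows(recs[[id]], wcfg$window_s, overlap = 0)
    extractFeatures(recs[[id]], w, "model1")
  })
  budget_for <- function(fit, tag, tier) {
    preds <- do.call(rbind, lapply(infer, function(ftc) {
      tabc <- .apply_feature_subset(.retag(ftc, tag), fit$model$featureNames)
      cbind(tableData(tabc)[c("calf_id", "start_s")],
            label = predictModel(fit$model, tabc)$label)
    }))
    tb <- timeBudget(preds, tracks[plan$test_ids], wcfg$window_s, tier)
    r <- vapply(split(tb, tb$behavior), function(g)
      tryCatch(pearsonR(g$predicted_s, g$observed_s), error = function(e) NA_real_),
      numeric(1))
    list(budget = tb, r = r)
  }
  tb1 <- budget_for(m1, "model1", "action")
  tb2 <- budget_for(m2, "model2", "state")

  ev_pred <- cbind(tableData(te3ft)[c("calf_id")],
                   t_s = tableData(te3ft)$peak_index / fs,
                   label = pred3$label)
  cf <- coughFrequency(ev_pred, tracks[plan$test_ids])
  r_cough <- tryCatch(pearsonR(cf$predicted_n, cf$observed_n),
                      error = function(e) NA_real_)

  report <- list(
    config = config,
    split = plan[c("train_ids", "test_ids")],
    funnel = list(n_windows = nrow(tableData(ft1)),
                  n_event_windows = nrow(d3),
                  n_cough_events = sum(d3$label == "coughing"),
                  n_features_model1 = length(m1$model$featureNames),
                  n_features_model2 = length(m2$model$featureNames),
                  n_features_model3 = length(featureNames(tab3))),
    model1 = list(metrics = m1$report$metrics, auc = m1$report$auc,
                  confusion = m1$report$confusion$table,
                  selection = m1$selection, predictions = m1$predictions),
    model2 = list(metrics = m2$report$metrics, auc = m2$report$auc,
                  confusion = m2$report$confusion$table,
                  selection = m2$selection, predictions = m2$predictions),
    model3 = list(metrics = rep3$metrics, auc = rep3$auc,
                  confusion = rep3$confusion$table,
                  selection = sel3[c("correlation", "importance")],
                  cv = if (!is.null(cv3)) cv3$metrics,
                  smote = list(before = table(tableData(tab3)$label[tr3]),
                               after = table(os$labels)),
                  predictions = cbind(ev_pred, pred3[-1])),
    time_budget = list(action = tb1$budget, r_action = tb1$r,
                       state = tb2$budget, r_state = tb2$r,
                       cough = cf, r_cough = r_cough)
  )
  if (!is.null(outDir)) .write_report(report, outDir)
  report
}

.write_report <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (tag in c("model1", "model2", "model3")) {
    utils::write.csv(report[[tag]]$metrics,
                     file.path(outDir, paste0(tag, "_metrics.csv")),
                     row.names = FALSE)
    utils::write.csv(report[[tag]]$predictions,
                     file.path(outDir, paste0(tag, "_predictions.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(report$time_budget$action,
                   file.path(outDir, "time_budget_action.csv"), row.names = FALSE)
  utils::write.csv(report$time_budget$state,
                   file.path(outDir, "time_budget_state.csv"), row.names = FALSE)
  utils::write.csv(report$time_budget$cough,
                   file.path(outDir, "cough_frequency.csv"), row.names = FALSE)
  summary <- list(
    seed = report$config$seed,
    funnel = report$funnel,
    macro_f1 = lapply(c(model1 = "model1", model2 = "model2",
                        model3 = "model3"), function(tag) {
      m <- report[[tag]]$metrics
      m$f1[m$class == "Overall"]
    }),
    auc = lapply(c(model1 = "model1", model2 = "model2",
                   model3 = "model3"), function(tag) as.list(report[[tag]]$auc)),
    r_action = as.list(report$time_budget$r_action),
    r_state = as.list(report$time_budget$r_state),
    r_cough = report$time_budget$r_cough,
    package_version = as.character(utils::packageVersion("calfIMU")),
    r_version = R.version.string)
  jsonlite::write_json(summary, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(report$config, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}

#' Inter-observer agreement between two annotation files
#'
#' Bins two observers' annotation tracks for the same calf onto a common
#' time lattice (default 1 s bins over the overlap of their annotated
#' spans) and computes Cohen's kappa on the binned label sequences.
#' Untagged action time is binned as \code{"others"}.
#'
#' @param pathA,pathB annotation CSV files for the same calf.
#' @param tier tier to compare (\code{"action"} or \code{"state"}).
#' @param binS lattice bin width in seconds.
#' @return list(kappa, p0, pc, n_bins).
#' @export
kappaFromFiles <- function(pathA, pathB, tier = "action", binS = 1) {
  a <- readAnnotations(pathA); b <- readAnnotations(pathB)
  if (calfId(a) != calfId(b))
    stop("alignment error: annotation files are for different calves",
         call. = FALSE)
  bin_track <- function(track, lo, hi) {
    iv <- intervals(track)
    iv <- iv[iv$tier == tier, , drop = FALSE]
    mids <- seq(lo + binS / 2, hi, by = binS)
    lab <- rep(if (tier == "action") "others" else "untagged", length(mids))
    for (i in seq_len(nrow(iv))) {
      inbin <- mids >= iv$start_s[i] & mids < iv$end_s[i]
      lab[inbin] <- iv$behavior[i]
    }
    lab
  }
  span <- function(track) {
    iv <- intervals(track); iv <- iv[iv$tier == tier, , drop = FALSE]
    if (!nrow(iv)) stop("alignment error: no '", tier, "' intervals",
                        call. = FALSE)
    c(min(iv$start_s), max(iv$end_s))
  }
  sa <- span(a); sb <- span(b)
  lo <- max(sa[1], sb[1]); hi <- min(sa[2], sb[2])
  if (hi - lo < binS)
    stop("alignment error: annotated spans do not overlap", call. = FALSE)
  la <- bin_track(a, lo, hi); lb <- bin_track(b, lo, hi)
  k <- cohensKappa(la, lb)
  c(k, list(n_bins = length(la)))
}
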