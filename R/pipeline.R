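#' Train the water-assessment classifier from a labeled corpus
#'
#' Preprocesses every bundle, extracts the conformity features against the
#' reference library, and trains the fuzzy pattern classifier. The class
#' order follows [CLASS_LABELS] for labels drawn from that scheme.
#'
#' @param bundles List of [measurement_bundle()] objects.
#' @param labels Class label per bundle.
#' @param ref_library Reference library, see [build_reference_library()].
#' @param feature_order Feature columns the classifier uses; the default
#'   adds the normalized turbidity reading to the four conformity features.
#' @param u_expanded Expanded uncertainties per feature.
#' @param taps,tmodel,cal Preprocessing configuration.
#' @return List with `classifier` (a [ft_train()] model) and `features`
#'   (the training feature table, one row per bundle, with a `label`
#'   column).
#' @export
run_training <- function(bundles, labels, ref_library,
                         feature_order = c("r2_440", "r2_590", "r2_850",
                                           "r2_uvvis", "turb"),
                         u_expanded = default_feature_uncertainties(),
                         taps = design_lowpass(),
                         tmodel = temperature_model(),
                         cal = turbidity_calibration()) {
  stopifnot(length(bundles) == length(labels))
  features <- assemble_features(bundles, ref_library, taps, tmodel, cal)
  features$label <- as.character(labels)
  lv <- intersect(CLASS_LABELS, unique(features$label))
  lv <- c(lv, setdiff(unique(features$label), lv))
  clf <- ft_train(features, factor(features$label, levels = lv),
                  feature_order = feature_order, u_expanded = u_expanded)
  list(classifier = clf, features = features)
}

#' Assess a set of measurement bundles
#'
#' Runs the full chain for each bundle - preprocessing, feature
#' extraction, fuzzy classification - and returns one report row per
#' sample: the features, the per-class memberships, the assignment, and
#' warning flags (saturation, temperature above the validity bound,
#' turbidity above the compensation bound). When a non-assigned class
#' reaches a membership above `alert_threshold` it is reported as a
#' secondary-class alert, the numeric form of "elevated competing class
#' warrants a warning".
#'
#' @param bundles List of [measurement_bundle()] objects.
#' @param clf A trained [ft_train()] classifier.
#' @param ref_library Reference library, see [build_reference_library()].
#' @param taps,tmodel,cal Preprocessing configuration.
#' @param alert_threshold Secondary-class alert level in \[0, 1\].
#' @return Data frame: `sample_id`, feature columns, `mu_*` memberships,
#'   `assigned`, `tie`, `secondary_alert`, `warnings`.
#' @export
run_assessment <- function(bundles, clf, ref_library,
                           taps = design_lowpass(),
                           tmodel = temperature_model(),
                           cal = turbidity_calibration(),
                           alert_threshold = 0.4) {
  features <- assemble_features(bundles, ref_library, taps, tmodel, cal,
                                collect_warnings = TRUE)
  warnings <- attr(features, "warnings")
  res <- ft_classify(clf, features)
  mu_cols <- grep("^mu_", names(res), value = TRUE)
  res$secondary_alert <- vapply(seq_len(nrow(res)), function(i) {
    mus <- unlist(res[i, mu_cols])
    names(mus) <- sub("^mu_", "", mu_cols)
    mus <- mus[names(mus) != res$assigned[i]]
    hot <- names(mus)[mus > alert_threshold]
    paste(hot, collapse = ";")
  }, "")
  out <- cbind(features, res)
  out$warnings <- vapply(warnings, paste, "", collapse = "; ")
  rownames(out) <- NULL
  out
}

assemble_features <- function(bundles, ref_library, taps, tmodel, cal,
                              collect_warnings = FALSE) {
  rows <- vector("list", length(bundles))
  warns <- vector("list", length(bundles))
  for (i in seq_along(bundles)) {
    prep <- preprocess_bundle(bundles[[i]], taps = taps,
                              tmodel = tmodel, cal = cal)
    rows[[i]] <- extract_features(prep, ref_library,
                                  valid_max_fnu = cal$valid_max_fnu)
    warns[[i]] <- prep$warnings
  }
  features <- do.call(rbind, rows)
  if (collect_warnings) attr(features, "warnings") <- warns
  features
}
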