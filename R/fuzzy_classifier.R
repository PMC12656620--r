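#' One-dimensional Aizerman membership parameters
#'
#' A unimodal potential-type membership function around the representative
#' value `x0`, with side-specific fuzziness `b` (membership at distance
#' `c`), scope of uncertainty `c` and slope `d`:
#' `mu(x) = a / (1 + (1/b_s - 1) * (|x - x0| / c_s)^d_s)`,
#' with side `s = l` for `x < x0` and `s = r` otherwise.
#'
#' @param x0 Representative feature value (point of maximum membership).
#' @param a Maximum membership (default 1).
#' @param b_l,b_r Fuzziness per side, in (0, 1].
#' @param c_l,c_r Scope of uncertainty per side, > 0.
#' @param d_l,d_r Slope per side, > 0.
#' @return Object of class `membership_params`.
#' @export
membership_params <- function(x0, a = 1, b_l = 0.5, b_r = 0.5,
                              c_l, c_r, d_l = 2, d_r = 2) {
  if (!(b_l > 0 && b_l <= 1 && b_r > 0 && b_r <= 1))
    stop("fuzziness b must lie in (0, 1]")
  if (!(c_l > 0 && c_r > 0)) stop("scope c must be positive")
  if (!(d_l > 0 && d_r > 0)) stop("slope d must be positive")
  structure(list(x0 = x0, a = a, b_l = b_l, b_r = b_r,
                 c_l = c_l, c_r = c_r, d_l = d_l, d_r = d_r),
            class = "membership_params")
}

#' Evaluate the Aizerman membership function
#'
#' @param x Numeric feature values (vectorized).
#' @param p A [membership_params()].
#' @return Membership values in (0, a], with `mu(x0) = a` exactly.
#' @export
aizerman_membership <- function(x, p) {
  stopifnot(inherits(p, "membership_params"))
  left <- x < p$x0
  b <- ifelse(left, p$b_l, p$b_r)
  cc <- ifelse(left, p$c_l, p$c_r)
  d <- ifelse(left, p$d_l, p$d_r)
  p$a / (1 + (1 / b - 1) * (abs(x - p$x0) / cc)^d)
}

#' Compensatory aggregation of per-dimension memberships
#'
#' The N-fold compensatory aggregation used here is the arithmetic mean of
#' the per-dimension memberships, which is idempotent and lies between the
#' minimum and maximum of its arguments.
#'
#' @param memberships Non-empty numeric vector of values in \[0, 1\].
#' @return Aggregated class membership.
#' @export
aggregate_memberships <- function(memberships) {
  if (!length(memberships)) stop("cannot aggregate an empty membership list")
  mean(memberships)
}

#' Train a fuzzy pattern classifier from labeled feature vectors
#'
#' For every class and feature dimension the representative value is the
#' class mean and the scope parameters follow the spread of the class
#' members widened by the expanded measurement uncertainty of that feature:
#' `x0 = mean(x)`, `c_l = (x0 - min(x)) + U`, `c_r = (max(x) - x0) + U`.
#' A singleton class therefore still has `c = U` on both sides, so its
#' membership function is exactly as wide as the measurement uncertainty.
#' Fuzziness and slope use the conventional defaults `b = 0.5`, `d = 2`,
#' and the maximum membership is `a = 1`.
#'
#' @param features Data frame of feature columns (plus optionally others).
#' @param labels Vector of class labels, one per row; a factor's level
#'   order fixes the class order (ties in classification break toward the
#'   earlier class).
#' @param feature_order Character vector naming the feature columns to use.
#' @param u_expanded Named numeric vector of expanded uncertainties per
#'   feature (see [default_feature_uncertainties()]).
#' @param a,b,d Membership defaults applied to every dimension.
#' @return Object of class `fuzzy_classifier`.
#' @export
ft_train <- function(features, labels,
                     feature_order = c("r2_440", "r2_590", "r2_850", "r2_uvvis"),
                     u_expanded = default_feature_uncertainties(),
                     a = 1, b = 0.5, d = 2) {
  stopifnot(is.data.frame(features), nrow(features) == length(labels))
  missing_cols <- setdiff(feature_order, names(features))
  if (length(missing_cols))
    stop(sprintf("features lack columns: %s", paste(missing_cols, collapse = ", ")))
  missing_u <- setdiff(feature_order, names(u_expanded))
  if (length(missing_u))
    stop(sprintf("no expanded uncertainty for: %s", paste(missing_u, collapse = ", ")))
  lv <- if (is.factor(labels)) levels(droplevels(labels)) else unique(as.character(labels))
  labels <- as.character(labels)
  if (length(lv) < 2) stop("training requires at least two classes")
  classes <- lapply(lv, function(cl) {
    rows <- which(labels == cl)
    if (!length(rows)) stop(sprintf("class '%s' has no training objects", cl))
    dims <- lapply(feature_order, function(f) {
      x <- features[[f]][rows]
      x0 <- mean(x)
      membership_params(x0 = x0, a = a, b_l = b, b_r = b,
                        c_l = (x0 - min(x)) + u_expanded[[f]],
                        c_r = (max(x) - x0) + u_expanded[[f]],
                        d_l = d, d_r = d)
    })
    names(dims) <- feature_order
    list(label = cl, n_objects = length(rows), dims = dims)
  })
  names(classes) <- lv
  structure(list(feature_order = feature_order, classes = classes,
                 aggregation = "mean"),
            class = "fuzzy_classifier")
}

#' @export
print.fuzzy_classifier <- function(x, ...) {
  cat(sprintf("<fuzzy_classifier> %d classes x %d dimensions (%s aggregation)\n",
              length(x$classes), length(x$feature_order), x$aggregation))
  for (cl in x$classes)
    cat(sprintf("  %-24s n=%d\n", cl$label, cl$n_objects))
  invisible(x)
}

#' Classify feature vectors
#'
#' Evaluates every class membership (per-dimension Aizerman memberships
#' aggregated by the classifier's rule) and assigns each sample to the
#' class with the highest membership. Exact ties resolve toward the class
#' listed first and are reported in the `tie` column.
#'
#' @param clf A [ft_train()] classifier.
#' @param newdata Data frame containing the classifier's feature columns.
#' @return Data frame with one row per sample: the per-class memberships
#'   (`mu_<label>`), `assigned`, and `tie`.
#' @export
ft_classify <- function(clf, newdata) {
  stopifnot(inherits(clf, "fuzzy_classifier"), is.data.frame(newdata))
  missing_cols <- setdiff(clf$feature_order, names(newdata))
  if (length(missing_cols))
    stop(sprintf("feature vector lacks dimensions: %s",
                 paste(missing_cols, collapse = ", ")))
  n <- nrow(newdata)
  labels <- vapply(clf$classes, `[[`, "", "label")
  mu <- matrix(NA_real_, nrow = n, ncol = length(labels),
               dimnames = list(NULL, labels))
  for (j in seq_along(clf$classes)) {
    cl <- clf$classes[[j]]
    per_dim <- vapply(clf$feature_order, function(f)
      aizerman_membership(newdata[[f]], cl$dims[[f]]), numeric(n))
    per_dim <- matrix(per_dim, nrow = n)
    mu[, j] <- apply(per_dim, 1L, aggregate_memberships)
  }
  best <- apply(mu, 1L, which.max)   # first maximum -> earlier class on ties
  tie <- vapply(seq_len(n), function(i)
    sum(abs(mu[i, ] - mu[i, best[i]]) < 1e-12) > 1L, logical(1))
  out <- as.data.frame(mu)
  names(out) <- paste0("mu_", labels)
  out$assigned <- labels[best]
  out$tie <- tie
  out
}

#' Save / load a fuzzy classifier as JSON
#'
#' The model file stores the feature order, aggregation rule, and per
#' class the label and the full per-dimension parameter set. The round
#' trip preserves parameters to full double precision.
#'
#' @param clf A [ft_train()] classifier.
#' @param path JSON file path.
#' @export
save_model <- function(clf, path) {
  stopifnot(inherits(clf, "fuzzy_classifier"))
  obj <- list(
    format = "aquaspec_fuzzy_classifier",
    version = 1L,
    feature_order = clf$feature_order,
    aggregation = clf$aggregation,
    classes = lapply(unname(clf$classes), function(cl) list(
      label = cl$label, n_objects = cl$n_objects,
      dims = lapply(cl$dims, unclass))))
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the `fuzzy_classifier`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "aquaspec_fuzzy_classifier"))
    stop("not an aquaspec fuzzy classifier model file")
  feature_order <- unlist(obj$feature_order)
  classes <- lapply(obj$classes, function(cl) {
    if (is.null(cl$dims) || !all(feature_order %in% names(cl$dims)))
      stop(sprintf("model file: class '%s' is missing dimension parameters",
                   if (is.null(cl$label)) "?" else cl$label))
    dims <- lapply(cl$dims[feature_order], function(p)
      membership_params(x0 = p$x0, a = p$a, b_l = p$b_l, b_r = p$b_r,
                        c_l = p$c_l, c_r = p$c_r, d_l = p$d_l, d_r = p$d_r))
    list(label = cl$label, n_objects = cl$n_objects, dims = dims)
  })
  names(classes) <- vapply(classes, `[[`, "", "label")
  structure(list(feature_order = feature_order, classes = classes,
                 aggregation = obj$aggregation),
            class = "fuzzy_classifier")
}
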