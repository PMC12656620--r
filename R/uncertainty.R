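#' Combine standard uncertainties
#'
#' Root-sum-of-squares combination of independent standard uncertainty
#' components, the first-order law of propagation for uncorrelated inputs
#' with unit sensitivity coefficients.
#'
#' @param components Numeric vector of standard uncertainties (>= 0); may
#'   be empty.
#' @return Combined standard uncertainty.
#' @export
combine_uncertainty <- function(components) {
  components <- as.numeric(components)
  if (any(components < 0)) stop("standard uncertainties must be non-negative")
  sqrt(sum(components^2))
}

#' Expand a combined uncertainty
#'
#' `U = k_cov * u_c`. The conventional coverage factor `k_cov = 2`
#' corresponds to approximately 95% coverage for a normal distribution.
#'
#' @param u_c Combined standard uncertainty (>= 0).
#' @param k_cov Coverage factor (> 0).
#' @return Expanded uncertainty `U`.
#' @export
expand_uncertainty <- function(u_c, k_cov = 2) {
  if (u_c < 0) stop("combined uncertainty must be non-negative")
  if (k_cov <= 0) stop("coverage factor must be positive")
  k_cov * u_c
}

#' Uncertainty budget
#'
#' Named standard-uncertainty components with their combination and
#' expansion, in the units of the feature they describe.
#'
#' @param components Named numeric vector of standard uncertainties.
#' @param k_cov Coverage factor.
#' @return Object of class `uncertainty_budget` with fields `components`,
#'   `k_cov`, `u_c`, `U`.
#' @export
uncertainty_budget <- function(components, k_cov = 2) {
  u_c <- combine_uncertainty(components)
  structure(list(components = components, k_cov = k_cov,
                 u_c = u_c, U = expand_uncertainty(u_c, k_cov)),
            class = "uncertainty_budget")
}

#' Default expanded uncertainty of the conformity features
#'
#' The expanded uncertainty of the R^2 features, on the R^2 scale, as
#' determined for this measurement system: 0.0590 for UV/Vis and 0.0711
#' for the fluorescence and scattered-light channels. These set the scope
#' parameter `c` of the fuzzy membership functions.
#'
#' @param modality One of [MODALITIES].
#' @param overrides Optional named numeric vector replacing the defaults.
#' @return Expanded uncertainty as a fraction of the R^2 scale.
#' @export
default_feature_uncertainty <- function(modality, overrides = NULL) {
  defaults <- c(uvvis = 0.0590, fl440 = 0.0711, fl590 = 0.0711, sc850 = 0.0711)
  if (!is.null(overrides)) defaults[names(overrides)] <- overrides
  if (!modality %in% names(defaults))
    stop(sprintf("unknown modality '%s'", modality))
  unname(defaults[[modality]])
}

#' Default expanded uncertainties per feature column
#'
#' Maps the feature columns produced by [extract_features()] to expanded
#' uncertainties: the UV/Vis value for `r2_uvvis`, the fluorescence /
#' scattered-light value for the emission channels and for the normalized
#' turbidity feature (which derives from the scattered-light channel).
#'
#' @param overrides Optional named numeric vector of replacements keyed by
#'   feature name.
#' @return Named numeric vector over
#'   `c("r2_440", "r2_590", "r2_850", "r2_uvvis", "turb")`.
#' @export
default_feature_uncertainties <- function(overrides = NULL) {
  u <- c(r2_440 = default_feature_uncertainty("fl440"),
         r2_590 = default_feature_uncertainty("fl590"),
         r2_850 = default_feature_uncertainty("sc850"),
         r2_uvvis = default_feature_uncertainty("uvvis"),
         turb = default_feature_uncertainty("sc850"))
  if (!is.null(overrides)) u[names(overrides)] <- overrides
  u
}
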