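#' The domain-specific feature catalogue
#'
#' The catalogue is the machine-readable list that fixes the names, families
#' and order of the domain-specific radiomics features. The default
#' catalogue shipped with the package enumerates the standard set:
#' 14 shape + 18 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM +
#' 5 NGTDM = 107 features. Entries can be disabled (or a trimmed JSON file
#' supplied) to match any alternative published feature list.
#'
#' @param path optional path to a catalogue JSON file; default is the
#'   catalogue shipped in `inst/extdata/feature_catalogue.json`.
#' @return data.frame with columns `family`, `name`, `enabled`, plus a
#'   `catalogue_id` attribute.
#' @export
feature_catalogue <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "feature_catalogue.json", package = "hybridpCR")
  cat_json <- jsonlite::fromJSON(path)
  df <- as.data.frame(cat_json$features)
  if (is.null(df$enabled)) df$enabled <- TRUE
  attr(df, "catalogue_id") <- cat_json$catalogue_id
  df
}

#' Extract the full domain-specific feature vector
#'
#' Runs every enabled feature family (shape, first-order, GLCM, GLRLM,
#' GLSZM, GLDM, NGTDM) on a volume/mask pair and concatenates the results
#' in canonical catalogue order. Non-finite values (possible only through a
#' disabled degenerate-value convention or pathological input) are replaced
#' by 0 with a warning.
#'
#' @param vol an `image_volume` (intensities expected in `[0, 1]`).
#' @param mask the paired non-empty `roi_mask`.
#' @param n_bins gray levels for discretisation (default 32).
#' @param catalogue a catalogue data.frame from [feature_catalogue()].
#' @return named numeric vector in catalogue order, with attributes
#'   `catalogue_id` and `families`.
#' @export
extract_domain_vector <- function(vol, mask, n_bins = 32L,
                                  catalogue = feature_catalogue()) {
  check_roi_nonempty(mask)
  q <- discretize(vol, mask, n_bins = n_bins)
  fams <- list(
    shape = function() shape_features(mask),
    firstorder = function() first_order_features(vol, mask, n_bins = n_bins),
    glcm = function() glcm_features(q),
    glrlm = function() glrlm_features(q),
    glszm = function() glszm_features(q),
    gldm = function() gldm_features(q),
    ngtdm = function() ngtdm_features(q)
  )
  enabled <- catalogue[catalogue$enabled, , drop = FALSE]
  need <- unique(enabled$family)
  computed <- lapply(fams[need], function(f) f())
  out <- numeric(nrow(enabled))
  names(out) <- paste(enabled$family, enabled$name, sep = "_")
  for (k in seq_len(nrow(enabled))) {
    fam <- enabled$family[k]
    val <- computed[[fam]][[enabled$name[k]]]
    if (is.null(val))
      stop_hybridpcr(paste("catalogue names unknown feature:", names(out)[k]),
                     "hybridpcr_parameter_error")
    out[k] <- val
  }
  bad <- !is.finite(out)
  if (any(bad)) {
    warning(sprintf("replacing %d non-finite feature value(s) by 0: %s",
                    sum(bad), paste(names(out)[bad], collapse = ", ")))
    out[bad] <- 0
  }
  attr(out, "catalogue_id") <- attr(catalogue, "catalogue_id")
  attr(out, "families") <- enabled$family
  out
}
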