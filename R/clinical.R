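# Clinical parameters: encoding and cohort chi-square comparisons.

clinical_levels <- list(
  figo_stage = c("IB", "IIA-IIB", "IIIA-IIIC1"),
  path_type = c("squamous", "adeno", "other"),
  scc_level = c("<1.5", "1.5-5", ">5", "unclear"),
  lymph_node = c("negative", "positive"),
  pcr_label = c("non-pCR", "pCR")
)

#' Encode the five clinical parameters as numeric features
#'
#' Fixed, documented mapping producing one numeric value per parameter, so
#' that the clinical block always contributes exactly 5 dimensions
#' (109 + 5 = 114 for the domain vector, 90 + 5 = 95 for the abstract
#' vector): age is linearly scaled over the plausible cohort range
#' `[25, 65]` years; FIGO stage is the ordinal code IB = 0, IIA-IIB = 1,
#' IIIA-IIIC1 = 2; pathological type squamous = 0, adeno = 1, other = 2;
#' SCC antigen band `<1.5` = 0, `1.5-5` = 1, `>5` = 2 with "unclear" a
#' dedicated code 3 (never imputed); lymph-node status negative = 0,
#' positive = 1.
#'
#' @param age age in years.
#' @param figo_stage one of `"IB"`, `"IIA-IIB"`, `"IIIA-IIIC1"`.
#' @param path_type one of `"squamous"`, `"adeno"`, `"other"`.
#' @param scc_level one of `"<1.5"`, `"1.5-5"`, `">5"`, `"unclear"` (ng/mL bands).
#' @param lymph_node `"negative"` or `"positive"`.
#' @param age_range scaling range for age (default `c(25, 65)`).
#' @return named numeric vector of length 5.
#' @export
encode_clinical <- function(age, figo_stage, path_type, scc_level, lymph_node,
                            age_range = c(25, 65)) {
  code <- function(value, var) {
    m <- match(value, clinical_levels[[var]])
    if (is.na(m))
      stop_hybridpcr(sprintf("unknown %s category: '%s'", var, value),
                     "hybridpcr_encoding_error")
    m - 1
  }
  c(age = (age - age_range[1]) / (age_range[2] - age_range[1]),
    figo_stage = code(figo_stage, "figo_stage"),
    path_type = code(path_type, "path_type"),
    scc_level = code(scc_level, "scc_level"),
    lymph_node = code(lymph_node, "lymph_node"))
}

#' Encode a clinical table into the 5-column numeric matrix
#'
#' @param records data.frame with columns `age`, `figo_stage`, `path_type`,
#'   `scc_level`, `lymph_node` (e.g. from [read_clinical_csv()]).
#' @inheritParams encode_clinical
#' @return numeric matrix, one row per record, 5 named columns.
#' @export
encode_clinical_table <- function(records, age_range = c(25, 65)) {
  t(mapply(encode_clinical, records$age, records$figo_stage,
           records$path_type, records$scc_level, records$lymph_node,
           MoreArgs = list(age_range = age_range)))
}

#' Read and validate a clinical CSV
#'
#' Requires the columns `patient_id`, `age`, `figo_stage`, `path_type`,
#' `scc_level`, `lymph_node`, `pcr_label`; extra columns (for example
#' `tumor_diameter` or `rt_tech`) are kept and used only by the cohort
#' statistics report. Categorical values are validated against their
#' documented level sets.
#'
#' @param path CSV path.
#' @return data.frame with `pcr_label` as a factor with levels
#'   `("non-pCR", "pCR")`.
#' @export
read_clinical_csv <- function(path) {
  req <- c("patient_id", "age", "figo_stage", "path_type", "scc_level",
           "lymph_node", "pcr_label")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop_hybridpcr(paste("clinical CSV is missing columns:",
                         paste(missing_cols, collapse = ", ")),
                   "hybridpcr_io_error")
  for (var in c("figo_stage", "path_type", "scc_level", "lymph_node", "pcr_label")) {
    bad <- setdiff(unique(df[[var]]), clinical_levels[[var]])
    if (length(bad))
      stop_hybridpcr(sprintf("unknown %s value(s): %s", var,
                             paste(bad, collapse = ", ")),
                     "hybridpcr_encoding_error")
  }
  df$pcr_label <- factor(df$pcr_label, levels = clinical_levels$pcr_label)
  df
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Plain Pearson chi-square without continuity correction:
#' `X^2 = sum (O - E)^2 / E` with expectations from the marginal products,
#' `df = (r - 1)(c - 1)`, and the p-value from the upper chi-square tail.
#' Rows or columns with zero marginals are dropped with a warning before
#' testing.
#'
#' @param counts matrix of nonnegative counts (at least 2 x 2 after
#'   dropping empty margins).
#' @return list with `statistic`, `df`, `p_value`, and the `expected` table.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop_hybridpcr("counts must be finite and nonnegative", "hybridpcr_parameter_error")
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-marginal rows/columns before the chi-square test")
    counts <- counts[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop_hybridpcr("need at least 2 rows and 2 columns with nonzero marginals",
                   "hybridpcr_parameter_error")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected)
}

#' Cohort comparison report for a clinical table
#'
#' Cross-tabulates each categorical variable against the pCR label and runs
#' the uncorrected Pearson chi-square test, reproducing the style of a
#' baseline-characteristics table.
#'
#' @param records clinical data.frame (see [read_clinical_csv()]).
#' @param variables categorical columns to test (default: every documented
#'   categorical plus any extra character column present).
#' @return data.frame with one row per variable: `variable`, `statistic`,
#'   `df`, `p_value`.
#' @export
clinical_cohort_stats <- function(records, variables = NULL) {
  if (is.null(variables)) {
    cand <- c("tumor_diameter", "lymph_node", "figo_stage", "rt_tech",
              "path_type", "scc_level")
    variables <- intersect(cand, names(records))
  }
  rows <- lapply(variables, function(v) {
    tab <- table(records[[v]], records$pcr_label)
    res <- tryCatch(chi_square_independence(tab), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(variable = v, statistic = res$statistic, df = res$df,
               p_value = res$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
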