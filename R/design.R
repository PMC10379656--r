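#' Build the covariate design block
#'
#' Encodes the analysis covariates in a fixed, deterministic order: age
#' (numeric, years), gender (0/1), and four indicator columns for clinical
#' diagnostic status with CN as the reference level (SMC, EMCI, LMCI, AD).
#' The intercept is added by the model-fitting functions, so this block has
#' six columns; with intercept, two SNP main effects and their product the
#' full interaction model has ten.
#'
#' @param cohort Cohort tibble with complete `age`, `gender`, `cds`.
#' @return A numeric matrix `n x 6` with column names
#'   `age, gender, cdsSMC, cdsEMCI, cdsLMCI, cdsAD`.
#' @export
build_design <- function(cohort) {
  required <- c("age", "gender", "cds")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort lacks covariate column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(cohort[required])) abort("covariates must be complete (run subject QC first)")
  unseen <- setdiff(unique(cohort$cds), CDS_LEVELS)
  if (length(unseen) > 0) {
    abort(paste0("unknown cds level(s): ", paste(unseen, collapse = ", ")))
  }
  X <- cbind(
    age = as.numeric(cohort$age),
    gender = as.numeric(cohort$gender),
    cdsSMC = as.numeric(cohort$cds == "SMC"),
    cdsEMCI = as.numeric(cohort$cds == "EMCI"),
    cdsLMCI = as.numeric(cohort$cds == "LMCI"),
    cdsAD = as.numeric(cohort$cds == "AD")
  )
  constant <- apply(X[, c("age", "gender"), drop = FALSE], 2, function(v) {
    length(unique(v)) == 1L
  })
  if (any(constant)) {
    warn(paste0(
      "covariate column(s) constant and collinear with the intercept: ",
      paste(names(constant)[constant], collapse = ", ")
    ))
  }
  X
}
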