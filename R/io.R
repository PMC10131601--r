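#' Load an ED diagnosis-probability table
#'
#' Reads a table mapping ED diagnosis codes to probabilities that the visit
#' was emergent, non-emergent, or other (rows sum to 1), in the style of
#' published probabilistic ED-visit classification schemes. With no `path`,
#' the synthetic table shipped with the package is loaded; users may supply
#' a real table in the same format (CSV with columns `diag_code`,
#' `p_emergent`, `p_nonemergent`, `p_other`).
#'
#' @param path Optional path to a CSV in the documented format.
#' @return A validated tibble.
#' @export
ed_probability_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ed_probability_table_synthetic.csv",
                        package = "pupmatch", mustWork = TRUE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("diag_code", "p_emergent", "p_nonemergent", "p_other")
  check_that(all(need %in% names(tab)),
             paste0("ED table must have columns ", paste(need, collapse = ", ")))
  probs <- as.matrix(tab[, c("p_emergent", "p_nonemergent", "p_other")])
  check_that(all(probs >= 0 & probs <= 1), "ED table probabilities must be in [0, 1]")
  check_that(all(abs(rowSums(probs) - 1) < 1e-6), "ED table rows must sum to 1")
  check_that(!anyDuplicated(tab$diag_code), "ED table diagnosis codes must be unique")
  tab
}

#' Write a synthetic cohort to delimited files
#'
#' Writes `members.csv` and `claims.csv` (UTF-8, comma-separated, header
#' row; currency in integer cents in claims) under `dir`.
#'
#' @param members,claims Tibbles from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(members, claims, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(members, file.path(dir, "members.csv"), progress = FALSE)
  readr::write_csv(claims, file.path(dir, "claims.csv"), progress = FALSE)
  invisible(dir)
}

#' Read a member roster written by [write_cohort()]
#' @param path Path to `members.csv`.
#' @return A member tibble.
#' @export
read_members <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      member_id = readr::col_character(),
      age = readr::col_integer(),
      sex = readr::col_character(),
      pharmacy_data_available = readr::col_logical(),
      comm_receptivity = readr::col_logical(),
      care_management = readr::col_logical(),
      member_advocacy = readr::col_logical(),
      chronic_count = readr::col_integer(),
      risk_score = readr::col_double(),
      enrolled = readr::col_logical(),
      enroll_month = readr::col_integer(),
      eligibility_start = readr::col_integer(),
      eligibility_end = readr::col_integer(),
      .default = readr::col_character()
    ))
}

#' Read a claim-line table written by [write_cohort()]
#' @param path Path to `claims.csv`.
#' @return A claims tibble (amounts in integer cents).
#' @export
read_claims <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      member_id = readr::col_character(),
      month = readr::col_integer(),
      category = readr::col_character(),
      amount_cents = readr::col_double(),
      nonimpactable = readr::col_logical(),
      pregnancy_related = readr::col_logical(),
      ed_diag_code = readr::col_character()
    ))
}
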