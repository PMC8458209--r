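#' Read a cohort CSV
#'
#' Cohort files are UTF-8, comma-separated, "." decimal, one header row,
#' angles in decimal degrees; lines starting with `#` (the provenance
#' header written by [write_cohort_csv()]) are skipped. The minimal column
#' set is `id,mFTA,mMPTA,mLDFA,JLCA,WBL_ratio`; appended classification or
#' plan columns are passed through.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "mFTA", "mMPTA", "mLDFA")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cohort CSV `", path, "` lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in intersect(c("mFTA", "mMPTA", "mLDFA", "JLCA", "WBL_ratio"),
                        names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "NA")
    if (length(bad))
      stop("cohort CSV `", path, "`: non-numeric `", col, "` on data line ",
           bad[1], call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' Write a cohort (or any result) CSV with a provenance header
#'
#' Prepends `#`-comment lines recording the package version and, when
#' given, scenario and seed, so every artifact is self-describing.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param scenario optional [scenario_limits()] recorded in the header.
#' @param seed optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(df, path, scenario = NULL, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("osteoplanr"))
  writeLines(sprintf("# osteoplanr %s", ver), con)
  if (!is.null(scenario))
    writeLines(sprintf("# scenario: %s (mMPTA <= %g, mLDFA >= %g, target mFTA %g)",
                       scenario$name, scenario$mMPTA_upper,
                       scenario$mLDFA_lower, scenario$target_mFTA), con)
  if (!is.null(seed))
    writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario configuration JSON
#'
#' Accepts `{"mmpta_upper": 90, "mldfa_lower": 85, "target_mfta_varus": -2}`
#' (case-insensitive keys; each optional with the anatomic default).
#'
#' @param path file path.
#' @return A [scenario_limits()].
#' @export
read_scenario_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  names(obj) <- tolower(names(obj))
  scenario_limits(
    mMPTA_upper = if (!is.null(obj$mmpta_upper)) obj$mmpta_upper else 90,
    mLDFA_lower = if (!is.null(obj$mldfa_lower)) obj$mldfa_lower else 85,
    target_mFTA = if (!is.null(obj$target_mfta_varus)) obj$target_mfta_varus
                  else -2)
}
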