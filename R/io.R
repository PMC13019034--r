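# Delimited-text readers and writers for patient tables and noise logs.

#' Read a patient table
#'
#' Expects a delimited text file with header columns `patient_id`, `lden_db`,
#' `wnss`, `comfort`, `annoyance_vas`, `itl_vas`; optional extra columns
#' (e.g. demographics) are kept.
#'
#' @param path Path to the file.
#' @param sep Field separator (default comma).
#' @return A data frame.
#' @export
read_patient_table <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("patient_id", unname(.study_cols))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("patient table lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write a patient table
#'
#' @param df Data frame of patients.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a noise-measurement log
#'
#' Expects header columns `location_id`, `start`, `end` ("HH:MM" clock
#' times) and `leq_db` (interval Leq in dB).
#'
#' @inheritParams read_patient_table
#' @return A data frame.
#' @export
#' @examples
#' log <- read_noise_log(system.file("extdata", "example_noise_log.csv",
#'                                   package = "noisebn"))
#' lden_by_location(log)
read_noise_log <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("location_id", "start", "end", "leq_db")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_input("noise log lacks column(s): ", paste(miss, collapse = ", "))
  df$leq_db <- as.numeric(df$leq_db)
  if (anyNA(df$leq_db)) stop_input("non-numeric leq_db value in noise log")
  df
}

#' Write a noise-measurement log
#'
#' Levels are written rounded to 2 decimals.
#'
#' @param df Noise-log data frame.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_noise_log <- function(df, path, sep = ",") {
  df$leq_db <- round(df$leq_db, 2)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
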