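# NONMEM-style dataset reading and writing. The interchange dialect is a
# comma-separated file with header ID, TIME, AMT, DV, EVID (case-insensitive,
# any order, extra covariate columns such as SEX preserved); dose rows have
# EVID = 1 and AMT > 0, observation rows have EVID = 0 and a numeric DV.
# "." marks a missing DV on dose rows. Units are fixed: h and ng/mL.

.required_cols <- c("ID", "TIME", "AMT", "DV", "EVID")

validate_dataset <- function(ds) {
  for (col in c("ID", "TIME", "AMT", "EVID")) {
    if (any(!is.finite(ds[[col]]))) {
      stop("dataset: non-numeric or missing ", col, " at row ",
           which(!is.finite(ds[[col]]))[1], call. = FALSE)
    }
  }
  if (!all(ds$EVID %in% c(0L, 1L))) {
    stop("dataset: EVID must be 0 (observation) or 1 (dose); offending row ",
         which(!ds$EVID %in% c(0L, 1L))[1], call. = FALSE)
  }
  bad_dose <- ds$EVID == 1L & ds$AMT <= 0
  if (any(bad_dose)) {
    stop("dataset: dose row with AMT <= 0 at row ", which(bad_dose)[1],
         call. = FALSE)
  }
  bad_obs <- ds$EVID == 0L & !is.finite(ds$DV)
  if (any(bad_obs)) {
    stop("dataset: observation row with non-numeric DV at row ",
         which(bad_obs)[1], call. = FALSE)
  }
  no_dose <- setdiff(unique(ds$ID), unique(ds$ID[ds$EVID == 1L]))
  if (length(no_dose)) {
    stop("dataset: subject(s) without any dose event: ",
         paste(no_dose, collapse = ", "), call. = FALSE)
  }
  invisible(ds)
}

#' Read a NONMEM-style dataset
#'
#' @param path Path to a CSV file with (case-insensitive) columns ID, TIME,
#'   AMT, DV, EVID; extra columns are kept. Lines starting with `#` are
#'   treated as comments. `.` denotes a missing DV.
#' @return A validated `pk_dataset` data.frame.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("read_dataset: file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  names(raw) <- toupper(names(raw))
  missing <- setdiff(.required_cols, names(raw))
  if (length(missing)) {
    stop("read_dataset: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw$DV[raw$DV == "."] <- NA
  for (col in c("ID", "TIME", "AMT", "DV", "EVID")) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  raw$ID <- as.integer(raw$ID)
  raw$EVID <- as.integer(raw$EVID)
  validate_dataset(raw)
  structure(raw, class = c("pk_dataset", "data.frame"))
}

#' Write a NONMEM-style dataset
#'
#' Writes the dataset as CSV with `.` for missing DV values and an optional
#' leading comment line carrying run metadata (e.g. the config hash).
#'
#' @param dataset A `pk_dataset` data.frame.
#' @param path Output file path.
#' @param header_comment Optional single-line comment written first,
#'   prefixed with `#`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, header_comment = NULL) {
  validate_dataset(dataset)
  out <- as.data.frame(dataset)
  out$DV <- ifelse(is.na(out$DV), ".", format(out$DV, digits = 15, trim = TRUE,
                                              scientific = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pk_dataset <- function(x, ...) {
  nobs <- sum(x$EVID == 0L)
  cat(sprintf("PK dataset: %d subjects, %d observation rows, %d dose rows\n",
              length(unique(x$ID)), nobs, sum(x$EVID == 1L)))
  NextMethod()
}
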