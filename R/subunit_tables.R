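#' Read a per-subunit glycine Hill-parameter study table
#'
#' Delimited text with columns `study`, `subunit`, `ec50_uM`,
#' `hill_slope`; blank cells are missing values (some studies did not
#' characterise NR2D). Subunits must be among NR2A, NR2B, NR2C, NR2D.
#'
#' @param path Path to a tab-delimited file.
#' @return A data frame of class `subunit_study_table`.
#' @export
read_subunit_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  as_subunit_study_table(x)
}

#' Validate a subunit study table
#'
#' @param x A data frame with columns `study`, `subunit`, `ec50_uM`,
#'   `hill_slope`.
#' @return `x` with class `subunit_study_table` prepended.
#' @export
as_subunit_study_table <- function(x) {
  need <- c("study", "subunit", "ec50_uM", "hill_slope")
  if (!all(need %in% names(x))) {
    stop("subunit table needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(x$subunit), c("NR2A", "NR2B", "NR2C", "NR2D"))
  if (length(bad)) stop("unknown subunit(s): ", paste(bad, collapse = ", "))
  if (any(x$ec50_uM <= 0, na.rm = TRUE)) stop("ec50_uM must be > 0")
  if (any(x$hill_slope <= 0, na.rm = TRUE)) stop("hill_slope must be > 0")
  class(x) <- unique(c("subunit_study_table", class(x)))
  x
}

#' Write a subunit study table as tab-delimited text
#'
#' @param x A subunit study table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subunit_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Experimentally reported glycine EC50 and Hill slopes per NR2 subunit
#'
#' The bundled transcription of published patch-clamp determinations of
#' glycine co-agonist site EC50 (uM) and Hill slope for recombinant
#' NR2A-NR2D receptors across five studies (one study lacks NR2D data).
#'
#' @return A `subunit_study_table` data frame.
#' @examples
#' subunit_averages(nr2_hill_studies())
#' @export
nr2_hill_studies <- function() {
  read_subunit_table(system.file("extdata", "nr2_glycine_hill_studies.tsv",
                                 package = "glyqsp", mustWork = TRUE))
}

#' Per-subunit mean EC50 and Hill slope
#'
#' Arithmetic means over the non-missing entries for each requested
#' subunit. A subunit with no data for a requested field is an error,
#' not a zero.
#'
#' @param t A `subunit_study_table` (see [read_subunit_table]).
#' @param subunits Subunits to average (default: all present).
#' @return A data frame with columns `subunit`, `ec50_uM`,
#'   `hill_slope`, `n_ec50`, `n_slope`.
#' @export
subunit_averages <- function(t, subunits = unique(t$subunit)) {
  t <- as_subunit_study_table(t)
  rows <- lapply(subunits, function(s) {
    sub <- t[t$subunit == s, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no records for subunit ", s)
    e <- sub$ec50_uM[!is.na(sub$ec50_uM)]
    h <- sub$hill_slope[!is.na(sub$hill_slope)]
    if (length(e) == 0L) stop("no EC50 data for subunit ", s)
    if (length(h) == 0L) stop("no Hill-slope data for subunit ", s)
    data.frame(subunit = s, ec50_uM = mean(e), hill_slope = mean(h),
               n_ec50 = length(e), n_slope = length(h))
  })
  do.call(rbind, rows)
}

#' Construct a dose-response curve record
#'
#' @param glycine_uM Strictly increasing glycine grid (uM).
#' @param response Response values, same length.
#' @param what What the response is: one of `"ratio"`,
#'   `"network_outcome"`, `"panss_proxy"`.
#' @return A data frame of class `dose_response_curve` with attribute
#'   `what`.
#' @export
dose_response_curve <- function(glycine_uM, response,
                                what = c("ratio", "network_outcome",
                                         "panss_proxy")) {
  what <- match.arg(what)
  stopifnot(length(glycine_uM) == length(response))
  if (any(diff(glycine_uM) <= 0)) {
    stop("glycine grid must be strictly increasing")
  }
  structure(data.frame(glycine_uM = glycine_uM, response = response),
            what = what,
            class = c("dose_response_curve", "data.frame"))
}

#' Write a dose-response curve with a JSON metadata sidecar
#'
#' The curve goes to `<path>` as tab-delimited text
#' (`glycine_uM`, `response`); metadata (response type, point count)
#' goes to `<path>.json`.
#'
#' @param curve A [dose_response_curve].
#' @param path Output path for the delimited curve.
#' @return `path`, invisibly.
#' @export
write_dose_response <- function(curve, path) {
  stopifnot(inherits(curve, "dose_response_curve"))
  utils::write.table(curve, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  meta <- list(what = attr(curve, "what"), n = nrow(curve),
               glycine_range_uM = range(curve$glycine_uM))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a dose-response curve written by [write_dose_response]
#'
#' @param path Path to the delimited curve (the `.json` sidecar is read
#'   if present).
#' @return A [dose_response_curve].
#' @export
read_dose_response <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  what <- "network_outcome"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    what <- jsonlite::read_json(sidecar)$what
  }
  dose_response_curve(x$glycine_uM, x$response, what = what)
}
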