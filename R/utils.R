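#' Round half-up to a fixed number of decimals
#'
#' Printed survey tables round 5s upward (30.75 -> 30.8), whereas base R's
#' [round()] rounds half-to-even. All reported proportions and means in this
#' package go through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Normalise a resource name
#'
#' Case-folds, collapses internal whitespace, and strips trailing version
#' tokens (a final token like "2.0", "v2", "version 10.1"). Used for the
#' dictionary variant index and for cohort grouping during document-level
#' score adjustment, so that "ClustalW 2.0" and "clustalw" key together.
#'
#' @param x character vector of surface forms.
#' @return character vector of normalised forms.
#' @export
normalise_name <- function(x) {
  x <- tolower(x)
  x <- stringr::str_squish(x)
  # strip trailing "version 2.0" / "v2" / "2.0.1" tokens (word-separated only)
  x <- stringr::str_remove(x, "\\s+(version\\s+)?v?[0-9]+(\\.[0-9]+)*$")
  stringr::str_squish(x)
}

#' Normalised Levenshtein distance between two strings
#'
#' Edit distance divided by the length of the longer string; used by the
#' acronym long-form check with a tolerance ratio.
#'
#' @param a,b single strings.
#' @return number in \[0, 1\].
#' @keywords internal
norm_edit_distance <- function(a, b) {
  a <- tolower(stringr::str_squish(a))
  b <- tolower(stringr::str_squish(b))
  n <- max(nchar(a), nchar(b))
  if (n == 0L) return(0)
  as.numeric(utils::adist(a, b)) / n
}

# 0-based half-open span -> substring of body
span_text <- function(body, start, end) {
  substring(body, start + 1L, end)
}
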