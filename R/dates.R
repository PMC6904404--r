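# Permissive calendar-date handling for registry and citation exports, which
# mix granularities: "May 15, 2016", "May 2016", "2016", "2016-05-15".
# Partial dates are floored ("Month YYYY" -> first of month, "YYYY" ->
# January 1) so that every record has a total order for time-range filters.

.MONTHS <- c("January", "February", "March", "April", "May", "June", "July",
             "August", "September", "October", "November", "December")

#' Parse a registry-style date permissively
#'
#' @param x character vector of date strings (or NA).
#' @return a `Date` vector; unparseable or missing input yields `NA`.
#' @export
parse_flex_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  if (length(x) == 0L) return(out)
  x <- trimws(as.character(x))
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s) || s == "") next
    if (grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", s)) {
      out[i] <- as.Date(s)
    } else if (grepl("^[A-Za-z]+ [0-9]{1,2}, [0-9]{4}$", s)) {
      m <- match(sub(" .*$", "", s), .MONTHS)
      day <- as.integer(sub("^[A-Za-z]+ ([0-9]{1,2}),.*$", "\\1", s))
      yr <- as.integer(sub("^.*, ", "", s))
      if (!is.na(m)) out[i] <- as.Date(sprintf("%04d-%02d-%02d", yr, m, day))
    } else if (grepl("^[A-Za-z]+ [0-9]{4}$", s)) {
      m <- match(sub(" .*$", "", s), .MONTHS)
      yr <- as.integer(sub("^[A-Za-z]+ ", "", s))
      if (!is.na(m)) out[i] <- as.Date(sprintf("%04d-%02d-01", yr, m))
    } else if (grepl("^[0-9]{4}$", s)) {
      out[i] <- as.Date(sprintf("%s-01-01", s))
    }
  }
  out
}

# Locale-independent "Month D, YYYY" used when emitting trial XML.
format_registry_date <- function(d) {
  ifelse(is.na(d), NA_character_,
         sprintf("%s %d, %d",
                 .MONTHS[as.integer(format(d, "%m"))],
                 as.integer(format(d, "%d")),
                 as.integer(format(d, "%Y"))))
}
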