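#' Parse possibly partial calendar dates
#'
#' Spontaneous-report databases record dates at whatever precision the
#' reporter supplied: a bare year, a year-month, or a full date. Tokens may
#' be compact digit runs (\code{"2020"}, \code{"202003"}, \code{"20200315"})
#' or ISO-8601 (\code{"2020-03"}, \code{"2020-03-15"}). Each token is
#' expanded to the earliest calendar date consistent with it, together with
#' a precision tag, so downstream stages can decide what precision they
#' require (time-to-onset needs day precision; version ordering accepts
#' partial dates).
#'
#' @param x character vector of date tokens; \code{NA} and \code{""} parse
#'   to a missing date with precision \code{"none"}.
#' @return data.frame with columns \code{date} (\code{Date}, earliest
#'   consistent) and \code{precision} (one of \code{"day"}, \code{"month"},
#'   \code{"year"}, \code{"none"}). Unparseable tokens get precision
#'   \code{"none"} and an \code{NA} date.
#' @examples
#' parse_partial_date(c("202003", "2020", "20200315", "2020-02-30"))
#' @export
parse_partial_date <- function(x) {
  x <- trimws(as.character(x))
  n <- length(x)
  date <- rep(as.Date(NA), n)
  precision <- rep("none", n)
  if (n == 0L) {
    return(data.frame(date = date, precision = precision,
                      stringsAsFactors = FALSE))
  }
  tok <- gsub("-", "", x)
  ok_iso <- grepl("^\\d{4}(-\\d{2}(-\\d{2})?)?$", x) | grepl("^\\d{4}(\\d{2}(\\d{2})?)?$", x)
  # strptime returns NA for impossible dates (2020-02-30) instead of erroring
  safe_date <- function(s) as.Date(strptime(s, "%Y-%m-%d", tz = "UTC"))

  is_year <- ok_iso & nchar(tok) == 4L
  is_month <- ok_iso & nchar(tok) == 6L
  is_day <- ok_iso & nchar(tok) == 8L

  if (any(is_year)) {
    d <- safe_date(paste0(tok[is_year], "-01-01"))
    date[is_year] <- d
    precision[is_year][!is.na(d)] <- "year"
  }
  if (any(is_month)) {
    d <- safe_date(paste0(substr(tok[is_month], 1, 4), "-",
                        substr(tok[is_month], 5, 6), "-01"))
    date[is_month] <- d
    precision[is_month][!is.na(d)] <- "month"
  }
  if (any(is_day)) {
    d <- safe_date(paste0(substr(tok[is_day], 1, 4), "-",
                        substr(tok[is_day], 5, 6), "-",
                        substr(tok[is_day], 7, 8)))
    date[is_day] <- d
    precision[is_day][!is.na(d)] <- "day"
  }
  precision[is.na(date)] <- "none"
  data.frame(date = date, precision = precision, stringsAsFactors = FALSE)
}

#' Format a partial date back to its token form
#'
#' Inverse of \code{\link{parse_partial_date}} for the interchange format:
#' a date is rendered at its recorded precision (\code{"2020"},
#' \code{"2020-03"}, \code{"2020-03-15"}); missing dates render as \code{""}.
#'
#' @param date Date vector
#' @param precision character vector of precision tags
#' @return character vector
#' @export
format_partial_date <- function(date, precision) {
  out <- character(length(date))
  keep <- !is.na(date) & precision != "none"
  out[keep & precision == "year"] <- format(date[keep & precision == "year"], "%Y")
  out[keep & precision == "month"] <- format(date[keep & precision == "month"], "%Y-%m")
  out[keep & precision == "day"] <- format(date[keep & precision == "day"], "%Y-%m-%d")
  out
}
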