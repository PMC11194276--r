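#' Biological season of a timestamp
#'
#' Summer is April through September; winter is October through March. A
#' winter spanning the calendar-year boundary is labelled by the year of its
#' October, so January--March 2012 belongs to `winter_2011`.
#'
#' @param time POSIXct or Date vector (or ISO-8601 strings).
#' @return data.frame with `season` ("summer"/"winter"), `year` (season year)
#'   and `season_year` label such as "winter_2011".
#' @export
season_of <- function(time) {
  if (is.character(time)) time <- as.POSIXct(time, tz = "UTC")
  mon <- as.integer(format(time, "%m"))
  yr <- as.integer(format(time, "%Y"))
  summer <- mon >= 4L & mon <= 9L
  season <- ifelse(summer, "summer", "winter")
  year <- ifelse(summer, yr, ifelse(mon >= 10L, yr, yr - 1L))
  data.frame(season = season, year = as.integer(year),
             season_year = paste0(season, "_", year))
}

season_year_label <- function(season, year) paste0(season, "_", year)
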