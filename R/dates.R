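#' Month-resolution date index
#'
#' The whole pipeline works at monthly resolution. A month is encoded as a
#' single integer `year * 12 + (month - 1)` so that arithmetic on months is
#' plain integer arithmetic and differences are months elapsed.
#'
#' @param year calendar year (integer)
#' @param month calendar month 1-12
#' @return integer month index
#' @examples
#' ym(2021, 10) - ym(2021, 8)  # 2 months apart
#' @export
ym <- function(year, month) {
  stopifnot(all(month >= 1 & month <= 12))
  as.integer(year) * 12L + (as.integer(month) - 1L)
}

#' @rdname ym
#' @param x an integer month index
#' @export
ym_year <- function(x) as.integer(x %/% 12L)

#' @rdname ym
#' @export
ym_month <- function(x) as.integer(x %% 12L) + 1L

#' @rdname ym
#' @export
format_ym <- function(x) sprintf("%04d-%02d", ym_year(x), ym_month(x))

#' Season of a month index
#'
#' Dry season is May-October, wet season November-April, following the
#' rainfall regime of western Madagascar dry forest.
#'
#' @param x integer month index (see [ym()])
#' @return character vector, `"dry"` or `"wet"`
#' @export
season_of <- function(x) {
  m <- ym_month(x)
  ifelse(m >= 5 & m <= 10, "dry", "wet")
}

DRY_SEASON_MONTHS <- 5:10
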