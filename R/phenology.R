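#' Convert calendar dates to breeding-season Julian days (1 April = 1)
#'
#' Breeding phenology for spring-breeding cavity nesters is conveniently
#' expressed on a season-relative day scale where 1 April of each year is
#' day 1; 1 May is then day 31. Dates must fall between 1 April and
#' 31 July of their year.
#'
#' @param dates a \code{Date} vector (or something coercible by
#'   \code{as.Date}).
#' @return integer vector of Julian days.
#' @examples
#' toJulian(as.Date(c("2021-04-01", "2021-05-01", "2022-06-30")))
#' @export
toJulian <- function(dates) {
    dates <- as.Date(dates)
    if (anyNA(dates)) stop("dates contain NA or could not be parsed")
    origin <- as.Date(paste0(format(dates, "%Y"), "-04-01"))
    jd <- as.integer(dates - origin) + 1L
    limit <- as.integer(as.Date(paste0(format(dates, "%Y"), "-07-31")) -
                        origin) + 1L
    if (any(jd < 1L | jd > limit))
        stop("dates must fall between 1 April and 31 July; got ",
             paste(format(dates[jd < 1L | jd > limit]), collapse = ", "))
    jd
}

#' Convert 1-April Julian days back to calendar dates
#'
#' @param julian integer days, 1 = 1 April.
#' @param year calendar year (recycled).
#' @return \code{Date} vector.
#' @export
fromJulian <- function(julian, year) {
    as.Date(paste0(year, "-04-01")) + (as.integer(julian) - 1L)
}

#' Breeding period of a species from its breeding records
#'
#' The breeding period runs from the earliest first-egg date to the latest
#' hatching date over all of the species' nests, with the span counted
#' inclusively of both endpoint days (so 8 April to 1 July is 85 days).
#' Years are pooled; subset \code{records} first for per-year periods.
#'
#' @param records data.frame of breeding records with columns
#'   \code{species}, \code{first_egg} and \code{hatching} (either
#'   \code{Date}s or 1-April Julian day integers).
#' @param species label selecting the focal species.
#' @return a \linkS4class{BreedingPeriod}.
#' @examples
#' rec <- data.frame(species = "tit",
#'                   first_egg = as.Date(c("2021-04-08", "2021-05-20")),
#'                   hatching  = as.Date(c("2021-05-05", "2021-07-01")))
#' breedingPeriod(rec, "tit")
#' @export
breedingPeriod <- function(records, species) {
    records <- as.data.frame(records)
    rows <- records[records$species == species, , drop = FALSE]
    if (nrow(rows) == 0L)
        stop("no breeding records for species '", species, "'")
    asJulian <- function(x)
        if (inherits(x, "Date") || is.character(x)) toJulian(x) else
            as.integer(x)
    start <- min(asJulian(rows$first_egg))
    end <- max(asJulian(rows$hatching))
    if (end < start)
        stop("latest hatching precedes earliest first egg; check records")
    new("BreedingPeriod", species = as.character(species),
        startJulian = start, endJulian = end,
        lengthDays = end - start + 1L)
}

#' Co-breeding overlap of one species' breeding period with another's
#'
#' The fraction (as a percentage) of the focal species' breeding period
#' during which the other species is also breeding: 100 times the inclusive
#' day count of the period intersection over the focal period length.
#' Asymmetric by construction; a species whose period is nested inside the
#' other's scores 100.
#'
#' @param focal,other \linkS4class{BreedingPeriod} objects.
#' @return percentage in [0, 100], full precision (not truncated).
#' @examples
#' tit <- new("BreedingPeriod", species = "tit", startJulian = 8L,
#'            endJulian = 92L, lengthDays = 85L)
#' fly <- new("BreedingPeriod", species = "flycatcher", startJulian = 43L,
#'            endJulian = 91L, lengthDays = 49L)
#' periodOverlapFraction(tit, fly)   # 49/85 of the tit period
#' periodOverlapFraction(fly, tit)   # 100: flycatcher nested in tit period
#' @export
periodOverlapFraction <- function(focal, other) {
    stopifnot(is(focal, "BreedingPeriod"), is(other, "BreedingPeriod"))
    lo <- max(focal@startJulian, other@startJulian)
    hi <- min(focal@endJulian, other@endJulian)
    shared <- max(0L, hi - lo + 1L)
    100 * shared / focal@lengthDays
}

#' Hatching rate: brood size over clutch size
#'
#' @param brood_size,clutch_size non-negative integer vectors;
#'   \code{clutch_size} must be positive and \code{brood_size} cannot
#'   exceed it.
#' @return proportion(s) in [0, 1].
#' @examples
#' hatchingRate(5, 8)
#' @export
hatchingRate <- function(brood_size, clutch_size) {
    if (any(is.na(brood_size)) || any(is.na(clutch_size)))
        stop("brood_size and clutch_size must be non-missing")
    if (any(clutch_size <= 0)) stop("clutch_size must be positive")
    if (any(brood_size < 0 | brood_size > clutch_size))
        stop("brood_size must lie in [0, clutch_size]")
    brood_size / clutch_size
}
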