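#' Built-in study areas
#'
#' Natural-scale means and standard deviations of the "true" daily PM2.5
#' (ug/m3) and NO2 (ppb) exposures for the three study areas, together with
#' the "moderate" measurement-error SD for each pollutant. The three areas
#' differ mainly in their true-exposure-variance over error-variance ratios:
#' Europe has the lowest ratio for NO2, the two North-American areas have
#' similar, relatively low ratios for both pollutants.
#'
#' @return A data frame with one row per area and columns `area`, `label`,
#'   `mean_pm`, `sd_pm`, `mean_no2`, `sd_no2`, `mod_err_sd_pm`,
#'   `mod_err_sd_no2`.
#' @export
#' @examples
#' study_areas()
study_areas <- function() {
  data.frame(
    area = c("east_na", "europe", "west_na"),
    label = c("Eastern North America", "Europe", "Western North America"),
    mean_pm = c(19.0, 21.1, 18.7),
    sd_pm = c(8.6, 10.9, 8.3),
    mean_no2 = c(20.7, 21.6, 22.4),
    sd_no2 = c(11.6, 8.9, 10.9),
    mod_err_sd_pm = c(5.7, 5.2, 5.6),
    mod_err_sd_no2 = c(7.3, 6.2, 7.3),
    stringsAsFactors = FALSE
  )
}

#' Parameters of one study area
#'
#' @param area one of `"east_na"`, `"europe"`, `"west_na"`.
#' @return A one-row list of area parameters (see [study_areas()]).
#' @export
area_params <- function(area) {
  tab <- study_areas()
  i <- match(area, tab$area)
  if (is.na(i)) {
    stop("unknown area '", area, "'; available: ",
         paste(tab$area, collapse = ", "))
  }
  as.list(tab[i, ])
}
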