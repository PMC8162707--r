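#' Load the published per-bird migration table
#'
#' Twelve deployment seasons from nine birds (six males, three females),
#' exactly as printed in the source study's per-bird table, with the
#' completeness footnotes applied (two female seasons ended early when
#' tags failed). Distances in km, coordinates in decimal degrees, mass at
#' tagging in g. The file's checksum is verified on load.
#'
#' @return data.frame of class `bird_summary` rows: `bird_id`, `sex`,
#'   `season`, `total_km`, `farthest_km`, `farthest_lat`, `farthest_lon`,
#'   `period_start`, `period_end`, `mass_g`, `complete`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_printed.csv",
                      package = "puffinGLS", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, "35d083c7d249badec1379ddedf95b7cc")) {
    stop("load_table1_fixture: checksum mismatch (", sum, ")")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(bird_id = "character"))
  df$period_start <- as.Date(df$period_start)
  df$period_end <- as.Date(df$period_end)
  stopifnot(nrow(df) == 12, all(df$mass_g > 0), all(df$sex %in% c("M", "F")))
  df
}

#' Load the published monthly-distance table
#'
#' Group-level monthly mean distances from the colony by sex (mean, sd,
#' range, n of bird-seasons), October-May excluding the equinox months,
#' plus the printed female-minus-male difference row (which is internally
#' inconsistent with the printed means for some months; see
#' [monthly_table_discrepancies()]).
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_printed.csv",
                      package = "puffinGLS", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, "619dd57c748ddb557f5ab0c504307910")) {
    stop("load_table2_fixture: checksum mismatch (", sum, ")")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$month <- factor(df$month, levels = .season_months)
  df
}

.season_months <- c("Oct", "Nov", "Dec", "Jan", "Feb", "Apr", "May")

#' Sex-grouped summary statistics
#'
#' Mean, sample (n-1) standard deviation and range of one field over the
#' deployment seasons matching a sex, optionally restricted to complete
#' migrations. Repeated seasons from the same bird count once each, the
#' convention of the source analysis.
#'
#' @param records data.frame from [load_table1_fixture()] (or compatible).
#' @param field column to summarise (e.g. `"total_km"`).
#' @param sex `"M"`, `"F"`, or `NULL` for all.
#' @param complete_only drop incomplete seasons first (default TRUE).
#' @return one-row data.frame `group`, `n`, `mean`, `sd` (NA when n = 1),
#'   `min`, `max`.
#' @export
group_stats <- function(records, field, sex = NULL, complete_only = TRUE) {
  sel <- rep(TRUE, nrow(records))
  if (!is.null(sex)) sel <- sel & records$sex == sex
  if (complete_only) sel <- sel & records$complete
  x <- records[[field]][sel]
  if (length(x) == 0) {
    stop(sprintf("group_stats: no records match group '%s/%s'",
                 field, sex %||% "all"))
  }
  data.frame(group = paste0(field, "/", sex %||% "all"),
             n = length(x), mean = mean(x),
             sd = if (length(x) > 1) stats::sd(x) else NA_real_,
             min = min(x), max = max(x),
             stringsAsFactors = FALSE)
}

#' Mean difference between the sexes
#'
#' @param records as in [group_stats()].
#' @param field column to compare.
#' @param statistic summary function (default `mean`).
#' @param direction `"male_minus_female"` or `"female_minus_male"`.
#' @param complete_only restrict to complete migrations.
#' @return the signed difference.
#' @export
sex_difference <- function(records, field, statistic = mean,
                           direction = c("male_minus_female",
                                         "female_minus_male"),
                           complete_only = TRUE) {
  direction <- match.arg(direction)
  sel <- if (complete_only) records$complete else rep(TRUE, nrow(records))
  m <- records[[field]][sel & records$sex == "M"]
  f <- records[[field]][sel & records$sex == "F"]
  if (length(m) == 0 || length(f) == 0) {
    stop("sex_difference: one of the sex groups is empty")
  }
  d <- statistic(m) - statistic(f)
  if (direction == "female_minus_male") -d else d
}

#' Monthly distance grid by sex
#'
#' Per month and sex: mean, sample sd, range and n over bird-seasons of
#' monthly mean distance from the colony, plus a female-minus-male
#' difference row computed from the means.
#'
#' @param monthly data.frame with columns `bird_id`, `season`, `sex`,
#'   `month` (factor or name in Oct..May order), `mean_km` — one row per
#'   bird-season and month.
#' @return data.frame `month`, `sex` (`"M"`, `"F"`, `"F-M"`), `mean_km`,
#'   `sd_km`, `min_km`, `max_km`, `n`.
#' @export
monthly_table <- function(monthly) {
  stopifnot(all(c("sex", "month", "mean_km") %in% names(monthly)))
  mo <- factor(as.character(monthly$month),
               levels = intersect(.season_months,
                                  unique(as.character(monthly$month))))
  rows <- list()
  for (m in levels(mo)) {
    means <- c(M = NA_real_, F = NA_real_)
    for (s in c("M", "F")) {
      x <- monthly$mean_km[mo == m & monthly$sex == s]
      if (length(x) == 0) next
      means[s] <- mean(x)
      rows[[length(rows) + 1]] <- data.frame(
        month = m, sex = s, mean_km = mean(x),
        sd_km = if (length(x) > 1) stats::sd(x) else NA_real_,
        min_km = min(x), max_km = max(x), n = length(x),
        stringsAsFactors = FALSE)
    }
    if (all(is.finite(means))) {
      rows[[length(rows) + 1]] <- data.frame(
        month = m, sex = "F-M", mean_km = means["F"] - means["M"],
        sd_km = NA_real_, min_km = NA_real_, max_km = NA_real_,
        n = NA_integer_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Discrepancies in the published monthly difference row
#'
#' Compares the published female-minus-male difference row against the
#' subtraction of the published monthly means and reports months where
#' they disagree by more than 1 km (rounding allowance). The published
#' row cannot be reproduced from the published means for some months;
#' differences are therefore always recomputed from the means here.
#'
#' @param table2 data.frame from [load_table2_fixture()].
#' @return data.frame `month`, `printed_km`, `computed_km`, `consistent`.
#' @export
monthly_table_discrepancies <- function(table2 = load_table2_fixture()) {
  months <- levels(table2$month)
  rows <- lapply(months, function(m) {
    sub <- table2[table2$month == m, ]
    comp <- sub$mean_km[sub$sex == "F"] - sub$mean_km[sub$sex == "M"]
    printed <- sub$printed_difference_km[1]
    data.frame(month = m, printed_km = printed, computed_km = comp,
               consistent = abs(printed - comp) <= 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Round per the reporting convention
#'
#' Distances to whole km; latitudes/longitudes to 0.1 degrees; halves
#' rounded away from zero (the convention of the published tables, unlike
#' R's banker's rounding).
#' @param x numeric.
#' @param digits 0 for distances, 1 for coordinates.
#' @export
round_report <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
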