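# Recognised vital-rate names and age classes. The matrix model consumes a
# year x rate table keyed by (rate_name, age_class); NI2, H, S_chick, NS2 and
# S_juv are estimated with ages pooled.
RATE_NAMES <- c("NI1", "NI2", "CS1", "CS2", "H", "NS1", "NS2",
                "S_chick", "S_juv", "S_month", "S_season", "S_annual")
AGE_CLASSES <- c("SY", "ASY", "pooled")
POOLED_ONLY <- c("NI2", "H", "S_chick")

# Rates measured on the probability scale (clutch sizes are egg counts).
PROB_RATES <- setdiff(RATE_NAMES, c("CS1", "CS2"))

#' Rate/age combinations required to build an annual projection matrix
#'
#' @return A data frame with columns `rate_name` and `age_class`, one row per
#'   lower-level vital rate entering the two-age pre-birth-pulse matrix.
#' @export
required_matrix_rates <- function() {
  data.frame(
    rate_name = c("NI1", "NI1", "NI2", "CS1", "CS1", "CS2", "CS2", "H",
                  "NS1", "NS1", "NS2", "S_chick", "S_juv",
                  "S_annual", "S_annual"),
    age_class = c("SY", "ASY", "pooled", "SY", "ASY", "SY", "ASY", "pooled",
                  "SY", "ASY", "pooled", "pooled", "pooled", "SY", "ASY"),
    stringsAsFactors = FALSE
  )
}

validate_rate_rows <- function(x, file = "<data>") {
  needed <- c("year", "rate_name", "age_class", "mean", "se", "n")
  miss <- setdiff(needed, names(x))
  if (length(miss))
    stop("vital-rate table is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!x$rate_name %in% RATE_NAMES)
  if (length(bad))
    stop(sprintf("%s line %d: unknown rate_name '%s'", file, bad[1] + 1L,
                 x$rate_name[bad[1]]))
  bad <- which(!x$age_class %in% AGE_CLASSES)
  if (length(bad))
    stop(sprintf("%s line %d: unknown age_class '%s'", file, bad[1] + 1L,
                 x$age_class[bad[1]]))
  bad <- which(x$rate_name %in% POOLED_ONLY & x$age_class != "pooled")
  if (length(bad))
    stop(sprintf("%s line %d: rate %s must have age_class 'pooled'",
                 file, bad[1] + 1L, x$rate_name[bad[1]]))
  obs <- !is.na(x$mean)
  bad <- which(obs & x$rate_name %in% PROB_RATES &
                 (x$mean < 0 | x$mean > 1))
  if (length(bad))
    stop(sprintf("%s line %d: %s is a probability but mean = %g",
                 file, bad[1] + 1L, x$rate_name[bad[1]], x$mean[bad[1]]))
  bad <- which(obs & !x$rate_name %in% PROB_RATES & x$mean <= 0)
  if (length(bad))
    stop(sprintf("%s line %d: clutch size must be positive (got %g)",
                 file, bad[1] + 1L, x$mean[bad[1]]))
  if (any(obs & is.na(x$se))) {
    warning("missing SE treated as 0 (rate held as a known constant)")
    x$se[obs & is.na(x$se)] <- 0
  }
  bad <- which(obs & (x$se < 0 | !is.finite(x$se)))
  if (length(bad))
    stop(sprintf("%s line %d: se must be finite and >= 0", file, bad[1] + 1L))
  if (any(x$n < 0, na.rm = TRUE)) stop("sample sizes must be >= 0")
  x
}

#' Read an annual vital-rate table
#'
#' Reads a CSV with columns `year, rate_name, age_class, mean, se, n`, one row
#' per vital rate and year. Rows with an empty mean and `n = 0` represent
#' rate/year combinations with no data (e.g. re-nest clutch size in years
#' without observed yearling re-nests) and are kept as `NA` so that
#' [complete_cs2()] can fill them by the first-nest offset rule.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `vital_rate_table`.
#' @export
read_vital_rate_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(x) == 0) {
    x <- data.frame(year = integer(), rate_name = character(),
                    age_class = character(), mean = numeric(),
                    se = numeric(), n = numeric())
  }
  x <- validate_rate_rows(x, file = basename(path))
  class(x) <- c("vital_rate_table", "data.frame")
  x
}

#' Write an annual vital-rate table
#'
#' @param x A `vital_rate_table` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_vital_rate_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Fill missing re-nest clutch sizes from first-nest clutch size
#'
#' Years without observed re-nests for an age class carry no CS2 estimate; the
#' rate is then derived as first-nest clutch size minus a fixed age-specific
#' offset (meta-analytic difference between first and replacement clutches:
#' 1.39 eggs for yearlings, 1.63 for adults). The SE assigned to derived
#' values defaults to the SE printed for observed re-nest clutches.
#'
#' @param x A `vital_rate_table`.
#' @param offsets Named vector of egg offsets for `SY` and `ASY`.
#' @param fallback_se Named vector of SEs used for derived CS2 values.
#' @return The table with all CS2 rows populated.
#' @export
complete_cs2 <- function(x, offsets = c(SY = 1.39, ASY = 1.63),
                         fallback_se = c(SY = 0.40, ASY = 0.30)) {
  for (i in which(x$rate_name == "CS2" & is.na(x$mean))) {
    age <- x$age_class[i]
    j <- which(x$rate_name == "CS1" & x$age_class == age &
                 x$year == x$year[i])
    if (length(j) != 1 || is.na(x$mean[j]))
      stop("no CS1 available to derive CS2 for ", age, " in ", x$year[i])
    x$mean[i] <- clutch_size_renest(x$mean[j], age, offsets)
    x$se[i] <- unname(fallback_se[age])
  }
  x
}

#' Vital rates of the Trout Creek Mountains sage-grouse study, 2013-2018
#'
#' The packaged table of annual vital-rate means, SEs and sample sizes for the
#' post-wildfire study population (nest initiation, clutch size, hatchability,
#' nest survival, chick survival, derived juvenile survival and annual female
#' survival by age class).
#'
#' @param complete If `TRUE` (default), derive missing re-nest clutch sizes
#'   via [complete_cs2()].
#' @return A `vital_rate_table` data frame.
#' @export
trout_creek_rates <- function(complete = TRUE) {
  path <- system.file("extdata", "vital_rates_table1.csv",
                      package = "grousedemog", mustWork = TRUE)
  x <- read_vital_rate_table(path)
  if (complete) x <- complete_cs2(x)
  x
}

#' Extract one year's rates as a named vector
#'
#' Returns the 15 lower-level rates needed by the matrix model, named
#' `NI1_SY`, `NI1_ASY`, `NI2`, ..., `S_SY`, `S_ASY` (annual survival), with the
#' matching SEs as the `"se"` attribute.
#'
#' @param x A `vital_rate_table`.
#' @param year Calendar year to extract.
#' @return Named numeric vector with attribute `se`.
#' @export
rates_vector <- function(x, year) {
  req <- required_matrix_rates()
  key <- ifelse(req$age_class == "pooled", req$rate_name,
                paste(req$rate_name, req$age_class, sep = "_"))
  key[req$rate_name == "S_annual"] <-
    paste0("S_", req$age_class[req$rate_name == "S_annual"])
  out <- se <- stats::setNames(numeric(nrow(req)), key)
  for (i in seq_len(nrow(req))) {
    j <- which(x$year == year & x$rate_name == req$rate_name[i] &
                 x$age_class == req$age_class[i])
    if (length(j) != 1 || is.na(x$mean[j]))
      stop("missing vital rate for ", year, ": ", req$rate_name[i], " (",
           req$age_class[i], ")")
    out[i] <- x$mean[j]
    se[i] <- x$se[j]
  }
  attr(out, "se") <- se
  out
}

#' Split a vital-rate table into per-year rate vectors
#'
#' @param x A `vital_rate_table`.
#' @return Named list (by year) of [rates_vector()] outputs.
#' @export
annual_rates <- function(x) {
  yrs <- sort(unique(x$year))
  stats::setNames(lapply(yrs, function(y) rates_vector(x, y)),
                  as.character(yrs))
}
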