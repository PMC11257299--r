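#' Normalize a sex code
#'
#' Survey exports encode sex inconsistently; this maps the common encodings
#' `M`, `F`, `male`, `female`, `1`, `2` (case-insensitive) onto the canonical
#' `"male"` / `"female"`.
#'
#' @param sex character or numeric vector of sex codes.
#' @return character vector with elements `"male"` or `"female"`; unknown
#'   codes become `NA`.
#' @export
#' @examples
#' normalize_sex(c("M", "f", "male", 2))
normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("m", "male", "1")] <- "male"
  out[s %in% c("f", "female", "2")] <- "female"
  out
}

#' Construct a cohort of anthropometric records
#'
#' A cohort is one age-sex cell of a cross-sectional survey: a data frame
#' with columns `age` (integer completed years), `sex`, `height_cm` and
#' `weight_kg`. All records in a cohort share the same age and sex. Heights
#' are stored in centimetres as recorded; model fitting converts to metres
#' (all `C_q` values are on the metre scale).
#'
#' @param height_cm positive heights in centimetres.
#' @param weight_kg positive weights in kilograms.
#' @param age integer age in completed years, 5-17.
#' @param sex sex code, normalized via [normalize_sex()].
#' @return an object of class `cohort` (a data frame).
#' @export
cohort <- function(height_cm, weight_kg, age, sex) {
  stopifnot(length(height_cm) == length(weight_kg))
  sex <- normalize_sex(sex)[1L]
  age <- as.integer(age)[1L]
  df <- data.frame(age = age, sex = sex,
                   height_cm = as.numeric(height_cm),
                   weight_kg = as.numeric(weight_kg))
  ok <- validate_records(df)
  if (!all(ok)) stop("cohort() requires pre-validated records; ",
                     sum(!ok), " invalid")
  structure(df, class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> age %s, sex %s, n = %d\n",
              x$age[1], x$sex[1], nrow(x)))
  cat(sprintf("  height [cm]: %.1f-%.1f  weight [kg]: %.1f-%.1f\n",
              min(x$height_cm), max(x$height_cm),
              min(x$weight_kg), max(x$weight_kg)))
  invisible(x)
}

# heights in metres, the unit of every model formula
cohort_h <- function(x) x$height_cm / 100
cohort_w <- function(x) x$weight_kg

#' Validate a single anthropometric record
#'
#' A record is valid iff all four fields are present (non-missing), height
#' and weight are strictly positive, and age lies in 5-17 completed years.
#' Invalid records are excluded from analysis, never imputed.
#'
#' @param record a list or one-row data frame with fields `age`, `sex`,
#'   `height_cm`, `weight_kg`.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' validate_record(list(age = 8, sex = "female", height_cm = 128, weight_kg = 26))
#' validate_record(list(age = 8, sex = "female", height_cm = NA, weight_kg = 26))
validate_record <- function(record) {
  df <- as.data.frame(record[c("age", "sex", "height_cm", "weight_kg")])
  nrow(df) == 1L && validate_records(df)
}

#' Vectorized record validation
#'
#' @param df data frame with columns `age`, `sex`, `height_cm`, `weight_kg`.
#' @return logical vector, one element per row.
#' @export
validate_records <- function(df) {
  sex <- normalize_sex(df$sex)
  !is.na(df$age) & !is.na(sex) &
    !is.na(df$height_cm) & !is.na(df$weight_kg) &
    df$height_cm > 0 & df$weight_kg > 0 &
    df$age >= 5 & df$age <= 17
}

# first failing check per row, NA where valid; used for the exclusion log
exclusion_reason <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  miss <- is.na(df$age) | is.na(normalize_sex(df$sex)) |
    is.na(df$height_cm) | is.na(df$weight_kg)
  nonpos <- !miss & (df$height_cm <= 0 | df$weight_kg <= 0)
  badage <- !miss & !nonpos & (df$age < 5 | df$age > 17)
  reason[miss] <- "missing field"
  reason[nonpos] <- "nonpositive height or weight"
  reason[badage] <- "age outside 5-17"
  reason
}

#' Read one age-sex cohort from a survey CSV
#'
#' Reads a CSV with header `age,sex,height_cm,weight_kg`, drops records that
#' fail [validate_record()] (logging the first failing check per row), and
#' returns the validated records matching the requested age and sex, in file
#' order.
#'
#' @param path CSV file path.
#' @param age integer age filter.
#' @param sex sex filter (any encoding accepted by [normalize_sex()]).
#' @return a [cohort()]; attribute `exclusions` holds a data frame of
#'   excluded row numbers and reasons (for the whole file, not just the
#'   requested cell).
#' @export
read_cohort <- function(path, age, sex) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- names(read.csv(path, nrows = 1))
  cc <- rep(NA, length(hdr))  # NA = let read.csv infer
  names(cc) <- hdr
  cc[hdr == "sex"] <- "character"  # an all-"F" column must not parse as logical
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = cc)
  need <- c("age", "sex", "height_cm", "weight_kg")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("format error: missing column(s) ", paste(missing_cols, collapse = ", "))
  ok <- validate_records(df)
  excl <- data.frame(row = which(!ok), reason = exclusion_reason(df)[!ok])
  df <- df[ok, , drop = FALSE]
  sex <- normalize_sex(sex)[1L]
  sel <- df$age == as.integer(age) & normalize_sex(df$sex) == sex
  if (!any(sel))
    stop(sprintf("empty cohort: no valid records for age %d, sex %s",
                 as.integer(age), sex))
  out <- cohort(df$height_cm[sel], df$weight_kg[sel], age, sex)
  attr(out, "exclusions") <- excl
  out
}

#' Write a cohort to the standard survey CSV
#'
#' @param x a [cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  write.csv(as.data.frame(x)[, c("age", "sex", "height_cm", "weight_kg")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
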