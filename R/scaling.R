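#' Classify a cohort as uni- or multi-scaling
#'
#' A weight-for-height distribution is *uni-scaling* when all centile curves
#' share one exponent (parallel lines in log-log space) and *multi-scaling*
#' when \eqn{\alpha(q)} varies with \eqn{q}. Neither notion comes with a
#' formal test, so the rule here is a declared tolerance: with
#' `spread = max |alpha(q_i) - alpha(q_j)|` over centile pairs,
#' the profile is `"uni"` if `spread <= epsilon`; `"multi"` if
#' `spread > epsilon` *and* at least one pair of bootstrap alpha intervals is
#' disjoint; `"undetermined"` if the spread exceeds `epsilon` but every pair
#' of intervals overlaps (the spread could be sampling noise). Profiles fitted
#' without bootstrap intervals fall back to the spread rule alone.
#'
#' @param profile an `exponent_profile` from [fit_profile()], with at least
#'   two centiles.
#' @param epsilon exponent tolerance; the default 0.1 is of the order of the
#'   spread seen in near-adult (17-year) cohorts, well below the >1 spreads
#'   of strongly multi-scaling childhood cohorts.
#' @return the profile with `scaling_class` and `spread` filled in.
#' @export
classify_scaling <- function(profile, epsilon = 0.1) {
  stopifnot(inherits(profile, "exponent_profile"))
  e <- profile$entries
  if (nrow(e) < 2) stop("classification needs at least two centiles")
  spread <- max(e$alpha) - min(e$alpha)
  profile$spread <- spread
  if (spread <= epsilon) {
    profile$scaling_class <- "uni"
  } else {
    has_int <- !all(is.na(e$alpha_lo))
    disjoint <- FALSE
    if (has_int) {
      for (i in seq_len(nrow(e) - 1)) {
        for (j in seq(i + 1, nrow(e))) {
          if (e$alpha_lo[i] > e$alpha_hi[j] || e$alpha_lo[j] > e$alpha_hi[i]) {
            disjoint <- TRUE
          }
        }
      }
    } else {
      disjoint <- TRUE  # no intervals available: trust the point spread
    }
    profile$scaling_class <- if (disjoint) "multi" else "undetermined"
  }
  profile
}

#' Height at which two power-law centile curves cross
#'
#' Two curves \eqn{C_a h^{\alpha_a}} and \eqn{C_b h^{\alpha_b}} with
#' \eqn{\alpha_a \ne \alpha_b} intersect at exactly one positive height,
#' \deqn{h^* = (C_a / C_b)^{1/(\alpha_b - \alpha_a)}.}
#' Fitted centile curves of a multi-scaling cohort typically cross on the
#' short-height side, below the plausible height range of the age group;
#' a crossing inside the range would invalidate the fitted curve family.
#'
#' @param fit_a,fit_b `powerlaw_fit` objects (or any list with `alpha`, `C`).
#' @param range optional plausible height range (metres) used to flag the
#'   crossing.
#' @return `NULL` when the curves are parallel in log-log space (equal
#'   exponents, different constants); otherwise a list with `h` (metres) and,
#'   if `range` was given, `inside_range`.
#' @export
#' @examples
#' a <- list(alpha = 2.39, C = 12.19)  # 8-year male 2nd centile
#' b <- list(alpha = 4.05, C = 13.41)  # 8-year male 98th centile
#' crossing_height(a, b, range = c(1.10, 1.45))
crossing_height <- function(fit_a, fit_b, range = NULL) {
  stopifnot(fit_a$C > 0, fit_b$C > 0)
  da <- fit_b$alpha - fit_a$alpha
  if (da == 0) {
    if (fit_a$C == fit_b$C) stop("degenerate: the two curves coincide")
    return(NULL)
  }
  h <- exp((log(fit_a$C) - log(fit_b$C)) / da)
  out <- list(h = h)
  if (!is.null(range)) out$inside_range <- h >= range[1] && h <= range[2]
  out
}

#' Assemble an age-by-sex exponent table from fitted profiles
#'
#' @param profiles list of `exponent_profile` objects (e.g. one per age-sex
#'   cell); all must share the same centile grid. Missing cells are simply
#'   absent from the table.
#' @return list with `params`: long-format data frame
#'   `age, sex, q, alpha, alpha_lo, alpha_hi, C, C_lo, C_hi` (one row per
#'   age-sex-centile), and `classes`: per-cell data frame
#'   `age, sex, scaling_class, spread`.
#' @export
exponent_age_table <- function(profiles) {
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "exponent_profile")))
  grids <- lapply(profiles, function(p) p$entries$q)
  if (length(unique(vapply(grids, paste, "", collapse = ","))) != 1)
    stop("schema error: profiles have inconsistent centile grids")
  params <- do.call(rbind, lapply(profiles, function(p)
    cbind(data.frame(age = p$age, sex = p$sex), p$entries)))
  classes <- do.call(rbind, lapply(profiles, function(p)
    data.frame(age = p$age, sex = p$sex,
               scaling_class = p$scaling_class, spread = p$spread)))
  rownames(params) <- rownames(classes) <- NULL
  list(params = params, classes = classes)
}

#' Write an estimated-parameter table to CSV
#'
#' Serialises profiles as a long-format table with header
#' `age,sex,q,alpha,alpha_lo,alpha_hi,C,C_lo,C_hi`, one row per
#' (age, sex, centile). Values are rounded only at serialization.
#'
#' @param profiles list of `exponent_profile` objects sharing one centile
#'   grid (a single profile may be given bare).
#' @param path output CSV path.
#' @param digits decimal places written (default 2, matching conventional
#'   reporting of scaling exponents and cutoffs).
#' @return `path`, invisibly.
#' @export
write_params_table <- function(profiles, path, digits = 2) {
  if (inherits(profiles, "exponent_profile")) profiles <- list(profiles)
  tab <- exponent_age_table(profiles)$params
  num <- vapply(tab, is.numeric, TRUE) & names(tab) != "age" & names(tab) != "q"
  tab[num] <- lapply(tab[num], round, digits = digits)
  write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read back a parameter table written by [write_params_table()]
#'
#' @param path CSV path.
#' @return data frame with the table's columns.
#' @export
read_params_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "q", "alpha", "C")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("format error: missing column(s) ", paste(missing_cols, collapse = ", "))
  df
}
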