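#' Height-adjusted body index w / h^alpha
#'
#' The general index family behind BMI: `alpha = 2` gives conventional BMI,
#' `alpha = alpha(50)` the standardized (median-exponent) BMI, and
#' `alpha = alpha(q)` the extended BMI for centile `q`, `BMI_ext(q)`.
#' Units are kg m^-alpha.
#'
#' @param w weight in kg (positive).
#' @param h height in metres (positive).
#' @param alpha scaling exponent.
#' @return index value(s); vectorized over `w` and `h`.
#' @export
#' @examples
#' index_value(60, 1.5, 2)      # conventional BMI
#' index_value(50, 1.6, 1.85)   # standardized BMI with alpha(50) = 1.85
index_value <- function(w, h, alpha) {
  if (any(h <= 0)) stop("height must be positive")
  if (any(w <= 0)) stop("weight must be positive")
  w / h^alpha
}

#' Extended BMI of a cohort with its centile cutoff
#'
#' Computes `BMI_ext(q) = w / h^alpha(q)` for every record, using the
#' exponent of a fitted q-th centile curve, and flags records against the
#' cutoff `C_q` (the fitted proportionality constant). For lower centiles
#' (q < 50) the index assesses thinness: a record is flagged iff
#' `BMI_ext(q) < C_q`, which is algebraically the same as its weight lying
#' strictly below the q-th centile curve. For upper centiles (q > 50) the
#' direction reverses (fatness: flagged iff `BMI_ext(q) > C_q`). Comparisons
#' are strict; boundary records are unflagged.
#'
#' @param x a [cohort()] (or data frame with `height_cm`, `weight_kg`).
#' @param fit a `powerlaw_fit` for the target centile (its `q`, `alpha`, `C`
#'   are used), or a list with those fields, e.g. a row of a published
#'   parameter table.
#' @param direction `"auto"` (from `q` vs 50), `"below"` (thinness) or
#'   `"above"` (fatness).
#' @return object of class `bmi_ext_result`: data frame `values` with
#'   columns `height_m, weight_kg, index, flag`, plus fields `q`,
#'   `alpha_used`, `cutoff`, `direction`.
#' @export
bmi_ext <- function(x, fit, direction = c("auto", "below", "above")) {
  direction <- match.arg(direction)
  if (direction == "auto")
    direction <- if (fit$q <= 50) "below" else "above"
  h <- x$height_cm / 100
  w <- x$weight_kg
  idx <- index_value(w, h, fit$alpha)
  flag <- if (direction == "below") idx < fit$C else idx > fit$C
  structure(list(values = data.frame(height_m = h, weight_kg = w,
                                     index = idx, flag = flag),
                 q = fit$q, alpha_used = fit$alpha, cutoff = fit$C,
                 direction = direction),
            class = "bmi_ext_result")
}

#' @export
print.bmi_ext_result <- function(x, ...) {
  cat(sprintf("<bmi_ext_result> q = %g, alpha = %.3f, cutoff C_q = %.3f (%s): %d / %d flagged\n",
              x$q, x$alpha_used, x$cutoff, x$direction,
              sum(x$values$flag), nrow(x$values)))
  invisible(x)
}

#' Thinness / fatness cutoff of a fitted centile curve
#'
#' The cutoff for the extended BMI at centile `q` is the fitted
#' proportionality constant `C_q` itself: `BMI_ext(q) < C_q` iff the record
#' lies below the q-th centile curve.
#'
#' @param fit a `powerlaw_fit` (or list with field `C`).
#' @return the cutoff, kg m^-alpha.
#' @export
thinness_cutoff <- function(fit) fit$C

#' Equal-width height strata over median +/- 3 SD
#'
#' Defines `k` contiguous equal-width strata spanning
#' `[median(h) - 3 sd(h), median(h) + 3 sd(h)]`. Records outside the span
#' are excluded from stratified diagnostics (and counted), keeping the span
#' fixed rather than stretching the edge strata.
#'
#' @param x a [cohort()].
#' @param k number of strata (default 10).
#' @return object of class `height_strata`: data frame `bounds` with
#'   `stratum` (0-based), `low`, `high` (metres; intervals are
#'   `[low, high)`, the last closed), plus `span`, `n_excluded`.
#' @export
stratify_heights <- function(x, k = 10L) {
  stopifnot(nrow(x) >= k)
  h <- x$height_cm / 100
  s <- sd(h)
  if (s == 0) stop("degenerate: zero height standard deviation")
  m <- median(h)
  span <- c(m - 3 * s, m + 3 * s)
  edges <- seq(span[1], span[2], length.out = k + 1)
  structure(list(bounds = data.frame(stratum = seq_len(k) - 1L,
                                     low = edges[-(k + 1)], high = edges[-1]),
                 span = span,
                 n_excluded = sum(h < span[1] | h > span[2])),
            class = "height_strata")
}

# stratum index (0-based) per record, NA outside the span
stratum_of <- function(h, strata) {
  k <- nrow(strata$bounds)
  idx <- findInterval(h, c(strata$bounds$low, strata$bounds$high[k]),
                      rightmost.closed = TRUE)
  idx[idx < 1 | idx > k] <- NA_integer_
  idx - 1L
}

#' Empirical centile points per height stratum
#'
#' Computes the q-th empirical centiles of weight (or of an index
#' `w / h^alpha`) within each height stratum, using linear interpolation of
#' order statistics (R's default quantile rule, type 7). Plotted against
#' stratum height these points reveal whether the chosen index is
#' height-independent at each centile. Strata with fewer than `floor`
#' records are marked unreliable rather than dropped.
#'
#' @param x a [cohort()].
#' @param strata a [stratify_heights()] result.
#' @param centiles centiles to compute, in (0, 100).
#' @param value `"weight"` or `"index"`.
#' @param alpha exponent used when `value = "index"`.
#' @param floor minimum stratum size for a reliable estimate.
#' @return data frame with one row per stratum: `stratum`, `low`, `high`,
#'   `mid`, `n`, `reliable`, and one `q<centile>` column per centile
#'   (`NA` for empty strata).
#' @export
stratum_centiles <- function(x, strata, centiles = c(2, 50, 98),
                             value = c("weight", "index"), alpha = 2,
                             floor = 100L) {
  value <- match.arg(value)
  h <- x$height_cm / 100
  v <- if (value == "weight") x$weight_kg else index_value(x$weight_kg, h, alpha)
  si <- stratum_of(h, strata)
  b <- strata$bounds
  out <- data.frame(stratum = b$stratum, low = b$low, high = b$high,
                    mid = (b$low + b$high) / 2,
                    n = vapply(b$stratum, function(s) sum(si == s, na.rm = TRUE), 0L))
  out$reliable <- out$n >= floor
  for (q in centiles) {
    out[[paste0("q", q)]] <- vapply(b$stratum, function(s) {
      vs <- v[!is.na(si) & si == s]
      if (length(vs) == 0) NA_real_
      else quantile(vs, probs = q / 100, names = FALSE, type = 7)
    }, 0.0)
  }
  out
}

#' Height-dependence (flatness) diagnostic of an index centile
#'
#' Fits a linear quantile regression of the index `w / h^alpha` on height at
#' \eqn{\tau = q/100}. A slope near zero means the q-th centile of the index
#' is height-independent — the index is a valid height-adjusted measure at
#' that centile. Under uni-scaling the common exponent flattens every
#' centile; under multi-scaling only the matched exponent
#' `alpha = alpha(q)` flattens centile `q`.
#'
#' @param x a [cohort()].
#' @param alpha exponent defining the index.
#' @param q centile in (0, 100).
#' @param ... passed to [fit_linear_quantile()].
#' @return a `linear_quantile_fit` with extra fields `alpha_used`, `q`, and
#'   `relative_slope` — slope as a fraction of the cohort median index per
#'   metre of height.
#' @export
flatness_diagnostic <- function(x, alpha, q, ...) {
  h <- x$height_cm / 100
  idx <- index_value(x$weight_kg, h, alpha)
  fit <- fit_linear_quantile(h, idx, tau = q / 100, ...)
  fit$alpha_used <- alpha
  fit$q <- q
  fit$relative_slope <- fit$slope / median(idx)
  fit
}
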