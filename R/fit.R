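#' Pinball (quantile) loss of a power-law centile curve
#'
#' The weighted absolute-residual objective of quantile regression for the
#' allometric model \eqn{f(h) = C h^\alpha}:
#' \deqn{\sum_{i: w_i \ge f(h_i)} \tau\,|w_i - f(h_i)| +
#'       \sum_{i: w_i < f(h_i)} (1-\tau)\,|w_i - f(h_i)|.}
#' Residuals exactly on the curve contribute zero from either side.
#'
#' @param h heights in metres (positive).
#' @param w weights in kg.
#' @param C positive proportionality constant, kg m^-alpha.
#' @param alpha scaling exponent.
#' @param tau quantile level in (0, 1); `tau = q/100` for the q-th centile.
#' @return non-negative loss.
#' @export
#' @examples
#' pinball_loss(c(1, 1), c(12, 8), C = 10, alpha = 2, tau = 0.9)  # 2.0
pinball_loss <- function(h, w, C, alpha, tau) {
  stopifnot(length(h) == length(w), all(h > 0), tau > 0, tau < 1)
  if (C <= 0) stop("C must be positive")
  cpp_pinball(log(h), w, log(C), alpha, tau, 1L)
}

#' Fit a power-law quantile curve by simplex search
#'
#' Estimates \eqn{(C_q, \alpha(q))} of the extended power-law model
#' \eqn{w_q(h) = C_q h^{\alpha(q)}} at centile `q` by minimising the pinball
#' loss at \eqn{\tau = q/100} with a Nelder-Mead simplex search over
#' \eqn{(\log C, \alpha)}. Optimising \eqn{\log C} enforces \eqn{C > 0} and
#' conditions the search. The start point is a log-log linear quantile fit
#' at the same \eqn{\tau} (exact on noise-free power-law data); further
#' deterministic perturbed restarts are attempted up to `restarts`, stopping
#' early once a restart fails to improve the incumbent loss.
#'
#' @param x a [cohort()], or a data frame / list with `height_cm` and
#'   `weight_kg` columns; heights are converted to metres internally.
#' @param q centile in (0, 100).
#' @param tol relative simplex-size and loss-change tolerance.
#' @param max_iter objective-evaluation cap per start.
#' @param restarts maximum number of simplex starts.
#' @param init optional `c(logC, alpha)` start, e.g. a warm start from a
#'   neighbouring replicate; skips the internal log-log initialisation.
#' @return object of class `powerlaw_fit`: fields `q`, `tau` (= q/100),
#'   `alpha`, `C`, `loss`, `converged`, `n_iter`, `n_restarts_used`, `n`.
#' @export
#' @examples
#' h <- seq(1.1, 1.5, length.out = 50)
#' co <- cohort(h * 100, 15 * h^2, 8, "F")
#' fit_powerlaw_quantile(co, 50)
fit_powerlaw_quantile <- function(x, q, tol = 1e-8, max_iter = 2000L,
                                  restarts = 5L, init = NULL) {
  stopifnot(q > 0, q < 100)
  h <- x$height_cm / 100
  w <- x$weight_kg
  n <- length(h)
  if (n < 3) stop("need at least 3 records to fit")
  if (length(unique(h)) < 2)
    stop("unidentifiable exponent: all heights identical")
  tau <- q / 100
  lh <- log(h)
  if (is.null(init)) {
    ll <- fit_loglog_init(lh, log(w), tau, tol, max_iter)
    init <- c(ll$intercept, ll$slope)
  }
  res <- cpp_fit_pinball(lh, w, tau, 1L, as.numeric(init),
                         as.integer(restarts), tol, as.integer(max_iter))
  structure(list(q = q, tau = tau, alpha = res$p1, C = exp(res$p0),
                 loss = res$loss, converged = isTRUE(res$converged),
                 n_iter = res$neval, n_restarts_used = res$n_starts, n = n),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> q = %g: alpha = %.4f, C = %.4f (loss %.6g, n = %d%s)\n",
              x$q, x$alpha, x$C, x$loss, x$n,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Predicted centile curve of a power-law fit
#' @param object a `powerlaw_fit`.
#' @param h heights in metres.
#' @param ... unused.
#' @return predicted weights, kg.
#' @export
predict.powerlaw_fit <- function(object, h, ...) object$C * h^object$alpha

# log-log linear quantile fit used as the simplex start point: OLS slope on
# (log h, log w), intercept shifted to the tau-quantile of OLS residuals,
# then polished by the same simplex search on the log-scale pinball loss.
fit_loglog_init <- function(lx, ly, tau, tol, max_iter) {
  vx <- sum((lx - mean(lx))^2)
  b <- sum((lx - mean(lx)) * (ly - mean(ly))) / vx
  a <- quantile(ly - b * lx, probs = tau, names = FALSE, type = 7)
  res <- cpp_fit_pinball(lx, ly, tau, 0L, c(a, b), 2L, tol, as.integer(max_iter))
  list(intercept = res$p0, slope = res$p1, loss = res$loss)
}

#' Linear quantile regression (for index-vs-height diagnostics)
#'
#' Minimises the pinball objective for \eqn{f(x) = a + b x} by the same
#' simplex search, started from the least-squares line with its intercept
#' shifted to the \eqn{\tau}-quantile of the residuals.
#'
#' @param xs,ys predictor and response vectors (at least 2 distinct `xs`).
#' @param tau quantile level in (0, 1).
#' @param tol,max_iter,restarts as in [fit_powerlaw_quantile()].
#' @return object of class `linear_quantile_fit`: `tau`, `intercept`,
#'   `slope`, `loss`, `converged`.
#' @export
#' @examples
#' fit_linear_quantile(1:10, 3 + 2 * (1:10), tau = 0.5)
fit_linear_quantile <- function(xs, ys, tau, tol = 1e-8, max_iter = 2000L,
                                restarts = 5L) {
  stopifnot(length(xs) == length(ys), tau > 0, tau < 1)
  if (length(unique(xs)) < 2)
    stop("unidentifiable slope: all x values identical")
  vx <- sum((xs - mean(xs))^2)
  b <- sum((xs - mean(xs)) * (ys - mean(ys))) / vx
  a <- quantile(ys - b * xs, probs = tau, names = FALSE, type = 7)
  res <- cpp_fit_pinball(as.numeric(xs), as.numeric(ys), tau, 0L, c(a, b),
                         as.integer(restarts), tol, as.integer(max_iter))
  structure(list(tau = tau, intercept = res$p0, slope = res$p1,
                 loss = res$loss, converged = isTRUE(res$converged)),
            class = "linear_quantile_fit")
}

#' @export
print.linear_quantile_fit <- function(x, ...) {
  cat(sprintf("<linear_quantile_fit> tau = %g: intercept = %.4f, slope = %.4f (loss %.6g)\n",
              x$tau, x$intercept, x$slope, x$loss))
  invisible(x)
}

#' Fit an exponent profile over a centile grid with the smoothed bootstrap
#'
#' For each centile in `centiles`, fits the power-law quantile model on each
#' smoothed-bootstrap replicate of the cohort and reports the replicate
#' median of \eqn{\alpha(q)} and \eqn{C_q} together with central 95%
#' percentile intervals. All centiles are fitted on the same replicates.
#' Replicates after the first are warm-started from the first replicate's
#' estimates, which the resampling perturbs only slightly.
#'
#' @param x a [cohort()].
#' @param centiles ordered centile grid; the default `{2, 10, 50, 90, 98}`
#'   spans thinness to obesity assessment.
#' @param bootstrap a [bootstrap_config()]; `bootstrap = NULL` fits the raw
#'   cohort once, without smoothing (intervals absent).
#' @param epsilon exponent-spread tolerance passed to [classify_scaling()].
#' @param ... passed to [fit_powerlaw_quantile()].
#' @return object of class `exponent_profile`: `entries` (data frame with
#'   columns `q, alpha, alpha_lo, alpha_hi, C, C_lo, C_hi`), `n`, `age`,
#'   `sex`, `scaling_class`, `spread`, `B`, `bandwidths`.
#' @export
fit_profile <- function(x, centiles = c(2, 10, 50, 90, 98),
                        bootstrap = bootstrap_config(), epsilon = 0.1, ...) {
  stopifnot(inherits(x, "cohort"), all(centiles > 0), all(centiles < 100))
  centiles <- sort(unique(centiles))
  k <- length(centiles)
  if (is.null(bootstrap)) {
    fits <- lapply(centiles, function(q) fit_powerlaw_quantile(x, q, ...))
    entries <- data.frame(q = centiles,
                          alpha = vapply(fits, `[[`, 0, "alpha"),
                          alpha_lo = NA_real_, alpha_hi = NA_real_,
                          C = vapply(fits, `[[`, 0, "C"),
                          C_lo = NA_real_, C_hi = NA_real_)
    prof <- new_profile(entries, x, B = 0L, bandwidths = NULL)
    return(finish_profile(prof, epsilon))
  }
  # The first replicate is fitted cold (full initialisation and restart
  # budget); later replicates differ from it only by resampling noise, so
  # they are warm-started from its solution with a single simplex start.
  warm <- vector("list", k)  # per-centile (logC, alpha) warm starts
  estimator <- function(rep_cohort) {
    out <- numeric(2 * k)
    for (j in seq_len(k)) {
      f <- if (is.null(warm[[j]]))
        fit_powerlaw_quantile(rep_cohort, centiles[j], ...)
      else
        fit_powerlaw_quantile(rep_cohort, centiles[j], init = warm[[j]],
                              restarts = 1L, ...)
      if (is.null(warm[[j]])) warm[[j]] <<- c(log(f$C), f$alpha)
      out[j] <- f$alpha
      out[k + j] <- f$C
    }
    names(out) <- c(paste0("alpha_", centiles), paste0("C_", centiles))
    out
  }
  bs <- bootstrap_estimate(x, estimator, bootstrap)
  entries <- data.frame(q = centiles,
                        alpha = bs$estimate[seq_len(k)],
                        alpha_lo = bs$lower[seq_len(k)],
                        alpha_hi = bs$upper[seq_len(k)],
                        C = bs$estimate[k + seq_len(k)],
                        C_lo = bs$lower[k + seq_len(k)],
                        C_hi = bs$upper[k + seq_len(k)])
    prof <- new_profile(entries, x, B = bootstrap$B, bandwidths = bs$bandwidths)
  prof$replicates <- bs$replicates
  finish_profile(prof, epsilon)
}

# a single-centile profile has no exponent spread to assess: trivially uni
finish_profile <- function(prof, epsilon) {
  if (nrow(prof$entries) == 1) {
    prof$spread <- 0
    prof$scaling_class <- "uni"
    prof
  } else {
    classify_scaling(prof, epsilon)
  }
}

new_profile <- function(entries, x, B, bandwidths) {
  rownames(entries) <- NULL
  structure(list(entries = entries, n = nrow(x),
                 age = x$age[1], sex = x$sex[1],
                 scaling_class = "undetermined", spread = NA_real_,
                 B = B, bandwidths = bandwidths),
            class = "exponent_profile")
}

#' @export
print.exponent_profile <- function(x, ...) {
  cat(sprintf("<exponent_profile> age %s, sex %s, n = %d, B = %d: %s (spread %.3f)\n",
              x$age, x$sex, x$n, x$B, x$scaling_class, x$spread))
  print(x$entries, row.names = FALSE, digits = 4)
  invisible(x)
}
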