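#' Rule-of-thumb bandwidths for bivariate Gaussian kernel smoothing
#'
#' Normal-reference bandwidths for a bivariate Gaussian product kernel:
#' \eqn{b_j = m\,\hat\sigma_j\, n^{-1/6}} per margin (height, weight), the
#' standard \eqn{n^{-1/(d+4)}} rate at \eqn{d = 2}. The multiplier `m`
#' absorbs the constant factor of any particular published selector and
#' defaults to 1.
#'
#' @param x a [cohort()] with `n >= 2`.
#' @param multiplier positive scale factor on both bandwidths.
#' @return named numeric vector `c(height = b_h, weight = b_w)` in cm and kg.
#' @export
#' @examples
#' co <- cohort(c(120, 124, 130, 127), c(22, 25, 28, 24), 8, "F")
#' rot_bandwidths(co)
rot_bandwidths <- function(x, multiplier = 1) {
  stopifnot(inherits(x, "cohort"), nrow(x) >= 2, multiplier > 0)
  s <- c(height = sd(x$height_cm), weight = sd(x$weight_kg))
  if (any(s == 0)) stop("degenerate data: zero variance in a margin")
  multiplier * s * nrow(x)^(-1 / 6)
}

#' Smoothed-bootstrap configuration
#'
#' @param B number of bootstrap replicates (the reference protocol uses 200).
#' @param seed integer master seed; each replicate derives its own
#'   reproducible stream from `(seed, replicate_index)`.
#' @param bandwidth_rule `"normal_reference"` (compute bandwidths from the
#'   original cohort via [rot_bandwidths()]) or `"manual"`.
#' @param bandwidth_height,bandwidth_weight manual bandwidths (cm, kg);
#'   required when `bandwidth_rule = "manual"`. Zero bandwidths give the
#'   plain nonparametric bootstrap.
#' @param bandwidth_multiplier multiplier passed to [rot_bandwidths()].
#' @return an object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 200L, seed = 1L,
                             bandwidth_rule = c("normal_reference", "manual"),
                             bandwidth_height = NULL, bandwidth_weight = NULL,
                             bandwidth_multiplier = 1) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  stopifnot(B >= 1)
  if (bandwidth_rule == "manual") {
    stopifnot(!is.null(bandwidth_height), !is.null(bandwidth_weight),
              bandwidth_height >= 0, bandwidth_weight >= 0)
  }
  structure(list(B = as.integer(B), seed = as.integer(seed),
                 bandwidth_rule = bandwidth_rule,
                 bandwidth_height = bandwidth_height,
                 bandwidth_weight = bandwidth_weight,
                 bandwidth_multiplier = bandwidth_multiplier),
            class = "bootstrap_config")
}

# resolve config bandwidths against a concrete cohort
resolve_bandwidths <- function(x, config) {
  if (config$bandwidth_rule == "manual") {
    c(height = config$bandwidth_height, weight = config$bandwidth_weight)
  } else {
    rot_bandwidths(x, config$bandwidth_multiplier)
  }
}

# deterministic per-replicate substream seed, kept inside 32-bit range
replicate_seed <- function(seed, r) {
  (as.double(seed) * 48271 + as.double(r) * 16807) %% 2147483647
}

#' One smoothed-bootstrap replicate
#'
#' Draws `n` records with replacement from the `n`-record cohort, then adds
#' independent Gaussian noise to each height (sd = height bandwidth, cm) and
#' weight (sd = weight bandwidth, kg), de-discretising integer-recorded
#' survey values. Rows whose height or weight becomes nonpositive have their
#' noise redrawn (not clipped) until positive. Reproducible from
#' `(config$seed, replicate_index)`.
#'
#' @param x a [cohort()].
#' @param config a [bootstrap_config()].
#' @param replicate_index replicate number (1-based).
#' @param bandwidths optional precomputed bandwidths (height, weight);
#'   computed from `x` if missing. Supplying them matches the reference
#'   protocol of computing bandwidths once on the original data.
#' @return a [cohort()] of the same size.
#' @export
smoothed_replicate <- function(x, config, replicate_index = 1L,
                               bandwidths = NULL) {
  stopifnot(inherits(x, "cohort"), inherits(config, "bootstrap_config"))
  if (is.null(bandwidths)) bandwidths <- resolve_bandwidths(x, config)
  n <- nrow(x)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(replicate_seed(config$seed, replicate_index))
  idx <- sample.int(n, n, replace = TRUE)
  h <- x$height_cm[idx] + rnorm(n, 0, bandwidths[["height"]])
  w <- x$weight_kg[idx] + rnorm(n, 0, bandwidths[["weight"]])
  bad <- which(h <= 0 | w <= 0)
  while (length(bad) > 0) {
    h[bad] <- x$height_cm[idx[bad]] + rnorm(length(bad), 0, bandwidths[["height"]])
    w[bad] <- x$weight_kg[idx[bad]] + rnorm(length(bad), 0, bandwidths[["weight"]])
    bad <- bad[h[bad] <= 0 | w[bad] <= 0]
  }
  cohort(h, w, x$age[1], x$sex[1])
}

#' Smoothed-bootstrap estimate: replicate median and percentile interval
#'
#' Applies `estimator` to each of `B` smoothed replicates of the cohort and
#' summarises each component by the median across replicates (the point
#' estimate) and the central 95% percentile interval (a diagnostic).
#'
#' @param x a [cohort()].
#' @param estimator function mapping a cohort to a (named) numeric vector.
#' @param config a [bootstrap_config()].
#' @param level coverage of the percentile interval.
#' @return list with `estimate` (component medians), `lower`, `upper`,
#'   `replicates` (B x p matrix, failed replicates as `NA` rows),
#'   `n_failed`, and the `bandwidths` used.
#' @export
bootstrap_estimate <- function(x, estimator, config, level = 0.95) {
  stopifnot(inherits(x, "cohort"), is.function(estimator),
            inherits(config, "bootstrap_config"))
  bw <- resolve_bandwidths(x, config)
  B <- config$B
  rows <- vector("list", B)
  for (r in seq_len(B)) {
    rep_cohort <- smoothed_replicate(x, config, r, bandwidths = bw)
    rows[[r]] <- tryCatch(estimator(rep_cohort), error = function(e) NULL)
  }
  ok <- !vapply(rows, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * B)
    stop(sprintf("bootstrap failed: %d of %d replicates errored", n_failed, B))
  p <- length(rows[[which(ok)[1]]])
  mat <- matrix(NA_real_, B, p)
  colnames(mat) <- names(rows[[which(ok)[1]]])
  for (r in which(ok)) mat[r, ] <- rows[[r]]
  a <- (1 - level) / 2
  list(estimate = apply(mat, 2, median, na.rm = TRUE),
       lower = apply(mat, 2, quantile, probs = a, na.rm = TRUE, names = FALSE),
       upper = apply(mat, 2, quantile, probs = 1 - a, na.rm = TRUE, names = FALSE),
       replicates = mat, n_failed = n_failed, bandwidths = bw)
}
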