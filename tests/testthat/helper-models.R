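# Shared fixtures, all built in code.

# parallel log-log lines (uni-scaling), the simplest valid model
uni_model_3anchor <- function(round = FALSE) {
  synthetic_model(data.frame(q = c(2, 50, 98), alpha = 2, C = c(12, 15, 18)),
                  height_mean = 1.2, height_sd = 0.06,
                  height_range = c(1.0, 1.4), round_to_integers = round)
}

# small deterministic cohort lying near w = 15 h^2.2
noisy_cohort <- function(n = 60, seed = 42, age = 8, sex = "F") {
  set.seed(seed)
  h <- runif(n, 1.0, 1.7)
  w <- 15 * h^2.2 * exp(rnorm(n, 0, 0.15))
  cohort(h * 100, w, age, sex)
}

# exact power-law cohort (zero pinball loss at the truth, every centile)
exact_cohort <- function(C, alpha, n = 200, age = 10, sex = "M") {
  h <- seq(0.9, 1.8, length.out = n)
  cohort(h * 100, C * h^alpha, age, sex)
}

# brute-force pinball oracle: minimum over a (logC, alpha) grid
grid_pinball_min <- function(h, w, tau, alphas, logCs) {
  best <- Inf
  lh <- log(h)
  for (a in alphas) {
    preds <- outer(exp(logCs), exp(a * lh))
    r <- matrix(w, nrow = length(logCs), ncol = length(h), byrow = TRUE) - preds
    loss <- rowSums(ifelse(r >= 0, tau * r, (tau - 1) * r))
    best <- min(best, min(loss))
  }
  best
}

# write a small survey CSV and return its path
write_survey_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}
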