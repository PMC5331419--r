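# Shared fixtures built in code.

# small random regression instance with named columns and row ids
random_instance <- function(n, p, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("c%02d", seq_len(n)), paste0("d", seq_len(p))))
  beta <- rnorm(p)
  y <- 1 + drop(x %*% beta) + rnorm(n, sd = noise_sd)
  list(x = x, y = y, beta = beta)
}

# write a CSV from a character matrix (first column = ids), return the path
write_tmp_csv <- function(header, rows) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(c(header, rows), path)
  path
}

# independent normal-equations OLS oracle (kept free of the package's QR path)
ols_oracle <- function(x, y) {
  xt <- cbind(1, x)
  solve(t(xt) %*% xt, t(xt) %*% y)[, 1]
}

# brute-force leave-one-out Q2 by explicit refitting
q2_loo_refit_oracle <- function(x, y) {
  n <- nrow(x)
  press <- sum(vapply(seq_len(n), function(i) {
    b <- ols_oracle(x[-i, , drop = FALSE], y[-i])
    (y[i] - (b[1] + sum(b[-1] * x[i, ])))^2
  }, numeric(1)))
  1 - press / sum((y - mean(y))^2)
}
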