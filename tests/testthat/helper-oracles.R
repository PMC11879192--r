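## Independent brute-force oracles. These deliberately use literal loops and
## textbook formulas, not the package's vectorised implementations.

## DFT terms by literal summation over segments, one frame at a time.
oracle_fourier_terms <- function(mat, power = "power") {
  n <- ncol(mat)
  s0 <- s1 <- numeric(n)
  for (t in seq_len(n)) {
    x0 <- 0 + 0i
    x1 <- 0 + 0i
    for (k in 0:5) {
      v <- mat[k + 1, t]
      x0 <- x0 + v * exp(-2i * pi * 0 * k / 6)
      x1 <- x1 + v * exp(-2i * pi * 1 * k / 6)
    }
    s0[t] <- if (power == "power") Mod(x0)^2 else Mod(x0)
    s1[t] <- if (power == "power") Mod(x1)^2 else Mod(x1)
  }
  list(s0 = s0, s1 = s1)
}

oracle_cure <- function(mat, power = "power", pooling = "per_frame") {
  ft <- oracle_fourier_terms(mat, power)
  tot <- ft$s0 + ft$s1
  if (pooling == "per_frame") {
    r <- numeric(length(tot))
    for (t in seq_along(tot)) {
      r[t] <- if (tot[t] == 0) 1 else ft$s0[t] / tot[t]
    }
    mean(r)
  } else {
    if (sum(tot) == 0) 1 else sum(ft$s0) / sum(tot)
  }
}

## Positive-increment stretch sum by explicit frame-pair enumeration.
## Windows are 0-based inclusive, matching the package convention.
oracle_stretch <- function(series, ws, we, require_prior_shortening) {
  keep <- numeric(0)
  started <- FALSE
  for (i in (ws + 1):we) {         # 0-based transition ending at frame i
    inc <- series[i + 1] - series[i]
    if (require_prior_shortening) {
      if (started && inc > 0) keep <- c(keep, inc)
      if (!started && inc < 0) started <- TRUE
    } else {
      if (inc > 0) keep <- c(keep, inc)
    }
  }
  sum(keep)
}

## AUC by literal pairwise counting, ties worth 1/2.
oracle_auc <- function(cases, controls) {
  s <- 0
  for (a in cases) {
    for (b in controls) {
      s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  s / (length(cases) * length(controls))
}

## Youden threshold by exhaustive search over all midpoints (plus sentinels),
## tie-broken by highest specificity then lowest threshold.
oracle_youden <- function(cases, controls, direction) {
  v <- sort(unique(c(cases, controls)))
  thr <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
           v[length(v)] + 1)
  best <- NULL
  for (th in thr) {
    if (direction == "greater") {
      sens <- mean(cases >= th); spec <- mean(controls < th)
    } else {
      sens <- mean(cases <= th); spec <- mean(controls > th)
    }
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(threshold = th, j = j, sens = sens, spec = spec)
    }
  }
  best
}

## Two-way ANOVA mean squares by literal double loops.
oracle_icc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_tot <- ss_tot + (m[i, j] - grand)^2
  }
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  list(
    icc2 = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    icc3 = (msr - mse) / (msr + (k - 1) * mse),
    sem = sqrt(mse)
  )
}

## Single-predictor logistic regression by plain Newton-Raphson on the
## log-likelihood, independent of stats::glm.
oracle_logistic <- function(x, y, iter = 50) {
  beta <- c(0, 0)
  X <- cbind(1, x)
  for (it in seq_len(iter)) {
    eta <- X %*% beta
    p <- 1 / (1 + exp(-eta))
    W <- as.vector(p * (1 - p))
    grad <- t(X) %*% (y - p)
    H <- t(X) %*% (X * W)
    beta <- beta + solve(H, grad)
  }
  list(beta = beta[2], se = sqrt(diag(solve(H)))[2])
}
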