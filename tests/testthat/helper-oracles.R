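# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# Exact primal oracle for linear epsilon-SVR: minimizes
# J(beta, b) = 0.5|beta|^2 + C sum(max(0, |y - X beta - b| - eps))
# directly (annealed smoothed-hinge BFGS from several starts, then an
# exact KKT solve on the implied support partition).  Valid for tiny
# instances (p <= 3, N <= ~12); agreement with libsvm was verified
# during development.
svr_primal_oracle <- function(X, y, eps, C, n_starts = 3) {
  p <- ncol(X)
  J_exact <- function(par) {
    r <- y - drop(X %*% par[1:p]) - par[p + 1]
    0.5 * sum(par[1:p]^2) + C * sum(pmax(0, abs(r) - eps))
  }
  J_smooth <- function(par, mu) {
    r <- y - drop(X %*% par[1:p]) - par[p + 1]
    u <- abs(r) - eps
    h <- ifelse(u <= -mu, 0, ifelse(u >= mu, u, (u + mu)^2 / (4 * mu)))
    0.5 * sum(par[1:p]^2) + C * sum(h)
  }
  g_smooth <- function(par, mu) {
    r <- y - drop(X %*% par[1:p]) - par[p + 1]
    u <- abs(r) - eps
    dh <- ifelse(u <= -mu, 0, ifelse(u >= mu, 1, (u + mu) / (2 * mu)))
    w <- -C * dh * sign(r)
    c(par[1:p] + drop(crossprod(X, w)), sum(w))
  }
  polish <- function(par) {
    r <- y - drop(X %*% par[1:p]) - par[p + 1]
    tol_r <- 1e-4 * max(1, eps, max(abs(r)))
    free <- abs(abs(r) - eps) < tol_r
    bound <- abs(r) > eps + tol_r & !free
    s_b <- sign(r[bound]); s_f <- sign(r[free])
    nf <- sum(free)
    beta_b <- if (any(bound)) {
      C * drop(crossprod(X[bound, , drop = FALSE], s_b))
    } else numeric(p)
    if (nf == 0) return(par)
    Xf <- X[free, , drop = FALSE]
    A <- rbind(cbind(tcrossprod(Xf), 1), c(rep(1, nf), 0))
    rhs <- c(y[free] - drop(Xf %*% beta_b) - s_f * eps, -C * sum(s_b))
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) return(par)
    c(beta_b + drop(crossprod(Xf, sol[1:nf])), sol[nf + 1])
  }
  best <- Inf
  starts <- c(list(rep(0, p + 1)),
              lapply(seq_len(n_starts - 1),
                     function(k) stats::rnorm(p + 1, 0, 1.5)))
  for (s0 in starts) {
    par <- s0
    for (mu in c(1e-1, 1e-3, 1e-5, 1e-7)) {
      o <- stats::optim(par, J_smooth, g_smooth, mu = mu, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
      par <- o$par
    }
    best <- min(best, J_exact(par), J_exact(polish(par)))
  }
  best
}

# Jaccard overlap of two logical masks
jaccard <- function(a, b) sum(a & b) / sum(a | b)

# intensity center of mass of an image (rows, cols)
center_of_mass <- function(m) {
  c(sum(row(m) * m), sum(col(m) * m)) / sum(m)
}

# amplitude of a known-frequency sinusoid in a series, by regression
sinusoid_amplitude <- function(x, freq, fs = 1) {
  t <- seq_along(x) / fs
  fit <- stats::lm(x ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# brute-force Pearson r by the textbook covariance formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (stats::sd(x) * stats::sd(y))
}
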