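#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Derivative-free stochastic minimizer with rank-mu covariance update and
#' cumulative step-size adaptation, for box-constrained problems.  The
#' search runs in coordinates normalized to the unit box; candidates
#' outside the box are evaluated at their projection with a quadratic
#' penalty on the violation.
#'
#' @param fn objective, called with a vector in the original coordinates.
#' @param x0 starting point (original coordinates, inside the box).
#' @param lower,upper finite box bounds.
#' @param sigma0 initial step size as a fraction of the box width
#'   (default 0.3).
#' @param lambda population size (default `4 + floor(3 log d)`).
#' @param max_evals evaluation budget.
#' @param tol_fun stop when the per-generation best objectives over the
#'   last `10 + 30 d / lambda` generations span less than this (relative).
#' @param seed integer seed; the optimizer uses its own RNG stream.
#' @return List with `par`, `value`, `evals`, `generations`, and `trace`
#'   (best objective per generation).
#' @export
cma_es <- function(fn, x0, lower, upper, sigma0 = 0.3, lambda = NULL,
                   max_evals = 2000, tol_fun = 1e-12, seed = 1L) {
  d <- length(x0)
  stopifnot(length(lower) == d, length(upper) == d,
            all(is.finite(lower)), all(is.finite(upper)),
            all(upper > lower))
  width <- upper - lower
  to_z <- function(x) (x - lower) / width
  to_x <- function(z) lower + z * width

  eval_pen <- function(z) {
    zc <- pmin(pmax(z, 0), 1)
    f <- fn(to_x(zc))
    if (!is.finite(f)) f <- 1e12
    f + 1e6 * sum((z - zc)^2)
  }

  if (is.null(lambda)) lambda <- 4L + floor(3 * log(d))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)

  cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  cs <- (mueff + 2) / (d + mueff + 5)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  m <- to_z(x0)
  sigma <- sigma0
  C <- diag(d); ps <- numeric(d); pc <- numeric(d)
  B <- diag(d); D <- rep(1, d)
  evals <- 0L; gen <- 0L
  best <- list(z = m, f = eval_pen(m)); evals <- evals + 1L
  trace <- numeric(0)
  hist_len <- ceiling(10 + 30 * d / lambda)

  while (evals + lambda <= max_evals) {
    gen <- gen + 1L
    Z <- matrix(stats::rnorm(d * lambda), nrow = d)
    Y <- B %*% (D * Z)                    # N(0, C) samples
    X <- m + sigma * Y
    f <- apply(X, 2, eval_pen)
    evals <- evals + lambda
    ord <- order(f)
    if (f[ord[1]] < best$f) best <- list(z = X[, ord[1]], f = f[ord[1]])
    trace <- c(trace, f[ord[1]])  # per-generation best (TolFun window)

    ysel <- Y[, ord[seq_len(mu)], drop = FALSE]
    ybar <- drop(ysel %*% w)
    m <- m + sigma * ybar

    # cumulation paths
    Cinv_sqrt_y <- B %*% ((1 / D) * crossprod(B, ybar))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(Cinv_sqrt_y)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * gen)) / chiN < 1.4 + 2 / (d + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ybar

    # covariance update
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * (ysel %*% (w * t(ysel)))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    sigma <- min(sigma, 5)  # cap runaway step size in flat regions

    ev <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(ev$values, 1e-20))
    B <- ev$vectors
    if (max(D) / min(D) > 1e7) {  # condition guard
      C <- diag(d); B <- diag(d); D <- rep(1, d)
    }

    if (length(trace) > hist_len) {
      recent <- trace[(length(trace) - hist_len):length(trace)]
      if (max(recent) - min(recent) < tol_fun * (abs(min(recent)) + 1e-30))
        break
    }
  }

  list(par = to_x(pmin(pmax(best$z, 0), 1)), value = best$f,
       evals = evals, generations = gen, trace = trace)
}
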