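#' Normalized distance objective
#'
#' Weighted sum of squared differences between simulated and observed
#' targets, `sum_i (w_min / w_i) * (X_i - X_exp_i)^2` with `w_i = X_exp_i`
#' and `w_min = min_i w_i`, so the absolute errors of differently scaled
#' observables (pressures, rates, volumes) contribute comparably.
#'
#' @param X Simulated values (numeric vector).
#' @param X_exp Observed target values, all positive, same length as `X`.
#' @return Non-negative scalar; zero iff `X == X_exp`.
#' @examples
#' f_dist(c(110, 50), c(100, 50))   # (50/100) * 10^2 = 50
#' @export
f_dist <- function(X, X_exp) {
  if (length(X) != length(X_exp) || length(X) < 1)
    stop("X and X_exp must be non-empty and of equal length")
  if (any(X_exp <= 0)) stop("X_exp must be positive (weights are X_exp)")
  w <- X_exp
  sum((min(w) / w) * (X - X_exp)^2)
}

#' Quadratic constraint penalty
#'
#' For box constraints `Y_min <= Y_j(t) <= Y_max` sampled over time, the
#' penalty is the double sum of squared bound violations:
#' `sum_t ( sum_j max(0, Y_min_j - Y_j(t))^2 + sum_j max(0, Y_j(t) - Y_max_j)^2 )`.
#'
#' @param series Numeric matrix of sampled constrained quantities, one column
#'   per constraint, one row per time sample (a vector is treated as a
#'   single sample).
#' @param lower,upper Numeric vectors of bounds, one entry per constraint.
#' @return Non-negative scalar; zero iff every sample is within bounds.
#' @export
f_penalty <- function(series, lower, upper) {
  if (is.null(dim(series))) series <- matrix(series, nrow = 1)
  if (ncol(series) != length(lower) || length(lower) != length(upper))
    stop("bounds must match the number of constrained quantities")
  lo <- matrix(lower, nrow(series), ncol(series), byrow = TRUE)
  hi <- matrix(upper, nrow(series), ncol(series), byrow = TRUE)
  sum(pmax(0, lo - series)^2) + sum(pmax(0, series - hi)^2)
}

#' Stochastic ranking of a constrained population
#'
#' Bubble-sort-like ranking used by the stochastic ranking evolution
#' strategy: adjacent individuals are compared by objective value when both
#' are feasible or, with probability `pf`, regardless of feasibility;
#' otherwise by penalty. Feasible-only populations therefore sort purely by
#' objective, and `pf -> 0` sorts infeasible individuals purely by penalty.
#'
#' @param objective Numeric vector of objective values.
#' @param penalty Numeric vector of penalties (0 = feasible).
#' @param pf Probability of comparing by objective for infeasible pairs
#'   (default 0.45).
#' @return Integer permutation ordering the population best-first.
#' @export
stochastic_rank <- function(objective, penalty, pf = 0.45) {
  n <- length(objective)
  if (n == 0) stop("empty population")
  if (length(penalty) != n) stop("objective and penalty lengths differ")
  if (pf <= 0 || pf >= 1) {
    if (pf != 0) stop("pf must lie in [0, 1)")
  }
  idx <- seq_len(n)
  for (sweep in seq_len(n)) {
    swapped <- FALSE
    for (j in seq_len(n - 1)) {
      a <- idx[j]; b <- idx[j + 1]
      both_feasible <- penalty[a] == 0 && penalty[b] == 0
      use_obj <- both_feasible || (stats::runif(1) < pf)
      worse <- if (use_obj) objective[a] > objective[b]
               else penalty[a] > penalty[b]
      if (worse) {
        idx[j] <- b; idx[j + 1] <- a
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  idx
}

#' Constrained minimization by a stochastic ranking evolution strategy
#'
#' A (mu, lambda) evolution strategy with log-normal self-adaptive step
#' sizes, boundary reflection and stochastic-ranking selection, suitable for
#' constrained global optimization of black-box objectives.
#'
#' @param evaluate Function taking a parameter vector and returning
#'   `c(objective, penalty)` (penalty 0 when feasible).
#' @param lower,upper Numeric search-box bounds.
#' @param mu,lambda Parent and offspring population sizes.
#' @param generations Number of generations.
#' @param pf Stochastic-ranking probability (default 0.45).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param init Optional matrix (rows = individuals) injected into the
#'   initial population, e.g. a known good starting point.
#' @return List with `par` (best parameters), `value`, `penalty`,
#'   `feasible`, `evaluations` and `trace` (best value per generation).
#' @export
sres_minimize <- function(evaluate, lower, upper, mu = 30, lambda = 200,
                          generations = 250, pf = 0.45, seed = 1,
                          init = NULL) {
  n <- length(lower)
  if (length(upper) != n || any(lower >= upper)) stop("invalid bounds")
  if (generations < 1 || lambda < 2 || mu < 1 || mu > lambda)
    stop("invalid population configuration")
  set.seed(seed)
  span <- upper - lower
  tau  <- 1 / sqrt(2 * sqrt(n))
  tau0 <- 1 / sqrt(2 * n)

  X <- matrix(stats::runif(lambda * n, lower, upper), lambda, n, byrow = FALSE)
  for (j in seq_len(n)) X[, j] <- stats::runif(lambda, lower[j], upper[j])
  if (!is.null(init)) {
    init <- matrix(init, ncol = n)
    k <- min(nrow(init), lambda)
    X[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                 matrix(lower, k, n, byrow = TRUE)),
                            matrix(upper, k, n, byrow = TRUE))
  }
  S <- matrix(rep(span / sqrt(n), each = lambda), lambda, n)

  evals <- 0L
  eval_pop <- function(X) {
    out <- t(apply(X, 1, function(x) {
      v <- tryCatch(evaluate(x), error = function(e) c(Inf, Inf))
      if (length(v) != 2 || any(is.na(v))) v <- c(Inf, Inf)
      v
    }))
    evals <<- evals + nrow(X)
    out
  }
  reflect <- function(x) {
    for (j in seq_len(n)) {
      while (x[j] < lower[j] || x[j] > upper[j]) {
        if (x[j] < lower[j]) x[j] <- 2 * lower[j] - x[j]
        if (x[j] > upper[j]) x[j] <- 2 * upper[j] - x[j]
      }
    }
    x
  }

  FP <- eval_pop(X)
  best <- NULL
  consider <- function(best, x, f, p) {
    cand <- list(par = x, value = f, penalty = p, feasible = p <= 0)
    if (is.null(best)) return(cand)
    if (cand$feasible && !best$feasible) return(cand)
    if (cand$feasible == best$feasible &&
        (cand$value < best$value ||
         (!cand$feasible && cand$penalty < best$penalty &&
          cand$value <= best$value))) return(cand)
    best
  }
  trace <- numeric(generations)

  for (gen in seq_len(generations)) {
    ord <- stochastic_rank(FP[, 1], FP[, 2], pf = pf)
    for (i in seq_len(lambda)) {
      best <- consider(best, X[ord[i], ], FP[ord[i], 1], FP[ord[i], 2])
    }
    parents  <- ord[seq_len(mu)]
    Xp <- X[parents, , drop = FALSE]
    Sp <- S[parents, , drop = FALSE]
    Xn <- matrix(0, lambda, n); Sn <- matrix(0, lambda, n)
    for (i in seq_len(lambda)) {
      k <- parents_idx <- ((i - 1) %% mu) + 1
      g0 <- stats::rnorm(1)
      Sn[i, ] <- pmin(Sp[k, ] * exp(tau0 * g0 + tau * stats::rnorm(n)),
                      span / 2)
      Xn[i, ] <- reflect(Xp[k, ] + Sn[i, ] * stats::rnorm(n))
    }
    X <- Xn; S <- Sn
    FP <- eval_pop(X)
    trace[gen] <- best$value
  }
  ord <- stochastic_rank(FP[, 1], FP[, 2], pf = pf)
  for (i in seq_len(lambda)) {
    best <- consider(best, X[ord[i], ], FP[ord[i], 1], FP[ord[i], 2])
  }
  c(best, list(evaluations = evals, trace = trace))
}
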