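#' Weighted similarity of the three metrics
#'
#' `S = w_cos * s_cosine + w_frob * s_frobenius + w_sw * (s_sw / 100)`.
#' The sequence similarity is rescaled from percent to [0, 1] before
#' mixing so all three metrics share a scale.
#'
#' @param scores a `score_table` (or data frame with columns `s_cosine`,
#'   `s_frobenius`, `s_sw`).
#' @param weights numeric length-3 vector `(w_cosine, w_frobenius, w_sw)`,
#'   non-negative; normalized to sum 1.
#' @return Numeric vector of weighted similarities, one per row.
#' @export
weighted_similarity <- function(scores, weights) {
  w <- normalize_weights(weights)
  m <- cbind(scores$s_cosine, scores$s_frobenius, scores$s_sw / 100)
  as.numeric(m %*% w)
}

normalize_weights <- function(weights) {
  w <- as.numeric(weights)
  if (length(w) != 3 || any(w < 0) || sum(w) <= 0)
    stop("weights must be 3 non-negative values with positive sum")
  w / sum(w)
}

#' Weight-selection objective
#'
#' Pearson correlation of the weighted similarity against each individual
#' metric column, and their average `O` — the quantity maximized when
#' choosing weights, so that the composite score stays faithful to all
#' three metrics at once.
#'
#' @inheritParams weighted_similarity
#' @return Named numeric vector `c(O, C_cosine, C_frobenius, C_sw)`.
#' @export
score_objective <- function(weights, scores) {
  if (nrow(scores) < 3) stop("need at least 3 score rows")
  for (col in c("s_cosine", "s_frobenius", "s_sw"))
    if (stats::sd(scores[[col]]) == 0)
      stop("undefined correlation: column ", col, " is constant")
  s <- weighted_similarity(scores, weights)
  if (stats::sd(s) == 0)
    stop("undefined correlation: weighted similarity is constant")
  cc <- c(C_cosine = stats::cor(s, scores$s_cosine),
          C_frobenius = stats::cor(s, scores$s_frobenius),
          C_sw = stats::cor(s, scores$s_sw))
  c(O = mean(cc), cc)
}

# ---- Gaussian-process machinery (zero prior mean, squared-exponential
# kernel, noise-free observations with a small jitter) ----

se_kernel <- function(x1, x2, sigma2, ell) {
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * tcrossprod(x1, x2)
  sigma2 * exp(-pmax(d2, 0) / (2 * ell^2))
}

#' Fit a Gaussian-process surrogate
#'
#' Zero-mean GP with squared-exponential covariance
#' `k(x, x') = sigma^2 exp(-|x - x'|^2 / (2 l^2))` over observed
#' weight/objective pairs. When `optimize_hyper` is `TRUE` the signal
#' variance and length-scale are chosen by maximizing the log marginal
#' likelihood; a diagonal jitter (1e-10, escalated if needed) keeps the
#' kernel matrix invertible.
#'
#' @param x numeric matrix of observed points (rows).
#' @param y numeric vector of observed objective values.
#' @param sigma2,ell initial hyperparameters.
#' @param optimize_hyper refit hyperparameters by marginal likelihood?
#' @return A `gp_model` list.
#' @export
gp_fit <- function(x, y, sigma2 = 1, ell = 0.2, optimize_hyper = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("need at least one observation")
  chol_with_jitter <- function(k) {
    jit <- 1e-10
    repeat {
      ch <- tryCatch(chol(k + diag(jit, nrow(k))), error = function(e) NULL)
      if (!is.null(ch)) return(list(chol = ch, jitter = jit))
      jit <- jit * 100
      if (jit > 1e-2) stop("kernel matrix singular beyond repair")
    }
  }
  nll <- function(par) {
    s2 <- exp(par[1]); l <- exp(par[2])
    k <- se_kernel(x, x, s2, l)
    cj <- tryCatch(chol_with_jitter(k), error = function(e) NULL)
    if (is.null(cj)) return(1e10)
    ch <- cj$chol
    alpha <- backsolve(ch, forwardsolve(t(ch), y))
    as.numeric(0.5 * sum(y * alpha) + sum(log(diag(ch))))
  }
  if (optimize_hyper && nrow(x) >= 3 && stats::sd(y) > 0) {
    fit <- tryCatch(
      stats::optim(log(c(sigma2, ell)), nll, method = "L-BFGS-B",
                   lower = log(c(1e-6, 0.02)), upper = log(c(1e3, 5))),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value)) {
      sigma2 <- exp(fit$par[1]); ell <- exp(fit$par[2])
    }
  }
  k <- se_kernel(x, x, sigma2, ell)
  cj <- chol_with_jitter(k)
  alpha <- backsolve(cj$chol, forwardsolve(t(cj$chol), y))
  structure(list(x = x, y = y, sigma2 = sigma2, ell = ell,
                 chol = cj$chol, alpha = alpha, jitter = cj$jitter),
            class = "gp_model")
}

#' GP posterior mean and variance at new points
#'
#' @param model a `gp_model` from [gp_fit()].
#' @param x_new matrix of prediction points (rows).
#' @return List with numeric vectors `mean` and `variance`. At an observed
#'   point the posterior collapses onto the observation; far from all
#'   observations it reverts to the zero-mean prior with variance
#'   `sigma^2`.
#' @export
gp_predict <- function(model, x_new) {
  x_new <- as.matrix(x_new)
  ks <- se_kernel(x_new, model$x, model$sigma2, model$ell)
  mu <- as.numeric(ks %*% model$alpha)
  v <- forwardsolve(t(model$chol), t(ks))
  var <- pmax(model$sigma2 - colSums(v^2), 0)
  list(mean = mu, variance = var)
}

#' Expected improvement acquisition (maximization form)
#'
#' `EI(x) = (mu - f_best) Phi(z) + s phi(z)` with `z = (mu - f_best)/s`,
#' the expected amount by which the GP posterior at `x` beats the incumbent
#' best objective value. With zero posterior variance it reduces to
#' `max(mu - f_best, 0)`.
#'
#' @param mean,variance GP posterior mean and variance (vectors).
#' @param f_best incumbent best observed objective value.
#' @return Non-negative numeric vector of EI values.
#' @export
expected_improvement <- function(mean, variance, f_best) {
  s <- sqrt(pmax(variance, 0))
  improve <- mean - f_best
  out <- pmax(improve, 0)
  pos <- s > 1e-12
  z <- improve[pos] / s[pos]
  out[pos] <- improve[pos] * stats::pnorm(z) + s[pos] * stats::dnorm(z)
  pmax(out, 0)
}

# Internal: n uniform points on the 2-simplex (Dirichlet(1,1,1)).
sample_simplex <- function(n) {
  g <- matrix(stats::rexp(3 * n), ncol = 3)
  g / rowSums(g)
}

#' Choose metric weights by Bayesian optimization
#'
#' Maximizes the average correlation objective ([score_objective()]) over
#' the weight simplex. The first `n_random` iterations sample the simplex
#' uniformly to seed the surrogate; each of the `n_guided` iterations
#' refits the GP, scores a fresh candidate set by expected improvement and
#' evaluates the objective at the EI argmax. Defaults follow the published
#' budget of 15 random + 100 guided = 115 iterations.
#'
#' @param scores a `score_table`.
#' @param n_random,n_guided iteration budgets.
#' @param n_candidates EI candidate points per guided iteration.
#' @param seed optional integer; makes the run fully reproducible.
#' @return List of class `weight_opt`: `weights` (normalized, best
#'   objective), `objective` (its `O`), `correlations`, and `trace` (one
#'   row per iteration with phase, weights, objective and running best).
#' @export
optimize_weights <- function(scores, n_random = 15L, n_guided = 100L,
                             n_candidates = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- sample_simplex(n_random)
  obj <- t(apply(x, 1, score_objective, scores = scores))
  phase <- rep("random", n_random)
  for (it in seq_len(n_guided)) {
    model <- gp_fit(x, obj[, "O"])
    cand <- sample_simplex(n_candidates)
    post <- gp_predict(model, cand)
    ei <- expected_improvement(post$mean, post$variance, max(obj[, "O"]))
    pick <- cand[which.max(ei), , drop = FALSE]
    x <- rbind(x, pick)
    obj <- rbind(obj, score_objective(pick, scores))
    phase <- c(phase, "guided")
  }
  best_so_far <- cummax(obj[, "O"])
  best <- which.max(obj[, "O"])
  trace <- data.frame(iteration = seq_len(nrow(x)), phase = phase,
                      w_cosine = x[, 1], w_frobenius = x[, 2], w_sw = x[, 3],
                      O = obj[, "O"], C_cosine = obj[, "C_cosine"],
                      C_frobenius = obj[, "C_frobenius"], C_sw = obj[, "C_sw"],
                      best_so_far = best_so_far)
  structure(list(weights = normalize_weights(x[best, ]),
                 objective = obj[best, "O"],
                 correlations = obj[best, c("C_cosine", "C_frobenius", "C_sw")],
                 trace = trace),
            class = "weight_opt")
}

#' @export
print.weight_opt <- function(x, ...) {
  cat(sprintf(paste0("weight_opt: w_cosine=%.3f w_frobenius=%.3f w_sw=%.3f",
                     " (O=%.4f, %d iterations)\n"),
              x$weights[1], x$weights[2], x$weights[3], x$objective,
              nrow(x$trace)))
  invisible(x)
}

#' Exhaustive simplex-grid search of the weight objective
#'
#' Brute-force reference for [optimize_weights()]: evaluates the objective
#' at every grid point `(i, j, k)/m` on the simplex with step `1/m`.
#'
#' @param scores a `score_table`.
#' @param step grid spacing (default 0.02).
#' @return List with `weights` and `objective` of the best grid point.
#' @export
grid_search_weights <- function(scores, step = 0.02) {
  m <- round(1 / step)
  pts <- list()
  for (i in 0:m) for (j in 0:(m - i)) pts[[length(pts) + 1L]] <- c(i, j, m - i - j)
  w <- do.call(rbind, pts) / m
  w <- w[rowSums(w) > 0, , drop = FALSE]
  mat <- cbind(scores$s_cosine, scores$s_frobenius, scores$s_sw / 100)
  s_all <- mat %*% t(w)            # rows x grid points
  o <- vapply(seq_len(ncol(s_all)), function(k) {
    s <- s_all[, k]
    if (stats::sd(s) == 0) return(-Inf)
    mean(c(stats::cor(s, scores$s_cosine), stats::cor(s, scores$s_frobenius),
           stats::cor(s, scores$s_sw)))
  }, numeric(1))
  best <- which.max(o)
  list(weights = w[best, ], objective = o[best])
}
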