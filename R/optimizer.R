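# Sequential model-based maximization on the unit hypercube.
#
# A small Gaussian-process surrogate (squared-exponential kernel, median
# pairwise-distance lengthscale, jitter-regularized Cholesky) with expected
# improvement maximized over a random candidate pool. This is the engine
# behind optimize_weights(); it is deliberately self-contained and
# deterministic under local_seed().

# Run code with a temporary RNG state; the caller's state is restored.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Derive a distinct 31-bit sub-seed from a base seed and a stream label.
derive_seed <- function(seed, ...) {
  parts <- c(seed, vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
  }, 0))
  as.integer((sum(parts * seq_along(parts) * 2654435761) %% 2147483629) + 1)
}

smbo_maximize <- function(fn, dim, budget, seed, first = NULL,
                          n_candidates = 256L) {
  stopifnot(budget >= 1L, dim >= 1L)
  local_seed(seed, {
    X <- matrix(numeric(0), 0L, dim)
    y <- numeric(0)
    push <- function(x) {
      X <<- rbind(X, x)
      y <<- c(y, fn(x))
    }
    if (!is.null(first)) push(first)
    n_init <- min(budget - nrow(X), max(4L, 2L * dim))
    if (n_init > 0L) {
      # jittered latin-hypercube initial design: each column a permutation
      design <- vapply(seq_len(dim), function(j) {
        (sample(n_init) - stats::runif(n_init)) / n_init
      }, numeric(n_init))
      if (n_init == 1L) design <- matrix(design, 1L, dim)
      for (i in seq_len(n_init)) push(design[i, ])
    }
    while (nrow(X) < budget) {
      cand <- propose_candidates(X, y, n_candidates, dim)
      scores <- tryCatch(gp_ei(X, y, cand), error = function(e) NULL)
      pick <- if (is.null(scores) || all(!is.finite(scores))) {
        sample.int(nrow(cand), 1L)
      } else {
        which.max(scores)
      }
      push(cand[pick, ])
    }
    best <- which.max(y)
    list(x = X[best, ], value = y[best], X = X, y = y)
  })
}

propose_candidates <- function(X, y, n, dim) {
  n_explore <- ceiling(n / 2)
  cand <- matrix(stats::runif(n_explore * dim), n_explore, dim)
  # exploit: Gaussian perturbations of the incumbent, clipped to [0,1]
  inc <- X[which.max(y), ]
  pert <- matrix(stats::rnorm((n - n_explore) * dim, mean = rep(inc, each = n - n_explore),
                              sd = 0.15), n - n_explore, dim)
  rbind(cand, pmin(pmax(pert, 0), 1))
}

# Expected improvement of candidates under a GP fit to (X, y).
gp_ei <- function(X, y, cand) {
  if (stats::var(y) < 1e-12) return(rep(NA_real_, nrow(cand)))
  mu_y <- mean(y); sd_y <- stats::sd(y)
  ys <- (y - mu_y) / sd_y
  d2 <- as.matrix(stats::dist(X))^2
  ell2 <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(ell2) || ell2 <= 0) ell2 <- ncol(X) / 4
  K <- exp(-0.5 * d2 / ell2) + diag(1e-6 + 1e-4, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, ys, transpose = TRUE))
  cross2 <- outer(rowSums(cand^2), rowSums(X^2), "+") - 2 * cand %*% t(X)
  Ks <- exp(-0.5 * pmax(cross2, 0) / ell2)
  mu <- as.numeric(Ks %*% alpha)
  v <- backsolve(L, t(Ks), transpose = TRUE)
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  best <- max(ys)
  z <- (mu - best) / s
  (mu - best) * stats::pnorm(z) + s * stats::dnorm(z)
}
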