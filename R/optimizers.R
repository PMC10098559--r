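ALGORITHMS <- c("pso", "cso", "fa", "ba", "fpo", "woa", "gwo")

#' Search configuration for a metaheuristic run
#'
#' All seven algorithms share one contract: `N` agents move through the
#' continuous box `[0,1]^D` for `T` iterations, each position is binarized
#' into a feature mask and scored by the wrapper cost, out-of-box moves are
#' clamped, and the best cost ever evaluated is recorded (elitism). Defaults
#' `T = 100`, `N = 10`.
#'
#' @param algorithm One of `"pso"`, `"cso"`, `"fa"`, `"ba"`, `"fpo"`,
#'   `"woa"`, `"gwo"`.
#' @param T Iteration count.
#' @param N Population size (>= 2; GWO needs >= 3).
#' @param seed Run seed; drives initialization, all per-iteration draws, and
#'   (unless pinned in the cost spec) the holdout split.
#' @param params Named list overriding the algorithm's default parameters,
#'   see [default_params()].
#' @return An object of class `search_config`.
#' @export
search_config <- function(algorithm, T = 100, N = 10, seed = 1L,
                          params = list()) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  if (T < 1) stop_param("T must be >= 1")
  if (N < 2) stop_param("N must be >= 2")
  if (algorithm %in% c("gwo", "fpo") && N < 3)
    stop_param(algorithm, " needs N >= 3")
  p <- default_params(algorithm)
  unknown <- setdiff(names(params), names(p))
  if (length(unknown)) stop_param("unknown parameter(s) for ", algorithm,
                                  ": ", paste(unknown, collapse = ", "))
  p[names(params)] <- params
  structure(list(algorithm = algorithm, T = as.integer(T), N = as.integer(N),
                 seed = as.integer(seed), params = p),
            class = "search_config")
}

#' Default per-algorithm parameters
#'
#' PSO: the default `preset = "conventional"` uses inertia decaying linearly
#' from 0.9 to 0.4, both acceleration coefficients 2, velocity clamped to
#' half the box width — the standard, convergent configuration.
#' `preset = "literal"` instead applies the literally published values
#' (inertia 2, coefficients 1 and 2, no velocity clamp); that setting makes
#' the velocity recursion divergent, pinning particles to box corners, and is
#' kept only for comparison. CSO: step size 1, Lévy exponent 1.5, abandonment
#' fraction 0.25. FA: base attractiveness 1, absorption 1, randomization
#' weight 1. BA: frequency range 0 to 2, initial loudness 2, loudness decay
#' and pulse-rate growth 0.9, pulse rates starting at 0.5. FPO: Lévy exponent
#' 1.5, switch probability 0.8, step scale 1. WOA: spiral constant 1. GWO has
#' no free parameters beyond the shared `T`, `N`.
#'
#' @param algorithm Algorithm name.
#' @return Named list of defaults.
#' @export
default_params <- function(algorithm) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  switch(algorithm,
    pso = list(inertia = 2, a1 = 1, a2 = 2, vmax = 0.5,
               preset = "conventional"),
    cso = list(alpha_step = 1, lambda = 1.5, pa = 0.25),
    fa  = list(beta0 = 1, gamma = 1, alpha_rand = 1),
    ba  = list(fmin = 0, fmax = 2, A0 = 2, loudness_decay = 0.9,
               pulse_growth = 0.9, pulse_rate0 = 0.5),
    fpo = list(lambda = 1.5, p_switch = 0.8, alpha_step = 1),
    woa = list(b = 1),
    gwo = list()
  )
}

#' Mantegna Lévy-flight steps
#'
#' Heavy-tailed random steps u / |v|^(1/lambda) with u ~ N(0, sigma_u^2),
#' v ~ N(0, 1) and sigma_u from the closed-form gamma expression, used for
#' global exploration in cuckoo search and flower pollination.
#'
#' @param lambda Tail exponent, in (1, 2].
#' @param n Number of draws.
#' @return Numeric vector of `n` steps.
#' @export
levy_sample <- function(lambda, n) {
  if (!(lambda > 1 && lambda <= 2)) stop_param("lambda must be in (1, 2]")
  sigma_u <- levy_sigma(lambda)
  u <- stats::rnorm(n, 0, sigma_u)
  v <- stats::rnorm(n)
  u / abs(v)^(1 / lambda)
}

#' @rdname levy_sample
#' @export
levy_sigma <- function(lambda) {
  (gamma(1 + lambda) * sin(pi * lambda / 2) /
     (gamma((1 + lambda) / 2) * lambda * 2^((lambda - 1) / 2)))^(1 / lambda)
}

# ---- Single-step update kernels -------------------------------------------
# Pure functions of their inputs (all random draws passed in explicitly), so
# each published update rule can be checked against hand arithmetic.

#' Metaheuristic update kernels
#'
#' The deterministic cores of the position-update rules, with every random
#' draw passed in as an argument. The step functions call these; tests can
#' hand-evaluate them.
#'
#' `pso_velocity_update`: v' = inertia*v + a1*b1*(pbest - x) + a2*b2*(gbest - x).
#'
#' `fa_attraction_move`: x + beta0*exp(-gamma*r^2)*(xj - x) + alpha_rand*eps,
#' with r the Euclidean distance between x and xj.
#'
#' `fpo_global_move`: x + alpha_step * L * (gbest - x).
#'
#' `woa_spiral_move`: |xstar - x| * exp(b*l) * cos(2*pi*l) + xstar.
#'
#' `gwo_position_update`: mean over the three leaders of
#' x_l - A_l * |C_l * x_l - x|.
#'
#' `ba_frequency`: fmin + (fmax - fmin) * beta.
#'
#' @param v,x,pbest,gbest,xj,xstar Numeric vectors (positions/velocity).
#' @param inertia,a1,a2,b1,b2,beta0,gamma,alpha_rand,eps,alpha_step,L,b,l,beta,fmin,fmax
#'   Scalars or conformable vectors per the formulas above.
#' @param leaders 3 x D matrix of leader positions (best, second, third).
#' @param A,C 3 x D matrices of coefficient draws.
#' @return The updated velocity or position vector (`ba_frequency`: scalar).
#' @name update-kernels
NULL

#' @rdname update-kernels
#' @export
pso_velocity_update <- function(v, x, pbest, gbest, inertia, a1, a2, b1, b2) {
  inertia * v + a1 * b1 * (pbest - x) + a2 * b2 * (gbest - x)
}

#' @rdname update-kernels
#' @export
fa_attraction_move <- function(x, xj, beta0, gamma, alpha_rand = 0, eps = 0) {
  r2 <- sum((x - xj)^2)
  x + beta0 * exp(-gamma * r2) * (xj - x) + alpha_rand * eps
}

#' @rdname update-kernels
#' @export
fpo_global_move <- function(x, gbest, alpha_step, L) {
  x + alpha_step * L * (gbest - x)
}

#' @rdname update-kernels
#' @export
woa_spiral_move <- function(x, xstar, b, l) {
  abs(xstar - x) * exp(b * l) * cos(2 * pi * l) + xstar
}

#' @rdname update-kernels
#' @export
gwo_position_update <- function(x, leaders, A, C) {
  stopifnot(nrow(leaders) == 3)
  cand <- leaders - A * abs(C * leaders - rep(x, each = 3))
  colMeans(cand)
}

#' @rdname update-kernels
#' @export
ba_frequency <- function(beta, fmin = 0, fmax = 2) {
  fmin + (fmax - fmin) * beta
}

# ---- Per-algorithm iteration steps ----------------------------------------
# Each step advances the whole population once, evaluating moved positions
# through `obj` (which records the elitist best as a side effect) and
# applying the algorithm's own acceptance rule.

step_pso <- function(st, obj, p, t, T) {
  N <- nrow(st$X); D <- ncol(st$X)
  conventional <- !identical(p$preset, "literal")
  w <- if (conventional) 0.9 - 0.5 * (t - 1) / max(1, T - 1) else p$inertia
  a1 <- if (conventional) 2 else p$a1
  a2 <- if (conventional) 2 else p$a2
  for (i in seq_len(N)) {
    b1 <- stats::runif(D); b2 <- stats::runif(D)
    v <- pso_velocity_update(st$V[i, ], st$X[i, ], st$P[i, ], st$gbest,
                             w, a1, a2, b1, b2)
    if (conventional) { v[v > p$vmax] <- p$vmax; v[v < -p$vmax] <- -p$vmax }
    st$V[i, ] <- v
    st$X[i, ] <- clamp01(st$X[i, ] + v)
    f <- obj(st$X[i, ])$J
    st$fitness[i] <- f
    if (f < st$pf[i]) { st$P[i, ] <- st$X[i, ]; st$pf[i] <- f }
    if (f < st$gf) { st$gbest <- st$X[i, ]; st$gf <- f }
  }
  st
}

step_cso <- function(st, obj, p, t, T) {
  N <- nrow(st$X); D <- ncol(st$X)
  for (i in seq_len(N)) {
    cand <- clamp01(st$X[i, ] + p$alpha_step * levy_sample(p$lambda, D))
    f <- obj(cand)$J
    j <- sample.int(N, 1)
    if (f < st$fitness[j]) { st$X[j, ] <- cand; st$fitness[j] <- f }
  }
  n_ab <- floor(p$pa * N)
  if (n_ab > 0) {
    worst <- order(st$fitness, decreasing = TRUE)[seq_len(n_ab)]
    keep <- setdiff(seq_len(N), worst)
    for (i in worst) {
      base <- if (length(keep)) keep[sample.int(length(keep), 1)] else i
      cand <- clamp01(st$X[base, ] + p$alpha_step * levy_sample(p$lambda, D))
      st$X[i, ] <- cand
      st$fitness[i] <- obj(cand)$J
    }
  }
  st
}

step_fa <- function(st, obj, p, t, T) {
  N <- nrow(st$X); D <- ncol(st$X)
  fit <- st$fitness            # intensities from the previous evaluation
  Xold <- st$X
  brightest <- which.min(fit)
  for (i in seq_len(N)) {
    if (i == brightest) next
    for (j in seq_len(N)) {
      if (fit[j] < fit[i]) {
        eps <- stats::runif(D, -0.5, 0.5)
        st$X[i, ] <- fa_attraction_move(st$X[i, ], Xold[j, ], p$beta0,
                                        p$gamma, p$alpha_rand, eps)
      }
    }
    st$X[i, ] <- clamp01(st$X[i, ])
  }
  st$X[brightest, ] <- clamp01(Xold[brightest, ] +
                               p$alpha_rand * stats::runif(D, -0.5, 0.5))
  for (i in seq_len(N)) st$fitness[i] <- obj(st$X[i, ])$J
  st
}

step_ba <- function(st, obj, p, t, T) {
  N <- nrow(st$X); D <- ncol(st$X)
  for (i in seq_len(N)) {
    f_i <- ba_frequency(stats::runif(1), p$fmin, p$fmax)
    st$V[i, ] <- st$V[i, ] + (st$X[i, ] - st$xbest) * f_i
    cand <- clamp01(st$X[i, ] + st$V[i, ])
    if (stats::runif(1) < st$r[i])
      cand <- clamp01(st$xbest + stats::runif(D, -1, 1) * mean(st$A))
    f_c <- obj(cand)$J
    # loudness/pulse-gated acceptance against the bat's own fitness (the
    # wrapper-toolbox convention); improvement must be strict
    if (stats::runif(1) < st$A[i] && f_c < st$fitness[i]) {
      st$X[i, ] <- cand
      st$fitness[i] <- f_c
      st$A[i] <- p$loudness_decay * st$A[i]
      st$r[i] <- p$pulse_rate0 * (1 - exp(-p$pulse_growth * t))
    }
    if (f_c < st$fbest) { st$fbest <- f_c; st$xbest <- cand }
  }
  st
}

step_fpo <- function(st, obj, p, t, T) {
  N <- nrow(st$X); D <- ncol(st$X)
  for (i in seq_len(N)) {
    if (stats::runif(1) < p$p_switch) {
      L <- levy_sample(p$lambda, D)
      cand <- fpo_global_move(st$X[i, ], st$gbest, p$alpha_step, L)
    } else {
      eps <- stats::runif(1)
      jk <- sample(setdiff(seq_len(N), i), 2)
      cand <- st$X[i, ] + eps * (st$X[jk[1], ] - st$X[jk[2], ])
    }
    cand <- clamp01(cand)
    f <- obj(cand)$J
    if (f < st$fitness[i]) { st$X[i, ] <- cand; st$fitness[i] <- f }
    if (f < st$gf) { st$gbest <- cand; st$gf <- f }
  }
  st
}

step_woa <- function(st, obj, p, t, T) {
  N <- nrow(st$X); D <- ncol(st$X)
  a <- 2 * (1 - t / T)
  for (i in seq_len(N)) {
    # coefficient vectors drawn per dimension, as in the reference code;
    # the shrinking-encirclement branch is decided on the mean |A|
    A <- 2 * a * stats::runif(D) - a
    C <- 2 * stats::runif(D)
    if (stats::runif(1) < 0.5) {
      ref <- if (mean(abs(A)) < 1) st$xbest else st$X[sample.int(N, 1), ]
      cand <- ref - A * abs(C * ref - st$X[i, ])
    } else {
      l <- stats::runif(1, -1, 1)
      cand <- woa_spiral_move(st$X[i, ], st$xbest, p$b, l)
    }
    st$X[i, ] <- clamp01(cand)
    st$fitness[i] <- obj(st$X[i, ])$J
    if (st$fitness[i] < st$fbest) {
      st$fbest <- st$fitness[i]; st$xbest <- st$X[i, ]
    }
  }
  st
}

step_gwo <- function(st, obj, p, t, T) {
  N <- nrow(st$X); D <- ncol(st$X)
  a <- 2 - 2 * t / T
  for (i in seq_len(N)) {
    A <- matrix(2 * a * stats::runif(3 * D) - a, 3, D)
    C <- matrix(2 * stats::runif(3 * D), 3, D)
    st$X[i, ] <- clamp01(gwo_position_update(st$X[i, ], st$leaders, A, C))
    st$fitness[i] <- obj(st$X[i, ])$J
    st <- gwo_update_leaders(st, st$X[i, ], st$fitness[i])
  }
  st
}

gwo_update_leaders <- function(st, x, f) {
  if (f < st$lf[1]) {
    st$leaders[3, ] <- st$leaders[2, ]; st$lf[3] <- st$lf[2]
    st$leaders[2, ] <- st$leaders[1, ]; st$lf[2] <- st$lf[1]
    st$leaders[1, ] <- x; st$lf[1] <- f
  } else if (f < st$lf[2]) {
    st$leaders[3, ] <- st$leaders[2, ]; st$lf[3] <- st$lf[2]
    st$leaders[2, ] <- x; st$lf[2] <- f
  } else if (f < st$lf[3]) {
    st$leaders[3, ] <- x; st$lf[3] <- f
  }
  st
}

#' Run one metaheuristic feature-selection search
#'
#' Initializes `N` positions uniformly in `[0,1]^D`, evaluates them, then
#' performs `T` iteration steps of the configured algorithm, scoring every
#' visited position with the wrapper cost on one fixed stratified holdout
#' split (derived from the run seed unless pinned via
#' `cost_spec(split_seed=)`). Cost evaluations are cached per mask — the cost
#' is a pure function of the mask — and the best mask ever evaluated is
#' returned (elitism), together with the non-increasing best-cost curve.
#' Identical inputs give a bit-identical result.
#'
#' @param table A `feature_table`.
#' @param config A [search_config()].
#' @param spec A [cost_spec()].
#' @return A `run_result`: list with `algorithm`, `best_mask`, `best_cost`,
#'   `best_accuracy`, `n_selected`, `curve` (length `T`), `evaluations`,
#'   `seed`.
#' @export
run_optimizer <- function(table, config, spec = cost_spec()) {
  stopifnot(inherits(table, "feature_table"),
            inherits(config, "search_config"), inherits(spec, "cost_spec"))
  D <- ncol(table$values)
  if (is.null(spec$split_seed)) {
    spec$split_seed <- derive_seed(config$seed, 77L)
  }
  split <- make_split(table, spec)

  cache <- new.env(parent = emptyenv(), hash = TRUE)
  best <- list(J = Inf, mask = NULL, accuracy = NA_real_, n_selected = NA)
  n_eval <- 0L
  obj <- function(position) {
    mask <- binarize(position, spec$binarize_threshold)
    key <- paste(mask$bits, collapse = "")
    res <- cache[[key]]
    if (is.null(res)) {
      res <- evaluate_cost(mask, table, split, spec)
      cache[[key]] <- res
    }
    n_eval <<- n_eval + 1L
    if (res$J < best$J)
      best <<- list(J = res$J, mask = mask, accuracy = res$accuracy,
                    n_selected = res$n_selected)
    res
  }

  alg <- config$algorithm
  p <- config$params
  T <- config$T; N <- config$N
  set.seed(derive_seed(config$seed, 1L))

  X <- matrix(stats::runif(N * D), N, D)
  fitness <- numeric(N)
  for (i in seq_len(N)) fitness[i] <- obj(X[i, ])$J
  st <- list(X = X, fitness = fitness)
  k <- which.min(fitness)
  if (alg == "pso") {
    st$V <- matrix(0, N, D); st$P <- X; st$pf <- fitness
    st$gbest <- X[k, ]; st$gf <- fitness[k]
  } else if (alg == "ba") {
    st$V <- matrix(0, N, D)
    st$A <- rep(p$A0, N)
    st$r <- rep(p$pulse_rate0, N)
    st$xbest <- X[k, ]; st$fbest <- fitness[k]
  } else if (alg == "fpo") {
    st$gbest <- X[k, ]; st$gf <- fitness[k]
  } else if (alg == "woa") {
    st$xbest <- X[k, ]; st$fbest <- fitness[k]
  } else if (alg == "gwo") {
    ord <- order(fitness)[1:3]
    st$leaders <- X[ord, , drop = FALSE]
    st$lf <- fitness[ord]
  }

  step_fn <- switch(alg, pso = step_pso, cso = step_cso, fa = step_fa,
                    ba = step_ba, fpo = step_fpo, woa = step_woa,
                    gwo = step_gwo)
  curve <- numeric(T)
  for (t in seq_len(T)) {
    st <- step_fn(st, obj, p, t, T)
    curve[t] <- best$J
  }

  structure(list(algorithm = alg, best_mask = best$mask, best_cost = best$J,
                 best_accuracy = best$accuracy, n_selected = best$n_selected,
                 curve = curve, evaluations = n_eval, seed = config$seed,
                 split = split),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf(
    "<run_result> %s: J = %.5f, accuracy = %.3f, %d features, %d evaluations\n",
    x$algorithm, x$best_cost, x$best_accuracy, x$n_selected, x$evaluations))
  invisible(x)
}
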