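test_that("Mantegna Lévy steps use the closed-form sigma and are heavy-tailed", {
  # independent log-gamma evaluation of the closed form, frozen
  lam <- 1.5
  sigma_ref <- exp((lgamma(1 + lam) + log(sin(pi * lam / 2)) -
                    lgamma((1 + lam) / 2) - log(lam) -
                    (lam - 1) / 2 * log(2)) / lam)
  expect_equal(levy_sigma(1.5), sigma_ref, tolerance = 1e-14)
  expect_equal(levy_sigma(1.5), 0.696574502557697, tolerance = 1e-12)

  s1 <- nirselect:::with_seed(99, levy_sample(1.5, 1e5))
  s2 <- nirselect:::with_seed(99, levy_sample(1.5, 1e5))
  expect_identical(s1, s2)
  expect_gt(max(abs(s1)), 50 * stats::median(abs(s1)))
  expect_error(levy_sample(0.9, 10), "lambda")
  expect_error(levy_sample(2.5, 10), "lambda")
})

test_that("update kernels reproduce hand-derived single-step values", {
  # PSO: X=0.5, V=0, pbest=0.5, gbest=0.9, inertia=2, a1=1, a2=2, b1=b2=0.5
  v <- pso_velocity_update(0, 0.5, 0.5, 0.9, 2, 1, 2, 0.5, 0.5)
  expect_equal(v, 0.4, tolerance = 1e-12)
  expect_equal(0.5 + v, 0.9, tolerance = 1e-12)
  # fixed point: at pbest = gbest with zero velocity nothing moves
  expect_equal(pso_velocity_update(0, 0.5, 0.5, 0.5, 2, 1, 2, 0.7, 0.3), 0)

  # FA: dimmer firefly at 0.2 attracted to 0.8 (r^2 = 0.36), no random term
  expect_equal(fa_attraction_move(0.2, 0.8, beta0 = 1, gamma = 1),
               0.2 + exp(-0.36) * 0.6, tolerance = 1e-12)
  # r = 0 gives full attractiveness beta0; gamma -> Inf kills the attraction
  expect_equal(fa_attraction_move(0.4, 0.4, 1, 1), 0.4)
  expect_equal(fa_attraction_move(0.2, 0.8, 1, 1e12), 0.2)

  # FPO global pollination: x=0.4, g*=0.8, alpha=1, L=0.5
  expect_equal(fpo_global_move(0.4, 0.8, 1, 0.5), 0.6, tolerance = 1e-12)
  expect_equal(fpo_global_move(0.8, 0.8, 1, 123), 0.8)   # x = g* fixed point

  # WOA spiral: x=0.2, x*=0.6, b=1, l=0 -> D'=0.4, 0.4*e^0*cos(0)+0.6 = 1
  expect_equal(woa_spiral_move(0.2, 0.6, 1, 0), 1.0, tolerance = 1e-12)
  expect_equal(woa_spiral_move(0.6, 0.6, 1, 0.33), 0.6)  # D' = 0 fixed point

  # GWO: leaders (0.9, 0.8, 0.7), r1 = r2 = 0.5 at t=0 -> A=0, C=1
  a <- 2                                   # iteration-0 control value
  A <- matrix(2 * a * 0.5 - a, 3, 1)       # = 0
  C <- matrix(2 * 0.5, 3, 1)               # = 1
  expect_equal(gwo_position_update(0.2, matrix(c(0.9, 0.8, 0.7), 3, 1), A, C),
               0.8, tolerance = 1e-12)
  # all leaders at x with A=0, C=1: fixed point
  expect_equal(gwo_position_update(0.3, matrix(0.3, 3, 1), A, C), 0.3)

  # BA frequency range endpoints (Table-1 values)
  expect_equal(ba_frequency(1, 0, 2), 2)
  expect_equal(ba_frequency(0, 0, 2), 0)
})

test_that("every algorithm keeps positions inside the unit box", {
  ft <- make_d8_table(5)
  spec <- cost_spec(split_seed = 50)
  split <- make_split(ft, spec)
  obj <- function(pos) evaluate_cost(pos, ft, split, spec)
  for (alg in c("pso", "cso", "fa", "ba", "fpo", "woa", "gwo")) {
    p <- default_params(alg)
    set.seed(123)
    N <- 6; D <- 8
    X <- matrix(runif(N * D, -0.2, 1.2), N, D)   # deliberately out of box
    X <- nirselect:::clamp01(X)
    fitness <- apply(X, 1, function(x) obj(x)$J)
    st <- list(X = X, fitness = fitness)
    k <- which.min(fitness)
    if (alg == "pso") {
      st$V <- matrix(0, N, D); st$P <- X; st$pf <- fitness
      st$gbest <- X[k, ]; st$gf <- fitness[k]
    } else if (alg == "ba") {
      st$V <- matrix(0, N, D); st$A <- rep(p$A0, N)
      st$r <- rep(p$pulse_rate0, N)
      st$xbest <- X[k, ]; st$fbest <- fitness[k]
    } else if (alg %in% c("fpo")) {
      st$gbest <- X[k, ]; st$gf <- fitness[k]
    } else if (alg == "woa") {
      st$xbest <- X[k, ]; st$fbest <- fitness[k]
    } else if (alg == "gwo") {
      ord <- order(fitness)[1:3]
      st$leaders <- X[ord, , drop = FALSE]; st$lf <- fitness[ord]
    }
    step_fn <- switch(alg, pso = nirselect:::step_pso,
                      cso = nirselect:::step_cso, fa = nirselect:::step_fa,
                      ba = nirselect:::step_ba, fpo = nirselect:::step_fpo,
                      woa = nirselect:::step_woa, gwo = nirselect:::step_gwo)
    for (t in 1:8) {
      st <- step_fn(st, obj, p, t, 8)
      expect_true(all(st$X >= 0 & st$X <= 1),
                  info = sprintf("%s, iteration %d", alg, t))
    }
  }
})

test_that("runs are elitist, deterministic, and reproduce their best cost", {
  ft <- make_d8_table(5)
  for (alg in c("pso", "cso", "fa", "ba", "fpo", "woa", "gwo")) {
    cfg <- search_config(alg, T = 15, N = 6, seed = 4)
    r1 <- run_optimizer(ft, cfg, cost_spec())
    r2 <- run_optimizer(ft, cfg, cost_spec())
    expect_identical(r1$best_mask$bits, r2$best_mask$bits, label = alg)
    expect_identical(r1$curve, r2$curve)
    expect_identical(r1$best_accuracy, r2$best_accuracy)
    expect_length(r1$curve, 15)
    expect_true(all(diff(r1$curve) <= 0), info = alg)
    expect_equal(r1$best_cost, r1$curve[15])
    # reported best cost reproduces evaluate_cost(best_mask) exactly
    spec <- cost_spec(split_seed = nirselect:::derive_seed(4, 77))
    again <- evaluate_cost(r1$best_mask, ft, make_split(ft, spec), spec)
    expect_identical(r1$best_cost, again$J)

    # seed isolation: results do not depend on the caller's RNG state
    set.seed(987654)
    r3 <- run_optimizer(ft, cfg, cost_spec())
    expect_identical(r1$curve, r3$curve)
    expect_identical(r1$best_mask$bits, r3$best_mask$bits)
  }
})

test_that("a flat cost landscape yields no spurious improvement", {
  ft <- make_d8_table(5)
  flat <- cost_spec(alpha = 0, beta = 0, split_seed = 8)
  for (alg in c("pso", "gwo", "cso")) {
    rr <- run_optimizer(ft, search_config(alg, T = 10, N = 6, seed = 2), flat)
    expect_true(all(rr$curve == rr$curve[1]))
  }
})

test_that("cuckoo abandonment follows the floor rule and zero steps freeze the nests", {
  ft <- make_d8_table(5)
  flat <- cost_spec(alpha = 0, beta = 0, split_seed = 50)  # all costs equal
  split <- make_split(ft, flat)
  calls <- 0L
  obj <- function(pos) { calls <<- calls + 1L; evaluate_cost(pos, ft, split, flat) }
  set.seed(7)
  X <- matrix(runif(10 * 8), 10, 8)
  st <- list(X = X, fitness = apply(X, 1, function(x) obj(x)$J))
  calls <- 0L
  # zero-magnitude steps on a flat landscape: replacement needs a strictly
  # lower cost, so no nest changes
  st2 <- nirselect:::step_cso(st, obj, list(alpha_step = 0, lambda = 1.5,
                                            pa = 0), 1, 10)
  expect_identical(st2$X, st$X)
  expect_equal(calls, 10L)           # one candidate per cuckoo, none extra
  # Pa = 0.25, N = 10: floor(2.5) = 2 abandoned nests re-evaluated
  calls <- 0L
  st3 <- nirselect:::step_cso(st, obj, list(alpha_step = 0, lambda = 1.5,
                                            pa = 0.25), 1, 10)
  expect_equal(calls, 12L)
  # with zero steps every surviving/reseeded nest is a copy of an existing one
  expect_true(all(apply(st3$X, 1, function(r)
    any(apply(st$X, 1, function(o) identical(unname(o), unname(r)))))))
})

test_that("bat acceptance requires strict improvement", {
  ft <- make_d8_table(5)
  flat <- cost_spec(alpha = 0, beta = 0, split_seed = 8)
  split <- make_split(ft, flat)
  obj <- function(pos) evaluate_cost(pos, ft, split, flat)
  set.seed(3)
  N <- 6; D <- 8
  X <- matrix(runif(N * D), N, D)
  p <- default_params("ba")
  st <- list(X = X, fitness = apply(X, 1, function(x) obj(x)$J),
             V = matrix(0, N, D), A = rep(p$A0, N),
             r = rep(p$pulse_rate0, N), xbest = X[1, ], fbest = 0)
  st2 <- nirselect:::step_ba(st, obj, p, 1, 10)
  # equal-cost candidates everywhere: no acceptance, loudness untouched,
  # positions frozen
  expect_identical(st2$A, st$A)
  expect_identical(st2$X, st$X)
})

test_that("invalid search configurations are rejected", {
  expect_error(search_config("simulated_annealing"), "arg")
  expect_error(search_config("gwo", N = 2), "N >= 3")
  expect_error(search_config("pso", T = 0), "T")
  expect_error(search_config("pso", params = list(bogus = 1)), "bogus")
})

test_that("GWO reaches the exhaustive optimum on a small fixture (spot check)", {
  ft <- make_d8_table(7)
  spec <- cost_spec(split_seed = 1234)
  sp <- make_split(ft, spec)
  oracle <- exhaustive_oracle(ft, sp, spec)
  hits <- 0
  for (s in 1:5) {
    rr <- run_optimizer(ft, search_config("gwo", T = 100, N = 10, seed = s),
                        spec)
    expect_gte(rr$best_cost, oracle$best_J - 1e-12)
    if (rr$best_cost <= oracle$best_J + 1e-12) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
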