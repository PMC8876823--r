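# Wavelength selectors: SPA projection logic, the CARS schedule, frog
# occupancy probabilities, UVE reliability thresholding, and the common
# contracts (sorted unique indices, determinism).

test_that("spa orders mutually orthogonal columns by norm", {
  set.seed(1)
  Q <- qr.Q(qr(matrix(rnorm(30 * 5), 30)))       # orthonormal columns
  X <- Q %*% diag(c(3, 1, 4, 2, 5))              # distinct norms
  y <- rnorm(30)
  res <- spa_select(X, y, max_k = 5, cv = cv_spec(shuffle_seed = 1))
  chain <- res$diagnostics$chains[[2]]           # start at the norm-1 column
  expect_equal(chain, c(2, 5, 3, 1, 4))          # then descending norms
})

test_that("an exactly collinear twin never enters a chain", {
  set.seed(2)
  X <- matrix(rnorm(25 * 5), 25)
  X <- cbind(X, X[, 3])                          # column 6 duplicates column 3
  y <- rnorm(25)
  res <- spa_select(X, y, max_k = 4, cv = cv_spec(shuffle_seed = 1))
  for (chain in res$diagnostics$chains)
    expect_lt(sum(chain %in% c(3, 6)), 2)
})

test_that("spa agrees with the brute-force Gram-Schmidt oracle", {
  set.seed(3)
  for (r in 1:10) {
    n <- sample(5:8, 1); p <- sample(4:8, 1)
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    max_k <- min(3, n - 1, p)
    folds <- rep_len(1:3, n)
    res <- spa_select(X, y, max_k, cv = cv_spec(folds = folds))
    orc <- suppressWarnings(oracle_spa_select(X, y, max_k, folds))
    expect_identical(res$selected, as.integer(orc$sel))
  }
})

test_that("edf_ratio satisfies its boundary conditions and closed form", {
  expect_equal(edf_ratio(1, 50, 104), 1.0)
  expect_equal(edf_ratio(50, 50, 104), 2 / 104)
  expect_equal(round(104 * edf_ratio(50, 50, 104)), 2)
  k <- log(52) / 49
  expect_equal(edf_ratio(25, 50, 104), (52)^(1 / 49) * exp(-k * 25))
  expect_error(edf_ratio(0, 50, 104), class = "configuration_error")
})

test_that("cars retained-count trace follows the EDF schedule exactly", {
  for (dims in list(c(104, 20, 150), c(20, 10, 60))) {
    p <- dims[1]; N <- dims[2]; n <- dims[3]
    des <- planted_design(n, p, channels = c(3, min(10, p)), seed = p)
    res <- cars_select(des$X, des$y,
                       cars_config(n_runs = N, n_components = 2,
                                   cv = cv_spec(shuffle_seed = 1)),
                       rng_seed = 5)
    sched <- pmax(2, round(p * edf_ratio(seq_len(N), N, p)))
    expect_identical(res$diagnostics$retained_trace, as.integer(sched))
    expect_true(all(diff(res$diagnostics$retained_trace) <= 0))
    expect_equal(res$diagnostics$retained_trace[N], 2)
  }
})

test_that("cars concentrates on planted informative channels", {
  hits <- vapply(1:5, function(s) {
    des <- planted_design(120, 40, channels = c(5, 20, 35), beta = 3,
                          noise_sd = 0.05, seed = 100 + s)
    res <- cars_select(des$X, des$y,
                       cars_config(n_runs = 30, n_components = 3,
                                   cv = cv_spec(shuffle_seed = s)),
                       rng_seed = s)
    sum(c(5, 20, 35) %in% res$selected)
  }, numeric(1))
  expect_gte(mean(hits >= 2), 0.8)
})

test_that("frog probabilities are exact occupancy fractions", {
  des <- planted_design(40, 12, channels = c(2, 9), seed = 4)
  res <- random_frog_select(des$X, des$y, n_iterations = 1, q_init = 12,
                            n_components = 2, rng_seed = 1)
  expect_equal(res$diagnostics$probability, rep(1, 12))

  res <- random_frog_select(des$X, des$y, n_iterations = 60, q_init = 4,
                            n_components = 2, rng_seed = 2)
  pr <- res$diagnostics$probability
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(pr * 60, round(pr * 60))    # counts / N exactly
})

test_that("frog ranks planted channels at the top", {
  top_ok <- vapply(1:5, function(s) {
    des <- planted_design(60, 30, channels = c(3, 11, 17, 22, 28), beta = 3,
                          noise_sd = 0.05, seed = 200 + s)
    res <- random_frog_select(des$X, des$y, n_iterations = 300, q_init = 8,
                              n_components = 3, rng_seed = s)
    ranks <- order(-res$diagnostics$probability)
    sum(c(3, 11, 17, 22, 28) %in% ranks[1:5])
  }, numeric(1))
  expect_gte(mean(top_ok >= 4), 0.8)
})

test_that("uve recovers a planted channel and thresholds by the noise block", {
  for (s in 1:5) {
    des <- planted_design(60, 20, channels = 5, beta = 3, noise_sd = 0.01,
                          seed = 300 + s)
    res <- uve_select(des$X, des$y, n_components = 2, rng_seed = s)
    expect_true(5 %in% res$selected)
  }
})

test_that("uve keeps little under a null response", {
  frac <- vapply(1:20, function(s) {
    set.seed(400 + s)
    X <- matrix(rnorm(40 * 20), 40)
    y <- rnorm(40)
    # under the null the threshold may legitimately eliminate everything;
    # the documented fallback (single best channel, with a warning) counts
    res <- suppressWarnings(uve_select(X, y, n_components = 2, rng_seed = s))
    res$n_selected / 20
  }, numeric(1))
  expect_lte(mean(frac), 0.15)
})

test_that("an extreme uve multiplier degrades to the single best channel", {
  des <- planted_design(50, 15, channels = 4, beta = 5, noise_sd = 0.01,
                        seed = 9)
  expect_warning(
    res <- uve_select(des$X, des$y, noise_multiplier = 1e12,
                      n_components = 2, rng_seed = 1),
    "single most reliable")
  expect_equal(res$n_selected, 1)
  expect_equal(res$selected, 4L)
})

test_that("every selector returns sorted unique in-range indices, deterministically", {
  des <- planted_design(60, 25, channels = c(4, 12, 21), seed = 77)
  cv <- cv_spec(shuffle_seed = 3)
  runs <- list(
    spa = function() spa_select(des$X, des$y, 6, cv),
    cars = function() cars_select(des$X, des$y,
                                  cars_config(n_runs = 15, n_components = 2, cv = cv),
                                  rng_seed = 11),
    rf = function() random_frog_select(des$X, des$y, n_iterations = 80,
                                       q_init = 6, n_components = 2,
                                       cv = cv, rng_seed = 11),
    uve = function() uve_select(des$X, des$y, n_components = 2, rng_seed = 11))
  for (nm in names(runs)) {
    a <- runs[[nm]]()
    b <- runs[[nm]]()
    expect_identical(a, b, info = nm)
    expect_false(is.unsorted(a$selected), info = nm)
    expect_equal(anyDuplicated(a$selected), 0, info = nm)
    expect_true(all(a$selected >= 1 & a$selected <= 25), info = nm)
    expect_true(a$n_selected >= 1 && a$n_selected <= 25, info = nm)
  }
})
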