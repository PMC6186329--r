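test_that("bell membership function matches its closed form", {
  expect_equal(bell_mf(3, a = 2, b = 7, c = 3), 1)      # value 1 at center
  for (b in c(0.5, 1, 2, 5)) {                          # 0.5 at c +/- a
    expect_equal(bell_mf(5, a = 2, b = b, c = 3), 0.5)
    expect_equal(bell_mf(1, a = 2, b = b, c = 3), 0.5)
  }
  expect_equal(bell_mf(2, a = 1, b = 1, c = 0), 0.2)    # 1/(1+4)
  expect_error(bell_mf(0, a = 0, b = 1, c = 0), "'a'")
  expect_error(bell_mf(0, a = 1, b = -1, c = 0), "'b'")
})

test_that("grid models enumerate the full rule base", {
  r5 <- matrix(c(0, 1), 5, 2, byrow = TRUE)
  m5 <- build_grid_model(r5, m = 2)
  expect_equal(nrow(m5$rule_mf), 32L)                   # 2^5 rules
  expect_equal(nrow(unique(m5$rule_mf)), 32L)           # one per grid cell

  m23 <- build_grid_model(matrix(c(0, 1), 2, 2, byrow = TRUE), m = 3)
  expect_equal(nrow(m23$rule_mf), 9L)

  # odometer order, last input fastest
  expect_equal(m23$rule_mf[1:4, 2], c(1L, 2L, 3L, 1L))
  expect_equal(m23$rule_mf[1:4, 1], c(1L, 1L, 1L, 2L))

  # centers at the range endpoints for m = 2
  m1 <- build_grid_model(matrix(c(0, 1), 1, 2), m = 2)
  expect_equal(m1$c[, 1], c(0, 1))
  expect_error(build_grid_model(matrix(c(1, 1), 1, 2), m = 2),
               "degenerate")
  expect_error(build_grid_model(matrix(c(0, 1), 1, 2), m = 1))
})

test_that("firing strengths are membership products", {
  m <- build_grid_model(matrix(c(0, 1), 2, 2, byrow = TRUE), m = 2)
  # at a grid corner one rule has membership 1 on both inputs
  w <- firing_strengths(m, c(0, 0))
  expect_equal(w[1], 1)                                  # rule (1,1)
  # against exhaustive recomputation on random models
  set.seed(101)
  for (rep in 1:25) {
    mod <- random_anfis(n = 3, m = 2)
    x <- runif(3, -1, 1)
    w <- firing_strengths(mod, x)
    w_oracle <- apply(mod$rule_mf, 1, function(idx)
      prod(vapply(1:3, function(j)
        bell_mf(x[j], mod$a[idx[j], j], mod$b[idx[j], j],
                mod$c[idx[j], j]), numeric(1))))
    expect_equal(w, w_oracle, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
  expect_error(firing_strengths(m, c(1, 2, 3)), "length")
})

test_that("strength normalization sums to one and rejects degenerate input", {
  expect_equal(normalize_strengths(c(1, 3)), c(0.25, 0.75))
  expect_equal(normalize_strengths(rep(0.7, 8)), rep(1 / 8, 8))
  expect_error(normalize_strengths(c(0, 0)), "zero")
  expect_error(normalize_strengths(c(-1, 2)), "non-negative")
  set.seed(11)
  for (rep in 1:50) {
    w <- runif(sample(2:32, 1), 0, 5)
    expect_equal(sum(normalize_strengths(w)), 1)
  }
})

test_that("constant consequents make the network output that constant", {
  set.seed(31)
  mod <- random_anfis(n = 3, m = 2)
  mod$coeffs[] <- 0
  mod$coeffs[, 4] <- 7.5
  for (rep in 1:20)
    expect_equal(anfis_forward(mod, runif(3, -1, 1))$output, 7.5)
})

test_that("forward trace is internally consistent and rule-order invariant", {
  set.seed(41)
  mod <- random_anfis(n = 2, m = 2)
  x <- c(0.3, -0.4)
  fw <- anfis_forward(mod, x)
  expect_equal(sum(fw$trace$normalized_strengths), 1)
  expect_equal(sum(fw$trace$rule_outputs), fw$output)
  expect_equal(fw$trace$firing_strengths /
                 sum(fw$trace$firing_strengths),
               fw$trace$normalized_strengths)
  # permuting the rule order leaves the output unchanged
  perm <- sample(nrow(mod$rule_mf))
  mod2 <- mod
  mod2$rule_mf <- mod$rule_mf[perm, , drop = FALSE]
  mod2$coeffs <- mod$coeffs[perm, , drop = FALSE]
  expect_equal(anfis_forward(mod2, x)$output, fw$output)
})

test_that("forward pass agrees with the naive layer-by-layer oracle", {
  set.seed(51)
  for (rep in 1:200) {
    n <- sample(1:4, 1)
    mod <- random_anfis(n = n, m = sample(2:3, 1))
    x <- runif(n, -1.2, 1.2)
    got <- anfis_forward(mod, x)$output
    want <- naive_anfis_forward(mod, x)
    expect_equal(got, want, tolerance = 1e-10)
    # the batch path agrees with the scalar path
    expect_equal(as.numeric(anfis_evaluate(mod, matrix(x, 1))), got,
                 tolerance = 1e-12)
  }
})

test_that("parameter vector codec is a bijection with the documented size", {
  expect_equal(anfis_dim(5, 2), 222L)     # 30 premise + 192 consequent
  expect_equal(anfis_dim(2, 2), 24L)      # 12 + 12
  set.seed(61)
  for (nm in list(c(2, 2), c(3, 2), c(2, 3), c(5, 2))) {
    mod <- random_anfis(n = nm[1], m = nm[2])
    v <- params_to_vector(mod)
    expect_length(v, anfis_dim(nm[1], nm[2]))
    back <- vector_to_params(v, mod)
    expect_equal(back$a, mod$a)
    expect_equal(back$b, mod$b)
    expect_equal(back$c, mod$c)
    expect_equal(unname(back$coeffs), unname(mod$coeffs))
    expect_equal(params_to_vector(back), v)
  }
  mod <- random_anfis(2, 2)
  expect_error(vector_to_params(numeric(5), mod), "length")
})

test_that("model serialization round-trips bit-exactly", {
  set.seed(77)
  mod <- random_anfis(n = 3, m = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_anfis(mod, f)
  back <- read_anfis(f)
  expect_identical(params_to_vector(back), params_to_vector(mod))
  expect_identical(back$rule_mf, mod$rule_mf)
  set.seed(88)
  X <- matrix(runif(30, -1, 1), 10, 3)
  expect_identical(anfis_evaluate(back, X), anfis_evaluate(mod, X))
})

test_that("parameter bounds keep membership functions valid", {
  mod <- build_grid_model(matrix(c(0, 2), 3, 2, byrow = TRUE), m = 2)
  b <- anfis_param_bounds(mod)
  D <- anfis_dim(3, 2)
  expect_length(b$lower, D)
  v0 <- params_to_vector(mod)
  expect_true(all(v0 >= b$lower & v0 <= b$upper))
  # a random point inside the initialization window decodes to a valid,
  # evaluable model
  set.seed(91)
  v <- runif(D, b$init_lower, b$init_upper)
  cand <- vector_to_params(v, mod)
  expect_true(all(cand$a > 0) && all(cand$b > 0))
  out <- anfis_evaluate(cand, matrix(runif(15, 0, 2), 5, 3))
  expect_true(all(is.finite(out)))
})
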