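toys <- toy_topologies()

test_that("shifted Hill hits its limits and midpoint", {
  expect_equal(shifted_hill(0, x0 = 10, n = 3, lam = 7), 1)
  expect_equal(shifted_hill(10, x0 = 10, n = 2, lam = 9), 5)   # (1 + lam)/2
  expect_equal(shifted_hill(1e9, x0 = 1, n = 2, lam = 0.1), 0.1,
               tolerance = 1e-6)
  expect_equal(shifted_hill(1e9, x0 = 1, n = 2, lam = 50), 50,
               tolerance = 1e-4)
  expect_error(shifted_hill(1, x0 = 0, n = 2, lam = 2), "x0")
  expect_error(shifted_hill(1, x0 = 1, n = 0, lam = 2), "n")
})

test_that("sampled parameters respect their ranges and distributions", {
  wt <- toys$wt
  rg <- parameter_ranges()
  set.seed(8)
  med <- estimate_operating_medians(wt, rg)
  ks <- replicate(400, sample_parameters(wt, rg, medians = med)$k[1])
  expect_true(all(ks >= 0.1 & ks <= 1))
  expect_gt(stats::ks.test(ks, "punif", 0.1, 1)$p.value, 0.01)

  p <- sample_parameters(wt, rg, medians = med)
  inh <- p$edges$sign == -1L
  expect_true(all(p$edges$lam[inh] < 1))
  expect_true(all(p$edges$lam[!inh] > 1))
  expect_true(all(p$edges$n %in% 1:6))

  set.seed(123); p1 <- sample_parameters(wt, rg, medians = med)
  set.seed(123); p2 <- sample_parameters(wt, rg, medians = med)
  expect_identical(p1, p2)
})

test_that("ODE right-hand side matches its defining algebra", {
  iso <- topology(data.frame(source = character(), target = character(),
                             sign = integer()), genes = "X")
  p <- list(g = c(X = 40), k = c(X = 0.5),
            edges = data.frame(source = character(), target = character(),
                               sign = integer(), n = integer(),
                               x0 = numeric(), lam = numeric()))
  expect_equal(ode_rhs(80, p, iso), 0)       # fixed point of linear decay
  expect_equal(ode_rhs(0, p, iso), 40)       # no spontaneous death state

  tgl <- toys$toggle
  tp <- toggle_params(tgl)
  expect_equal(ode_rhs(c(0, 0), tp, tgl), c(50, 50))
})

test_that("toggle fixed points are genuine roots of the vector field", {
  tgl <- toys$toggle
  tp <- toggle_params(tgl)
  set.seed(31)
  ss <- find_steady_states(tp, tgl, n_inits = 100)
  expect_equal(nrow(ss$states), 2L)
  expect_equal(ss$n_unconverged, 0L)
  for (r in seq_len(nrow(ss$states)))
    expect_lt(max(abs(ode_rhs(ss$states[r, ], tp, tgl))), 1e-9)
  # mirror symmetry of the symmetric switch
  expect_equal(sort(ss$states[1, ]), sort(ss$states[2, ]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("integration endpoints agree with an independent stiff integrator", {
  skip_if_not_installed("deSolve")
  tgl <- toys$toggle
  tp <- toggle_params(tgl)
  f <- function(t, y, parms) list(ode_rhs(y, tp, tgl))
  for (y0 in list(c(90, 5), c(5, 90))) {
    end <- deSolve::lsoda(y0, c(0, 500), f, NULL)[2, 2:3]
    set.seed(41)
    ss <- find_steady_states(tp, tgl, n_inits = 50)
    d <- apply(ss$states, 1, function(s) max(abs(log2(s) - log2(end))))
    expect_lt(min(d), 0.01)
  }
})

test_that("an isolated gene is always monostable at g/k", {
  iso <- topology(data.frame(source = character(), target = character(),
                             sign = integer()), genes = "X")
  rg <- parameter_ranges()
  set.seed(12)
  for (rep in 1:5) {
    p <- list(g = stats::setNames(stats::runif(1, 1, 100), "X"),
              k = stats::setNames(stats::runif(1, 0.1, 1), "X"),
              edges = data.frame(source = character(), target = character(),
                                 sign = integer(), n = integer(),
                                 x0 = numeric(), lam = numeric()))
    ss <- find_steady_states(p, iso, n_inits = 20)
    expect_equal(nrow(ss$states), 1L)
    expect_equal(unname(ss$states[1, 1]), unname(p$g / p$k), tolerance = 1e-8)
  }
  ens <- simulate_ensemble(iso, n_models = 50, n_inits = 5, seed = 4,
                           replicates = 1)
  expect_equal(ens$multistability$mono, 100)
})

test_that("a tuned repressilator oscillates and reports no stable state", {
  rp <- toys$repressilator
  p <- list(g = c(A = 50, B = 50, C = 50), k = c(A = 0.5, B = 0.5, C = 0.5),
            edges = cbind(rp$edges,
                          data.frame(n = c(6L, 6L, 6L), x0 = c(30, 30, 30),
                                     lam = c(0.01, 0.01, 0.01))))
  # the symmetric fixed point exists but is linearly unstable: the secant
  # condition for a 3-ring requires the loop gain to exceed 8
  set.seed(21)
  ss <- find_steady_states(p, rp, n_inits = 30)
  expect_equal(nrow(ss$states), 0L)
  expect_equal(ss$n_unconverged, 30L)
})

test_that("toggle bistable fraction is reproducible across seeds", {
  tgl <- toys$toggle
  frac <- sapply(c(101, 202), function(s) {
    ens <- simulate_ensemble(tgl, n_models = 300, n_inits = 30, seed = s,
                             replicates = 1)
    ens$multistability$bi
  })
  # binomial sampling error at n = 300 is ~2.5 pp; allow 4 sd
  expect_lt(abs(frac[1] - frac[2]), 10)
  expect_gt(mean(frac), 5)   # the toggle is robustly bistable in the ensemble
})

test_that("ensemble normalization gives exact z-columns and keeps order", {
  set.seed(13)
  raw <- matrix(stats::rexp(60, 0.1) + 0.1, 20, 3,
                dimnames = list(NULL, c("A", "B", "C")))
  z <- normalize_ensemble(raw)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(colMeans(z), c(A = 0, B = 0, C = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, pop_sd), c(A = 1, B = 1, C = 1),
               tolerance = 1e-12)
  expect_equal(order(raw[, "A"]), order(z[, "A"]))  # monotone (affine o log2)

  two <- normalize_ensemble(matrix(c(1, 4, 8, 2), 2, 2,
                                   dimnames = list(NULL, c("A", "B"))))
  expect_true(all(abs(abs(two) - 1) < 1e-12))

  const <- matrix(c(1, 1, 2, 3), 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(normalize_ensemble(const), "zero-variance.*A")
})

test_that("pooled ensemble satisfies residual and normalization invariants", {
  tgl <- toys$toggle
  ens <- simulate_ensemble(tgl, n_models = 60, n_inits = 20, seed = 9,
                           replicates = 2)
  expect_true(all(colMeans(ens$z) < 1e-10))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_true(all(abs(apply(ens$z, 2, pop_sd) - 1) < 1e-10))
  expect_equal(nrow(ens$z), length(ens$model))
  expect_true(all(ens$n_states_model >= 1))
  expect_true(all(2^ens$log2 > 0))
  # multistability rows sum to 100% per replicate
  sums <- rowSums(ens$multistability[, c("none", "mono", "bi", "tri", "multi4")])
  expect_equal(sums, rep(100, 2), tolerance = 1e-9)
})
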