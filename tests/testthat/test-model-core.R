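test_that("bundled model structures satisfy their documented constraints", {
  icrp <- zr_model("icrp")
  hmgu <- zr_model("hmgu")

  expect_length(icrp$compartments, 11)
  expect_equal(nrow(icrp$transfers), 15)
  expect_setequal(rate_indices(icrp), c(1:8, 13:19))
  expect_length(hmgu$compartments, 10)
  expect_equal(nrow(hmgu$transfers), 12)
  expect_setequal(rate_indices(hmgu), 1:12)

  # stomach drains exclusively to the small intestine in both models
  for (m in list(icrp, hmgu)) {
    out <- m$transfers[m$transfers$source == m$entry, ]
    expect_equal(nrow(out), 1)
    expect_equal(out$target, "y10")
    # terminal compartments are absorbing
    expect_false(any(m$transfers$source %in% m$terminals))
  }

  # HMGU: upper large intestine y5 receives exactly x8 (from y10) and
  # x10 (from y1)
  in5 <- hmgu$transfers[hmgu$transfers$target == "y5", ]
  expect_setequal(in5$rate, c(8, 10))
  expect_equal(in5$source[in5$rate == 8], "y10")
  expect_equal(in5$source[in5$rate == 10], "y1")

  # ICRP: both bone compartments transfer directly to bladder contents
  # (y11) and the upper large intestine (y5); HMGU has one bone pool
  for (b in icrp$bones) {
    tg <- icrp$transfers$target[icrp$transfers$source == b]
    expect_setequal(tg, c("y11", "y5"))
  }
  expect_length(hmgu$bones, 1)

  # shared transfers 1..8 connect the same compartments in both models,
  # up to relabelling: y1/y5/y6/y7/y8/y9/y10 name the same roles in both
  same_role <- c("y1", "y5", "y6", "y7", "y8", "y9", "y10")
  for (r in 1:8) {
    ti <- icrp$transfers[icrp$transfers$rate == r, ]
    th <- hmgu$transfers[hmgu$transfers$rate == r, ]
    if (ti$source %in% same_role || th$source %in% same_role)
      expect_equal(ti$source, th$source)
    if (ti$target %in% same_role || th$target %in% same_role)
      expect_equal(ti$target, th$target)
  }
})

test_that("model validation rejects malformed structures", {
  expect_error(compartmental_model(
    "bad", c("a", "b"), data.frame(rate = 1, source = "a", target = "a"),
    entry = "a", terminals = "b", plasma = "a", bones = character(0)),
    "self-transfer")
  expect_error(compartmental_model(
    "bad", c("a", "b", "c"),
    data.frame(rate = c(1, 1), source = c("a", "b"), target = c("b", "c")),
    entry = "a", terminals = "c", plasma = "a", bones = character(0)),
    "duplicated rate")
  expect_error(compartmental_model(
    "bad", c("a", "b"),
    data.frame(rate = 1:2, source = c("a", "b"), target = c("b", "a")),
    entry = "a", terminals = "b", plasma = "a", bones = character(0)),
    "terminal")
  expect_error(compartmental_model(
    "bad", c("a", "b"), data.frame(rate = 1, source = "a", target = "z"),
    entry = "a", terminals = "b", plasma = "a", bones = character(0)),
    "undeclared")
})

test_that("system matrix follows the mass-balance construction", {
  m <- toy_chain_model()
  # single transfer a -> urine at rate lambda
  A <- build_system_matrix(m, rate_vector(m, c(`1` = 0.7)))
  expect_equal(unname(A), matrix(c(-0.7, 0.7, 0, 0), 2, 2))
  # all rates zero -> zero matrix
  A0 <- build_system_matrix(m, rate_vector(m, c(`1` = 0)))
  expect_equal(unname(A0), matrix(0, 2, 2))

  # bundled models: column sums exactly zero, rate mismatch reported
  for (name in c("hmgu", "icrp")) {
    mm <- zr_model(name)
    set.seed(1)
    r <- rate_vector(mm, rprior(zr_prior(name), 1)[1, ])
    A <- build_system_matrix(mm, r)
    expect_equal(max(abs(colSums(A))), 0, tolerance = 1e-13)
  }
  mm <- zr_model("hmgu")
  expect_error(rate_vector(mm, c(`1` = 1)), "missing")
  expect_error(rate_vector(mm, rep(1, 5)), "expected 12 rates")
  expect_error(rate_vector(mm, stats::setNames(rep(1, 12), c(1:11, 13))),
               "missing: 12")

  # HMGU y5 row: positive entries exactly in columns y10 (x8) and y1 (x10)
  r <- rate_vector(mm, stats::setNames(seq(0.1, 1.2, by = 0.1),
                                       as.character(1:12)))
  A <- build_system_matrix(mm, r)
  pos <- which(A["y5", ] > 0)
  expect_setequal(names(pos), c("y10", "y1"))
  expect_equal(A["y5", "y10"], r[["8"]])
  expect_equal(A["y5", "y1"], r[["10"]])
})

test_that("exact trajectory matches closed forms and conserves mass", {
  m <- toy_chain_model()
  tt <- c(0, 0.3, 1, 2.5, 10)
  tra <- solve_trajectory(m, rate_vector(m, c(`1` = 1)), tt)
  expect_equal(tra$values[, "a"], 100 * exp(-tt), tolerance = 1e-12)
  expect_equal(rowSums(tra$values), rep(100, length(tt)), tolerance = 1e-12)

  # all rates zero: trajectory constant at the initial condition
  tra0 <- solve_trajectory(m, rate_vector(m, c(`1` = 0)), tt)
  expect_equal(tra0$values[, "a"], rep(100, length(tt)))

  # bundled models, random positive rates: mass conservation and
  # nonnegativity
  for (name in c("hmgu", "icrp")) {
    mm <- zr_model(name); pp <- zr_prior(name)
    set.seed(7)
    for (i in 1:5) {
      r <- rate_vector(mm, rprior(pp, 1)[1, ])
      tra <- solve_trajectory(mm, r, seq(0, 100, length.out = 21))
      expect_lt(max(abs(rowSums(tra$values) - 100)), 1e-9)
      expect_gt(min(tra$values), -1e-9)
    }
  }
})

test_that("exact solver agrees with an adaptive numerical integrator", {
  skip_if_not_installed("deSolve")
  for (name in c("hmgu", "icrp")) {
    mm <- zr_model(name); pp <- zr_prior(name)
    set.seed(11)
    r <- rate_vector(mm, rprior(pp, 1)[1, ])
    A <- build_system_matrix(mm, r)
    tt <- seq(0, 100, length.out = 41)
    y0 <- stats::setNames(numeric(length(mm$compartments)),
                          mm$compartments)
    y0[mm$entry] <- 100
    num <- deSolve::lsoda(y = y0, times = tt,
                          func = function(t, y, parms) list(A %*% y),
                          rtol = 1e-11, atol = 1e-11)
    tra <- solve_trajectory(mm, r, tt)
    expect_lt(max(abs(tra$values - num[, -1])), 1e-8)
  }
})

test_that("urine excretion rate is the analytic inflow sum", {
  m <- toy_chain_model()
  lam <- 0.8
  tt <- c(0.1, 0.5, 1, 3, 7)
  r <- rate_vector(m, c(`1` = lam))
  tra <- solve_trajectory(m, r, tt)
  expect_equal(urine_excretion_rate(m, r, tra), lam * 100 * exp(-lam * tt),
               tolerance = 1e-12)

  # zero rates -> identically zero
  tra0 <- solve_trajectory(m, rate_vector(m, c(`1` = 0)), tt)
  expect_equal(urine_excretion_rate(m, rate_vector(m, c(`1` = 0)), tra0),
               rep(0, length(tt)))

  # agrees with a central finite difference of the urine compartment
  mm <- zr_model("hmgu")
  set.seed(3)
  r <- rate_vector(mm, rprior(zr_prior("hmgu"), 1)[1, ])
  tt <- c(0.5, 1, 2, 5, 20, 80)
  h <- 1e-4
  tra <- solve_trajectory(mm, r, tt)
  rate <- urine_excretion_rate(mm, r, tra)
  y_up <- solve_trajectory(mm, r, tt + h)$values[, "y7"]
  y_dn <- solve_trajectory(mm, r, tt - h)$values[, "y7"]
  fd <- (y_up - y_dn) / (2 * h)
  expect_lt(max(abs(rate - fd) / pmax(abs(fd), 1e-12)), 1e-6)

  # model-definition error when the requested compartment is not absorbing
  expect_error(urine_excretion_rate(mm, r, tra, urine = "y1"),
               "outgoing transfers")
})

test_that("decay correction halves at one half-life and composes", {
  v <- c(10, 20, 40)
  # unchanged at t = 0
  expect_equal(decay_correct(v, c(0, 0, 0), 64.032), v)
  # halved at one half-life, quartered at two
  expect_equal(decay_correct(100, 64.032, half_life = 64.032), 50)
  expect_equal(decay_correct(100, 2 * 64.032, half_life = 64.032), 25)
  # semigroup: applying half_life h twice equals once with h/2
  tt <- c(1, 10, 50)
  expect_equal(decay_correct(decay_correct(v, tt, 30), tt, 30),
               decay_correct(v, tt, 15))
  expect_error(decay_correct(v, c(1, 2, 3), half_life = -1), "positive")
})

test_that("bone retention bands match brute-force quantiles", {
  mm <- zr_model("icrp"); pp <- zr_prior("icrp")
  set.seed(21)
  samples <- rprior(pp, 25)
  tt <- c(1, 5, 20, 60)
  band <- bone_retention(mm, samples, tt)
  # brute-force oracle: recompute every curve, quantile pointwise
  curves <- sapply(seq_len(nrow(samples)), function(i) {
    tra <- solve_trajectory(mm, rate_vector(mm, samples[i, ]), tt)
    rowSums(tra$values[, mm$bones])
  })
  for (j in seq_along(tt)) {
    q <- stats::quantile(curves[j, ], c(0.05, 0.5, 0.95), names = FALSE)
    expect_equal(unlist(band[j, c("lower", "median", "upper")]), q,
                 ignore_attr = TRUE)
  }
  # ICRP retention is trabecular + cortical summed
  tra1 <- solve_trajectory(mm, rate_vector(mm, samples[1, ]), tt)
  single <- bone_retention(mm, samples[1, , drop = FALSE], tt)
  expect_equal(single$median, tra1$values[, "y2"] + tra1$values[, "y3"],
               ignore_attr = TRUE)
  # single sample: zero-width band
  expect_equal(single$lower, single$upper)
  # decay-corrected retention never exceeds the uncorrected one for t > 0
  bandd <- bone_retention(mm, samples, tt, apply_decay = TRUE)
  expect_true(all(bandd$median <= band$median))
  expect_error(bone_retention(mm, list(), tt), "empty")
})
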