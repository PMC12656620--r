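test_that("the membership function hits its landmark values exactly", {
  p <- membership_params(x0 = 0.6, c_l = 0.2, c_r = 0.1)
  expect_identical(aizerman_membership(0.6, p), 1)
  # at distance c the membership equals b by construction (b = 0.5, d = 2)
  expect_equal(aizerman_membership(0.6 + 0.1, p), 0.5, tolerance = 1e-12)
  expect_equal(aizerman_membership(0.6 - 0.2, p), 0.5, tolerance = 1e-12)
  expect_equal(aizerman_membership(0.6 + 0.2, p), 1 / 5, tolerance = 1e-12)
})

test_that("membership is positive, bounded, continuous at x0 and strictly unimodal", {
  set.seed(7)
  for (i in 1:25) {
    p <- membership_params(x0 = runif(1, -1, 1), a = 1,
                           b_l = runif(1, 0.1, 1), b_r = runif(1, 0.1, 1),
                           c_l = runif(1, 0.05, 2), c_r = runif(1, 0.05, 2),
                           d_l = runif(1, 0.5, 4), d_r = runif(1, 0.5, 4))
    xr <- p$x0 + sort(runif(30, 0, 3))
    xl <- p$x0 - sort(runif(30, 0, 3))
    mr <- aizerman_membership(xr, p)
    ml <- aizerman_membership(xl, p)
    expect_true(all(mr > 0 & mr <= 1))
    expect_true(all(diff(mr) < 0))             # strictly decreasing rightward
    expect_true(all(diff(ml) < 0))             # and leftward
    # continuity at x0: shallow slopes (d < 1) approach the apex like a
    # root, so probe with a matched tolerance
    expect_equal(aizerman_membership(p$x0 - 1e-13, p), 1, tolerance = 1e-4)
    expect_equal(aizerman_membership(p$x0, p), 1)
  }
  expect_error(membership_params(0.5, b_l = 0, c_l = 1, c_r = 1), "fuzziness")
  expect_error(membership_params(0.5, c_l = 0, c_r = 1), "scope")
})

test_that("aggregation is the idempotent compensatory mean", {
  expect_identical(aggregate_memberships(c(1, 1, 1, 1)), 1)
  expect_equal(aggregate_memberships(c(0.8, 0.6)), 0.7, tolerance = 1e-12)
  expect_identical(aggregate_memberships(c(0.2, 0.2, 0.2)), 0.2)
  expect_error(aggregate_memberships(numeric()), "empty")
  set.seed(8)
  for (i in 1:25) {
    mu <- runif(sample(2:6, 1))
    agg <- aggregate_memberships(mu)
    expect_gte(agg, min(mu))
    expect_lte(agg, max(mu))
  }
})

test_that("training derives class parameters from mean, spread and uncertainty", {
  # a singleton class keeps a scope equal to the measurement uncertainty
  feats <- data.frame(f = c(0.9, 0.8, 1.0),
                      g = c(0.2, 0.35, 0.5))
  labels <- c("solo", "pair", "pair")
  clf <- ft_train(feats, labels, feature_order = c("f", "g"),
                  u_expanded = c(f = 0.0711, g = 0.0711))
  solo <- clf$classes$solo$dims
  expect_identical(solo$f$x0, 0.9)
  expect_identical(solo$f$c_l, 0.0711)
  expect_identical(solo$f$c_r, 0.0711)

  # a two-object class widens by its spread around the mean
  feats2 <- data.frame(f = c(0.8, 1.0, 0.5))
  clf2 <- ft_train(feats2, c("pair", "pair", "other"), feature_order = "f",
                   u_expanded = c(f = 0.059))
  pair <- clf2$classes$pair$dims
  expect_equal(pair$f$x0, 0.9, tolerance = 1e-12)
  expect_equal(pair$f$c_l, 0.159, tolerance = 1e-12)
  expect_equal(pair$f$c_r, 0.159, tolerance = 1e-12)

  # every training object keeps at least membership b in its own class dims
  pair_full <- clf$classes$pair$dims
  for (i in 2:3) for (f in c("f", "g"))
    expect_gte(aizerman_membership(feats[[f]][i], pair_full[[f]]), 0.5)

  expect_error(ft_train(feats, c("a", "a", "a"), feature_order = c("f", "g"),
                        u_expanded = c(f = 0.1, g = 0.1)), "two classes")
  expect_error(ft_train(feats, labels, feature_order = c("f", "missing"),
                        u_expanded = c(f = 0.1, missing = 0.1)), "lack columns")
})

test_that("classification assigns the maximum-membership class deterministically", {
  feats <- data.frame(f = c(0.2, 0.2, 0.9, 0.9), g = c(0.1, 0.3, 0.7, 0.9))
  clf <- ft_train(feats, c("low", "low", "high", "high"),
                  feature_order = c("f", "g"),
                  u_expanded = c(f = 0.07, g = 0.07))
  at_center <- data.frame(f = 0.9, g = 0.8)
  res <- ft_classify(clf, at_center)
  expect_identical(res$assigned, "high")
  expect_identical(res$mu_high, 1)
  expect_false(res$tie)

  res2 <- ft_classify(clf, data.frame(f = c(0.9, 0.2), g = c(0.8, 0.2)))
  expect_identical(res2$assigned, c("high", "low"))

  expect_error(ft_classify(clf, data.frame(f = 0.5)), "lacks dimensions")
})

test_that("exact ties resolve to the earlier class and are reported", {
  feats <- data.frame(f = c(0.4, 0.4))
  clf <- ft_train(feats, factor(c("first", "second"), levels = c("first", "second")),
                  feature_order = "f", u_expanded = c(f = 0.05))
  res <- ft_classify(clf, data.frame(f = 0.4))
  expect_identical(res$assigned, "first")
  expect_true(res$tie)
})

test_that("classification is invariant to class ordering up to the tie rule", {
  feats <- data.frame(f = c(0.2, 0.2, 0.9, 0.9), g = c(0.1, 0.3, 0.7, 0.9))
  labels <- c("low", "low", "high", "high")
  fwd <- ft_train(feats, factor(labels, levels = c("low", "high")),
                  feature_order = c("f", "g"), u_expanded = c(f = 0.07, g = 0.07))
  rev_ <- ft_train(feats, factor(labels, levels = c("high", "low")),
                   feature_order = c("f", "g"), u_expanded = c(f = 0.07, g = 0.07))
  probe <- data.frame(f = runif(10), g = runif(10))
  a <- ft_classify(fwd, probe); b <- ft_classify(rev_, probe)
  expect_identical(a$assigned[!a$tie], b$assigned[!b$tie])
  expect_equal(a$mu_high, b$mu_high, tolerance = 1e-12)
})

test_that("models survive the JSON round trip with identical memberships", {
  feats <- data.frame(f = runif(10), g = runif(10), h = runif(10))
  labels <- rep(c("a", "b"), 5)
  clf <- ft_train(feats, labels, feature_order = c("f", "g", "h"),
                  u_expanded = c(f = 0.06, g = 0.07, h = 0.07))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(clf, path)
  back <- load_model(path)
  probe <- data.frame(f = runif(20), g = runif(20), h = runif(20))
  expect_identical(ft_classify(back, probe), ft_classify(clf, probe))

  # corrupt: drop one class's dims
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  obj$classes[[1]]$dims <- NULL
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  expect_error(load_model(path), "missing dimension")

  # a model with more dimensions than the data provides
  expect_error(ft_classify(clf, data.frame(f = 0.1, g = 0.2)), "lacks dimensions")
})
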