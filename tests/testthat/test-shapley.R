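# Small fitted forest + background shared across attribution tests.
shap_fixture <- local({
  env <- new.env()
  function() {
    if (!is.null(env$fx)) return(env$fx)
    set.seed(42)
    p <- 8; n <- 260; B <- 16
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
    y <- X[, 1] - 0.8 * X[, 2] + 0.6 * X[, 3] * X[, 4] + rnorm(n, 0, 0.3) > 0
    ds <- ecg_dataset(X, lvef = ifelse(y, 30, 60), schema = tiny_schema(p))
    m <- fit_lvef_model(ds, "random_forest",
                        hyper = list(ntree = 60, maxnodes = 16), seed = 3)
    env$fx <- list(X = X, ds = ds, m = m, bg = X[1:B, ], p = p)
    env$fx
  }
})

test_that("tree-path attributions satisfy local accuracy exactly", {
  fx <- shap_fixture()
  sm <- shap_values(fx$m, fx$X[30:49, ], fx$bg,
                    bg = background_spec(size = nrow(fx$bg)))
  expect_lt(max(abs(sm$base_value + rowSums(sm$values) - sm$pred)), 1e-6)
})

test_that("tree path and kernel path agree with the enumeration oracle", {
  fx <- shap_fixture()
  f <- function(mm) predict_proba(fx$m, mm)
  sm <- shap_values(fx$m, fx$X[30:33, ], fx$bg,
                    bg = background_spec(size = nrow(fx$bg)))
  for (i in 1:4) {
    ex <- exact_shapley(f, fx$X[29 + i, ], fx$bg)
    expect_lt(max(abs(sm$values[i, ] - ex)), 1e-8)
  }
  # kernel WLS route on a smooth non-tree function
  g <- function(mm) plogis(mm[, 1] - mm[, 2]^2 + 0.5 * mm[, 3] * mm[, 4])
  ko <- ecgxai:::kernel_shap_exact(g, fx$X[5, ], fx$bg)
  expect_lt(max(abs(ko - exact_shapley(g, fx$X[5, ], fx$bg))), 1e-8)
})

test_that("the enumeration oracle obeys the Shapley axioms", {
  fx <- shap_fixture()
  bg <- fx$bg
  # symmetry: duplicated feature (same values everywhere) -> equal shares
  bg_dup <- bg; bg_dup[, 2] <- bg_dup[, 1]
  h <- function(mm) mm[, 1] + mm[, 2] + 0.3 * mm[, 5]
  x <- c(2, 2, 0, 1, -1, 0.5, 0, 3)
  phi <- exact_shapley(h, x, bg_dup)
  expect_lt(abs(phi[1] - phi[2]), 1e-12)
  # dummy: untouched features get exactly zero
  expect_equal(unname(phi[c(3, 4, 6, 7, 8)]), rep(0, 5))
  # efficiency: sum equals f(x) - mean f(background)
  expect_lt(abs(sum(phi) - (h(matrix(x, 1)) - mean(h(bg_dup)))), 1e-12)
  # linear closed form under the interventional distribution
  w <- c(0.5, -1, 2, 0, 1, -0.3, 0.7, 0.1)
  lin <- function(mm) as.numeric(mm %*% w)
  expect_lt(max(abs(exact_shapley(lin, x, bg) - w * (x - colMeans(bg)))),
            1e-12)
})

test_that("attribution guards reject invalid inputs", {
  fx <- shap_fixture()
  expect_error(exact_shapley(function(mm) rowSums(mm), rnorm(13),
                             matrix(rnorm(26), 2)), "p <= 12")
  expect_error(shap_values(fx$m, fx$X[1:2, ], fx$bg[0, , drop = FALSE],
                           bg = background_spec(size = 1)), "background")
})

test_that("constant models attribute nothing", {
  fx <- shap_fixture()
  cst <- function(mm) rep(0.4, nrow(mm))
  phi <- exact_shapley(cst, fx$X[1, ], fx$bg)
  expect_equal(unname(phi), rep(0, fx$p))
})

test_that("sampled kernel SHAP keeps the efficiency constraint", {
  set.seed(8)
  p <- 20
  X <- matrix(rnorm(40 * p), 40, p, dimnames = list(NULL, paste0("g", 1:p)))
  w <- rnorm(p)
  f <- function(mm) plogis(mm %*% w)
  phi <- ecgxai:::kernel_shap_sampled(f, X[1, ], X[2:17, ], nsamples = 600,
                                      seed = 5)
  delta <- f(X[1, , drop = FALSE]) - mean(f(X[2:17, ]))
  expect_lt(abs(sum(phi) - delta), 1e-8)
})

test_that("attribution matrices round-trip through CSV + sidecar", {
  fx <- shap_fixture()
  sm <- shap_values(fx$m, fx$X[10:12, ], fx$bg,
                    bg = background_spec(size = nrow(fx$bg)))
  f <- tempfile(fileext = ".csv")
  write_shap_matrix(sm, f)
  back <- read_shap_matrix(f)
  expect_equal(back$values, sm$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$base_value, sm$base_value)
})
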