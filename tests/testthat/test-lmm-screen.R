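make_long_fixture <- function(seed = 51, n_cycle = 2, cycle_effect = 2,
                              n_substances = 20, spec_args = list()) {
  spec <- do.call(effect_spec, c(
    list(
      n_substances = n_substances, n_contaminants = 0, n_cycle = n_cycle,
      n_age = 0, n_parity = 0, cycle_effect = cycle_effect, seed = seed
    ),
    spec_args
  ))
  cfg <- small_config(n_handling = 0, n_air = 0)
  design <- generate_design(cfg, seed = seed)
  truth <- simulate_intensities(design, spec, seed = seed)
  rel <- relative_areas(truth_area_table(truth))
  long <- vectorise(transform_response(rel, "normalised"), design)
  list(truth = truth, design = design, long = long)
}

screen_spec <- function() {
  build_model_spec(
    fixed = c("cycle_state", "age_z", "parity"),
    random_intercept = c("sample_id", "substance", "female_id"),
    random_slope = c(substance = "age_z"),
    random_interaction = list(substance = c("cycle_state", "parity")),
    test_predictors = c(
      "(1|substance:cycle_state)", "(1|substance:parity)",
      "(0+age_z|substance)"
    )
  )
}

test_that("vectorisation stacks sample-major with replicated covariates", {
  design <- generate_design(small_config(n_handling = 0, n_air = 0), seed = 51)
  wide <- tibble::tibble(
    sample_id = design$sample_id[1:2],
    subA = c(1, 4), subB = c(2, 5), subC = c(3, 6)
  )
  long <- vectorise(wide, design)
  expect_equal(nrow(long), 6)
  expect_equal(long$y, c(1, 2, 3, 4, 5, 6))
  expect_equal(long$substance, rep(c("subA", "subB", "subC"), 2))
  expect_equal(long$sample_id, rep(design$sample_id[1:2], each = 3))
  expect_equal(
    long$cycle_state, rep(design$cycle_state[1:2], each = 3)
  )
  # round trip
  expect_equal(un_vectorise(long), wide)
  # z-scored age over female-level values
  full <- vectorise(
    tibble::tibble(
      sample_id = design$sample_id,
      subA = seq_len(nrow(design))
    ),
    design
  )
  fem <- dplyr::distinct(full, female_id, age_z)
  expect_equal(mean(fem$age_z), 0, tolerance = 1e-12)
  expect_equal(sd(fem$age_z), 1, tolerance = 1e-12)
  # missing metadata errors
  expect_error(vectorise(wide, design[-1, ]), "missing sample")
})

test_that("the model-spec builder enumerates the study terms", {
  spec <- build_model_spec()
  expect_equal(n_predictors(spec), 33)
  expect_equal(sum(spec$terms$type == "fixed"), 9)
  expect_equal(sum(spec$terms$test_predictor), 3)
  # null specification drops the three test predictors
  expect_equal(n_predictors(drop_terms(spec)), 30)
  # fixed-effects-only specification
  fixed_only <- build_model_spec(
    fixed = c("cycle_state", "age_z"), random_intercept = character(),
    random_slope = character(), random_interaction = list(),
    test_predictors = character()
  )
  expect_equal(n_predictors(fixed_only), 2)
  expect_error(build_model_spec(fixed = "bodyweight"), "Unknown")
  expect_error(drop_terms(spec, "(1|nope)"), "unknown")
  f <- spec_formula(spec)
  expect_true(grepl("(1 | substance:cycle_state)", deparse1(f), fixed = TRUE))
})

test_that("ML fit matches the closed-form balanced one-way solution", {
  set.seed(52)
  k <- 6
  n_per <- 5
  g <- sprintf("sub%02d", rep(1:k, each = n_per))
  y <- rnorm(k * n_per) + rep(rnorm(k, 0, 1), each = n_per)
  df <- tibble::tibble(
    y = y, substance = g, sample_id = as.character(seq_along(y))
  )
  spec <- build_model_spec(
    fixed = character(), random_intercept = "substance",
    random_slope = character(), random_interaction = list(),
    test_predictors = character()
  )
  fit <- fit_lmm(df, spec, method = "ML")
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  ssw <- sum((y - ave(y, g))^2)
  ssb <- n_per * sum((tapply(y, g, mean) - mean(y))^2)
  sigma_e <- ssw / (k * n_per - k)
  sigma_a <- (ssb / k - sigma_e) / n_per
  expect_equal(vc$vcov[vc$grp == "substance"], sigma_a, tolerance = 1e-6)
  expect_equal(vc$vcov[vc$grp == "Residual"], sigma_e, tolerance = 1e-6)
})

test_that("zero group variance collapses to ordinary least squares", {
  set.seed(53)
  # balanced crossing of substance and cycle with residuals centred within
  # substance: the between-substance variation is exactly zero, so the ML
  # variance estimate must land on the boundary
  grid <- expand.grid(
    substance = sprintf("sub%02d", 1:10),
    cycle_state = c("follicular", "peri-ovulatory", "luteal"),
    rep = 1:4, stringsAsFactors = FALSE
  )
  e <- rnorm(nrow(grid))
  e <- e - stats::ave(e, grid$substance)
  df <- tibble::tibble(
    y = c(0, 1, 2)[match(
      grid$cycle_state, c("follicular", "peri-ovulatory", "luteal")
    )] + e,
    cycle_state = grid$cycle_state,
    substance = grid$substance
  )
  spec <- build_model_spec(
    fixed = "cycle_state", random_intercept = "substance",
    random_slope = character(), random_interaction = list(),
    test_predictors = character()
  )
  fit <- fit_lmm(df, spec, method = "ML")
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  expect_lt(vc$vcov[vc$grp == "substance"], 1e-6)
  ols <- stats::lm(y ~ cycle_state, data = df)
  expect_equal(
    unname(lme4::fixef(fit$model)), unname(stats::coef(ols)),
    tolerance = 1e-6
  )
})

test_that("likelihood-ratio tests compare nested ML fits", {
  fx <- make_long_fixture(seed = 54)
  spec <- screen_spec()
  full <- fit_lmm(fx$long, spec, method = "ML")
  same <- lrt(full, full)
  expect_equal(same$chisq, 0)
  expect_equal(same$df, 0)
  expect_equal(same$p, 1)

  red <- fit_lmm(fx$long, drop_terms(spec, "(1|substance:cycle_state)"),
    method = "ML"
  )
  one <- lrt(full, red)
  expect_equal(one$df, 1)
  expect_gte(one$chisq, 0)
  expect_true(one$p > 0 && one$p <= 1)
  # full log-likelihood dominates the nested fit at convergence
  expect_gte(full$logLik + 1e-6, red$logLik)

  null_fit <- fit_lmm(fx$long, drop_terms(spec), method = "ML")
  expect_equal(lrt(full, null_fit)$df, 3)

  expect_error(lrt(red, full), "not nested")
  reml <- fit_lmm(fx$long, spec, method = "REML")
  expect_error(lrt(reml, red), "ML")
  other <- fit_lmm(fx$long[-(1:20), ], spec, method = "ML")
  expect_error(lrt(full, other), "different data")
})

test_that("flagging rule: threshold, edge cases, scale equivariance", {
  flat <- flag_most_affected(c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(flat$threshold, 1)
  expect_true(all(flat$flagged))
  none <- flag_most_affected(c(a = 0, b = 0))
  expect_false(any(none$flagged))

  set.seed(55)
  scores <- abs(rnorm(30))
  scores[1:3] <- scores[1:3] + 5
  f1 <- flag_most_affected(scores)
  f2 <- flag_most_affected(scores * 7)
  expect_equal(f2$threshold, 7 * f1$threshold, tolerance = 1e-12)
  expect_equal(f2$flagged, f1$flagged)
})

test_that("the screen recovers strongly planted cycle substances", {
  fx <- make_long_fixture(seed = 56, n_cycle = 2, cycle_effect = 2)
  fit <- fit_lmm(fx$long, screen_spec())
  sc <- screen_substances(fit, "cycle")
  planted <- fx$truth$cycle_substances
  # the planted substances carry the top scores and are flagged
  expect_setequal(sc$substance[1:2], planted)
  expect_true(all(sc$flagged[1:2]))
  expect_false(any(sc$flagged[-(1:2)]))
  # directions point at the elevated state
  sub <- fx$truth$spec$substances
  for (s in planted) {
    i <- match(s, sub$substance)
    states <- c(sub$c_follicular[i], sub$c_periovulatory[i], sub$c_luteal[i])
    high <- c("follicular", "peri-ovulatory", "luteal")[which.max(states)]
    expect_equal(sc$direction[sc$substance == s], high)
  }
  expect_error(screen_substances(fit, "flavour"))
})

test_that("age and parity screens extract the matching components", {
  spec <- effect_spec(
    n_substances = 20, n_contaminants = 0, n_cycle = 0, n_age = 3,
    n_parity = 2, age_effect = 2, parity_effect = 2,
    prop_age_negative = 1, seed = 57
  )
  design <- generate_design(small_config(n_handling = 0, n_air = 0),
    seed = 57
  )
  truth <- simulate_intensities(design, spec, seed = 57)
  rel <- relative_areas(truth_area_table(truth))
  long <- vectorise(transform_response(rel, "normalised"), design)
  fit <- fit_lmm(long, screen_spec())

  age <- screen_substances(fit, "age")
  expect_setequal(age$substance[1:3], truth$age_substances)
  expect_true(all(
    age$direction[age$substance %in% truth$age_substances] == "decreasing"
  ))

  par <- screen_substances(fit, "parity")
  expect_setequal(par$substance[1:2], truth$parity_substances)
  expect_true(all(par$direction %in% c("nulliparous", "parous")))
})

test_that("a pure per-substance location shift flags nothing when normalised", {
  set.seed(58)
  design <- generate_design(small_config(n_handling = 0, n_air = 0),
    seed = 58
  )
  n_sub <- 8
  offsets <- seq(10, 80, length.out = n_sub)
  m <- matrix(rnorm(nrow(design) * n_sub, sd = 0.1),
    nrow = nrow(design)
  ) + rep(offsets, each = nrow(design))
  colnames(m) <- sprintf("sub%02d", seq_len(n_sub))
  wide <- dplyr::bind_cols(
    tibble::tibble(sample_id = design$sample_id),
    tibble::as_tibble(m)
  )
  long <- vectorise(transform_response(wide, "normalised"), design)
  fit <- fit_lmm(long, screen_spec())
  sc <- screen_substances(fit, "cycle")
  expect_false(any(sc$flagged))
})

test_that("VIF matches the direct-regression oracle", {
  # orthogonal balanced design
  df <- tibble::tibble(
    x1 = rep(c(-1, 1), 8),
    x2 = rep(c(-1, -1, 1, 1), 4)
  )
  v <- vif(df, c("x1", "x2"))
  expect_equal(v$vif, c(1, 1))

  # duplicated column is reported as infinite, not an error
  df$x3 <- df$x1
  v3 <- vif(df, c("x1", "x2", "x3"))
  expect_true(is.infinite(v3$vif[v3$term == "x3"]))

  # correlated continuous predictors against 1 / (1 - R^2)
  set.seed(59)
  z1 <- rnorm(200)
  z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(200)
  z3 <- rnorm(200)
  df2 <- tibble::tibble(z1 = z1, z2 = z2, z3 = z3)
  v2 <- vif(df2, c("z1", "z2", "z3"))
  r2 <- summary(stats::lm(z1 ~ z2 + z3))$r.squared
  expect_equal(v2$vif[v2$term == "z1"], 1 / (1 - r2), tolerance = 1e-6)
  expect_error(vif(df2, "z1"), "two fixed terms")
})

test_that("tidy and glance expose fit and screen summaries", {
  fx <- make_long_fixture(seed = 60, n_substances = 10)
  fit <- fit_lmm(fx$long, screen_spec())
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_true("(Intercept)" %in% td$term)
  gl <- glance(fit)
  expect_equal(gl$method, "ML")
  expect_true(gl$converged)
  sc <- screen_substances(fit, "cycle")
  expect_equal(nrow(tidy(sc)), 10)
  expect_equal(glance(sc)$n_substances, 10)
})
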