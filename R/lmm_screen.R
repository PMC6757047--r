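#' Vectorise a substance matrix into model-ready long data
#'
#' Stacks the samples-by-substances response matrix into one row per
#' (sample, substance) pair — 212 samples x 160 substances give 33,920
#' response rows — replicating the sample covariates for every substance.
#' Age is z-transformed over the female-level values (each female counted
#' once), so the age slope is per standard deviation of female age. Row
#' order is sample-major and deterministic.
#'
#' @param x A `transformed_response`, `relative_area_table`, or wide tibble
#'   (`sample_id` + one numeric column per substance). Blanks must already be
#'   excluded.
#' @param metadata Design/metadata tibble covering every sample in `x`.
#' @return A long tibble with columns `y`, `substance`, `sample_id`,
#'   `female_id`, `room`, `batch`, `cycle_state`, `age_z`, `parity`, `side`,
#'   `ultrasound`, `a1`..`a4`.
#' @export
vectorise <- function(x, metadata) {
  wide <- if (inherits(x, "transformed_response")) {
    x$y
  } else if (inherits(x, "relative_area_table")) {
    x$rel
  } else {
    x
  }
  missing <- setdiff(wide$sample_id, metadata$sample_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "Metadata is missing sample(s): %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  meta <- metadata[match(wide$sample_id, metadata$sample_id), ]
  if (any(meta$is_blank)) {
    abort("Blank samples must be excluded before vectorising.")
  }
  females <- meta |> distinct(.data$female_id, .data$age)
  z <- if (nrow(females) > 1 && sd(females$age) > 0) {
    setNames(
      (females$age - mean(females$age)) / sd(females$age),
      females$female_id
    )
  } else {
    setNames(rep(0, nrow(females)), females$female_id)
  }

  substances <- setdiff(names(wide), "sample_id")
  n_s <- nrow(wide)
  n_k <- length(substances)
  long <- tibble(
    y = as.vector(t(as.matrix(wide[substances]))),
    substance = rep(substances, times = n_s),
    sample_id = rep(wide$sample_id, each = n_k),
    female_id = rep(meta$female_id, each = n_k),
    room = rep(meta$room, each = n_k),
    batch = rep(meta$batch, each = n_k),
    cycle_state = rep(meta$cycle_state, each = n_k),
    age_z = rep(unname(z[meta$female_id]), each = n_k),
    parity = rep(meta$parity, each = n_k),
    side = rep(meta$side, each = n_k),
    ultrasound = rep(meta$ultrasound, each = n_k),
    a1 = rep(meta$a1, each = n_k),
    a2 = rep(meta$a2, each = n_k),
    a3 = rep(meta$a3, each = n_k),
    a4 = rep(meta$a4, each = n_k)
  )
  attr(long, "substances") <- substances
  attr(long, "samples") <- wide$sample_id
  long
}

#' Recover the wide matrix from vectorised long data
#'
#' Inverse of [vectorise()] for the response column.
#'
#' @param long A [vectorise()] result.
#' @return The wide tibble (`sample_id` + one column per substance).
#' @export
un_vectorise <- function(long) {
  long |>
    select("sample_id", "substance", "y") |>
    tidyr::pivot_wider(names_from = "substance", values_from = "y")
}

#' Build a mixed-model specification
#'
#' Enumerates the model terms of the substance-screening mixed model: fixed
#' effects for the study covariates; random intercepts for sample (matrix
#' rows), substance (matrix columns), female, room and sampling batch; an
#' uncorrelated random slope of z-scored age within substance; and random
#' interaction intercepts of the design factors within substance, female,
#' room and batch. Each random interaction is parameterised as one
#' independent variance component (`(1 | grouping:factor)`), so dropping a
#' single test predictor changes the parameter count by exactly one. The
#' default enumeration yields 33 predictor variables; the test predictors
#' are the substance-by-cycle and substance-by-parity interactions and the
#' age slope within substance.
#'
#' @param fixed Fixed-effect variables.
#' @param random_intercept Grouping variables with plain random intercepts.
#' @param random_slope Named character vector `c(grouping = variable)` of
#'   uncorrelated random slopes.
#' @param random_interaction Named list `list(grouping = variables)` of
#'   random interaction intercepts.
#' @param test_predictors Term ids (see the `term_id` column of the result)
#'   treated as test predictors.
#' @param response Name of the response column.
#' @return An object of class `model_spec` with a `terms` tibble.
#' @export
build_model_spec <- function(fixed = c(
                               "cycle_state", "age_z", "parity", "side",
                               "ultrasound", "a1", "a2", "a3", "a4"
                             ),
                             random_intercept = c(
                               "sample_id", "substance", "female_id",
                               "room", "batch"
                             ),
                             random_slope = c(substance = "age_z"),
                             random_interaction = list(
                               substance = c(
                                 "cycle_state", "parity", "side",
                                 "ultrasound", "a1", "a2", "a3", "a4"
                               ),
                               female_id = c(
                                 "cycle_state", "ultrasound",
                                 "a1", "a2", "a3", "a4"
                               ),
                               room = c("cycle_state", "ultrasound"),
                               batch = c("cycle_state", "ultrasound")
                             ),
                             test_predictors = c(
                               "(1|substance:cycle_state)",
                               "(1|substance:parity)",
                               "(0+age_z|substance)"
                             ),
                             response = "y") {
  known <- c(
    "y", "substance", "sample_id", "female_id", "room", "batch",
    "cycle_state", "age_z", "parity", "side", "ultrasound",
    "a1", "a2", "a3", "a4"
  )
  used <- unique(c(
    fixed, random_intercept, names(random_slope), unname(random_slope),
    names(random_interaction), unlist(random_interaction)
  ))
  unknown <- setdiff(used, known)
  if (length(unknown) > 0) {
    abort(sprintf(
      "Unknown model term(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  terms <- bind_rows(
    tibble(
      type = "fixed", grouping = NA_character_, variable = fixed,
      term_id = fixed
    ),
    tibble(
      type = "intercept", grouping = random_intercept,
      variable = NA_character_,
      term_id = sprintf("(1|%s)", random_intercept)
    ),
    if (length(random_slope) > 0) {
      tibble(
        type = "slope", grouping = names(random_slope),
        variable = unname(random_slope),
        term_id = sprintf(
          "(0+%s|%s)", unname(random_slope), names(random_slope)
        )
      )
    },
    if (length(random_interaction) > 0) {
      tibble(
        type = "interaction",
        grouping = rep(
          names(random_interaction),
          lengths(random_interaction)
        ),
        variable = unlist(random_interaction, use.names = FALSE)
      ) |>
        mutate(term_id = sprintf("(1|%s:%s)", .data$grouping, .data$variable))
    }
  )
  bad <- setdiff(test_predictors, terms$term_id)
  if (length(bad) > 0) {
    abort(sprintf(
      "Test predictor(s) not in the enumerated terms: %s",
      paste(bad, collapse = ", ")
    ))
  }
  terms$test_predictor <- terms$term_id %in% test_predictors
  structure(
    list(terms = terms, response = response),
    class = "model_spec"
  )
}

#' Number of predictor variables in a model specification
#'
#' Counts every fixed effect and every variance component (each random
#' interaction once), the convention under which the default specification
#' has 33 predictor variables.
#'
#' @param spec A `model_spec`.
#' @return Integer count.
#' @export
n_predictors <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  nrow(spec$terms)
}

#' Drop terms from a model specification
#'
#' @param spec A `model_spec`.
#' @param term_ids Term ids to remove; defaults to all test predictors,
#'   yielding the null specification.
#' @return The reduced `model_spec`.
#' @export
drop_terms <- function(spec, term_ids = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  term_ids <- term_ids %||% spec$terms$term_id[spec$terms$test_predictor]
  missing <- setdiff(term_ids, spec$terms$term_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "Cannot drop unknown term(s): %s", paste(missing, collapse = ", ")
    ))
  }
  spec$terms <- spec$terms |> filter(!.data$term_id %in% term_ids)
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> %d predictor variables (%d fixed, %d variance components; %d test predictors)\n",
    n_predictors(x), sum(x$terms$type == "fixed"),
    sum(x$terms$type != "fixed"), sum(x$terms$test_predictor)
  ))
  cat(deparse1(spec_formula(x)), "\n")
  invisible(x)
}

#' Model formula of a specification
#'
#' @param spec A `model_spec`.
#' @return A formula suitable for [lme4::lmer()] (or [stats::lm()] when the
#'   specification has no random terms).
#' @export
spec_formula <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  fixed <- spec$terms$term_id[spec$terms$type == "fixed"]
  random <- spec$terms$term_id[spec$terms$type != "fixed"]
  rhs <- c(if (length(fixed) > 0) fixed else "1", random)
  stats::as.formula(
    paste(spec$response, "~", paste(rhs, collapse = " + ")),
    env = globalenv()
  )
}

#' Fit the screening mixed model
#'
#' Fits the Gaussian mixed model described by a [build_model_spec()] via
#' [lme4::lmer()] with independent variance components (sparse model
#' matrices keep the 33,920-row study-scale problem feasible on one CPU).
#' Use maximum likelihood (`"ML"`, the default) for any fit that feeds a
#' likelihood-ratio test; `"REML"` is offered for variance-component
#' reporting. Variance parameters are constrained nonnegative by
#' construction; a fit that does not converge is flagged and refused by
#' [lrt()].
#'
#' @param data Long data from [vectorise()].
#' @param spec A `model_spec`.
#' @param method `"ML"` or `"REML"`.
#' @return An object of class `lmm_fit` wrapping the fitted model with its
#'   specification, log-likelihood, parameter count and convergence record.
#' @export
fit_lmm <- function(data, spec, method = c("ML", "REML")) {
  stopifnot(inherits(spec, "model_spec"))
  method <- match.arg(method)
  vars <- unique(c(
    spec$response,
    spec$terms$variable[spec$terms$type == "fixed"],
    spec$terms$grouping[spec$terms$type != "fixed"],
    spec$terms$variable[spec$terms$type %in% c("slope", "interaction")]
  ))
  vars <- vars[!is.na(vars)]
  missing <- setdiff(vars, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "Data lacks column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  form <- spec_formula(spec)
  has_random <- any(spec$terms$type != "fixed")
  converged <- TRUE
  messages <- character()
  if (has_random) {
    model <- withCallingHandlers(
      lme4::lmer(
        form,
        data = data, REML = (method == "REML"),
        control = lme4::lmerControl(calc.derivs = FALSE)
      ),
      warning = function(w) {
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        messages <<- c(messages, conditionMessage(m))
        invokeRestart("muffleMessage")
      }
    )
    opt_ok <- isTRUE(model@optinfo$conv$opt == 0)
    lme4_ok <- length(model@optinfo$conv$lme4) == 0 ||
      is.null(model@optinfo$conv$lme4$code)
    converged <- opt_ok && lme4_ok &&
      !any(grepl("failed to converge", messages, fixed = TRUE))
  } else {
    model <- stats::lm(form, data = data)
  }
  ll <- logLik(model)
  structure(
    list(
      model = model,
      spec = spec,
      method = method,
      logLik = as.numeric(ll),
      n_par = attr(ll, "df"),
      nobs = stats::nobs(model),
      converged = converged,
      messages = messages
    ),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> %s fit, %d obs, %d parameters, logLik %.2f%s\n",
    x$method, x$nobs, x$n_par, x$logLik,
    if (x$converged) "" else " (NOT converged)"
  ))
  invisible(x)
}

#' @export
tidy.lmm_fit <- function(x, effects = "fixed", ...) {
  if (inherits(x$model, "lm")) {
    cf <- summary(x$model)$coefficients
    return(tibble(
      term = rownames(cf),
      estimate = cf[, 1],
      std.error = cf[, 2],
      statistic = cf[, 3]
    ))
  }
  cf <- summary(x$model)$coefficients
  fixed <- tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"]
  )
  if (effects == "fixed") {
    return(fixed)
  }
  vc <- as.data.frame(lme4::VarCorr(x$model))
  bind_rows(
    fixed |> mutate(effect = "fixed"),
    tibble(
      term = paste0(
        "var_", vc$grp,
        ifelse(is.na(vc$var1), "", paste0(".", vc$var1))
      ),
      estimate = vc$vcov,
      effect = "variance"
    )
  )
}

#' @export
glance.lmm_fit <- function(x, ...) {
  tibble(
    logLik = x$logLik,
    n_par = x$n_par,
    nobs = x$nobs,
    method = x$method,
    converged = x$converged
  )
}

#' Likelihood-ratio test between nested fits
#'
#' Compares two maximum-likelihood fits of nested specifications:
#' `chi2 = 2 (logLik_full - logLik_reduced)` clipped at zero, with degrees of
#' freedom equal to the parameter-count difference, referred to the nominal
#' chi-square distribution. When the dropped terms are variance components,
#' the true null distribution lives partly on the boundary, so the nominal
#' p-value is conservative; this is standard practice and is documented
#' rather than corrected.
#'
#' @param full,reduced `lmm_fit` objects fitted by ML on identical data,
#'   with `reduced`'s terms a subset of `full`'s.
#' @return A one-row tibble of class `lrt_result` with `chisq`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "lmm_fit"), inherits(reduced, "lmm_fit"))
  if (full$method != "ML" || reduced$method != "ML") {
    abort("Likelihood-ratio tests require ML fits.")
  }
  if (!full$converged || !reduced$converged) {
    abort("Refusing a likelihood-ratio test on a non-converged fit.")
  }
  if (full$nobs != reduced$nobs) {
    abort("Fits use different data (observation counts differ).")
  }
  if (!all(reduced$spec$terms$term_id %in% full$spec$terms$term_id)) {
    abort("Specifications are not nested.")
  }
  chisq <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- full$n_par - reduced$n_par
  if (df < 0) abort("Reduced model has more parameters than the full model.")
  p <- if (df == 0) {
    1
  } else {
    pchisq(chisq, df = df, lower.tail = FALSE)
  }
  out <- tibble(chisq = chisq, df = df, p = p)
  class(out) <- c("lrt_result", class(out))
  out
}

#' Flag the most affected substances from a score vector
#'
#' Implements the screening rule: a substance is flagged when its absolute
#' slope score is at least two standard deviations above the mean absolute
#' score. The SD uses the population (n-denominator) convention so that a
#' homogeneous strongly-affected subset at the one-sided Chebyshev boundary
#' is still flaggable in the low-noise limit. Degenerate edge: when all
#' scores are equal, everything is flagged if the common score is positive
#' and nothing if it is zero.
#'
#' @param scores Named nonnegative numeric vector of per-substance scores.
#' @return A list with `threshold` and the logical `flagged` vector.
#' @export
flag_most_affected <- function(scores) {
  s <- sd_pop(scores)
  threshold <- mean(scores) + 2 * s
  if (s == 0) {
    flagged <- if (mean(scores) > 0) {
      rep(TRUE, length(scores))
    } else {
      rep(FALSE, length(scores))
    }
  } else {
    flagged <- scores >= threshold - 1e-12
  }
  names(flagged) <- names(scores)
  list(threshold = threshold, flagged = flagged)
}

ranef_component <- function(model, grouping, column) {
  re <- lme4::ranef(model)
  hits <- which(names(re) == grouping)
  for (h in hits) {
    if (column %in% names(re[[h]])) {
      return(re[[h]])
    }
  }
  NULL
}

#' Screen substances for a test predictor
#'
#' Extracts the per-substance conditional modes (BLUP analogues) of one test
#' predictor and flags the most affected substances by the two-SD rule:
#' * `age` - score is the absolute random age slope of the substance;
#'   direction is `increasing`/`decreasing`.
#' * `parity` - score is the absolute contrast between the two parity-level
#'   modes; direction names the level with the higher mode.
#' * `cycle` - score is the largest absolute deviation of a cycle-state mode
#'   from the substance's mean state mode; direction names the state with
#'   the highest mode.
#'
#' @param fit An `lmm_fit` whose specification contains the corresponding
#'   component.
#' @param predictor One of `"cycle"`, `"age"`, `"parity"`.
#' @return A tibble of class `screen_result` (`substance`, `score`,
#'   `direction`, `flagged`), sorted by decreasing score, with `threshold`,
#'   `predictor` and `n_flagged` attributes.
#' @export
screen_substances <- function(fit, predictor = c("cycle", "age", "parity")) {
  stopifnot(inherits(fit, "lmm_fit"))
  predictor <- match.arg(predictor)
  model <- fit$model
  if (inherits(model, "lm")) {
    abort("Screening needs a mixed model with substance-level components.")
  }

  if (predictor == "age") {
    comp <- ranef_component(model, "substance", "age_z")
    if (is.null(comp)) {
      abort("Fit has no random age slope within substance.")
    }
    scores <- abs(comp$age_z)
    names(scores) <- rownames(comp)
    direction <- ifelse(comp$age_z >= 0, "increasing", "decreasing")
    names(direction) <- rownames(comp)
  } else {
    grouping <- if (predictor == "cycle") {
      "substance:cycle_state"
    } else {
      "substance:parity"
    }
    comp <- ranef_component(model, grouping, "(Intercept)")
    if (is.null(comp)) {
      abort(sprintf("Fit has no %s interaction component.", grouping))
    }
    parts <- strsplit(rownames(comp), ":", fixed = TRUE)
    modes <- tibble(
      substance = map_chr(parts, 1),
      level = map_chr(parts, 2),
      mode = comp[["(Intercept)"]]
    )
    per_sub <- modes |>
      group_by(.data$substance) |>
      summarise(
        score = if (predictor == "cycle") {
          max(abs(.data$mode - mean(.data$mode)))
        } else {
          abs(diff(range(.data$mode)))
        },
        direction = .data$level[which.max(.data$mode)],
        .groups = "drop"
      )
    scores <- setNames(per_sub$score, per_sub$substance)
    direction <- setNames(per_sub$direction, per_sub$substance)
  }

  fl <- flag_most_affected(scores)
  out <- tibble(
    substance = names(scores),
    score = unname(scores),
    direction = unname(direction),
    flagged = unname(fl$flagged)
  ) |>
    arrange(dplyr::desc(.data$score))
  attr(out, "threshold") <- fl$threshold
  attr(out, "predictor") <- predictor
  attr(out, "n_flagged") <- sum(fl$flagged)
  class(out) <- c("screen_result", class(out))
  out
}

#' @export
tidy.screen_result <- function(x, ...) {
  out <- x
  out$threshold <- attr(x, "threshold")
  out$predictor <- attr(x, "predictor")
  class(out) <- class(tibble())
  out
}

#' @export
glance.screen_result <- function(x, ...) {
  tibble(
    predictor = attr(x, "predictor"),
    threshold = attr(x, "threshold"),
    n_flagged = attr(x, "n_flagged"),
    n_substances = nrow(x)
  )
}

#' Variance inflation factors of the fixed-effect design
#'
#' Computes, for every non-intercept column of the fixed-effects design
#' matrix, `VIF = 1 / (1 - R^2)` where `R^2` comes from regressing that
#' column on all the others. Random-effect structure is ignored. Perfectly
#' collinear columns get `Inf` rather than an error.
#'
#' @param data Long data (or any data frame with the fixed-effect columns).
#' @param fixed_terms Fixed-effect variable names (>= 2).
#' @return A tibble (`term`, `vif`), one row per design-matrix column.
#' @export
vif <- function(data, fixed_terms) {
  if (length(fixed_terms) < 2) {
    abort("VIF needs at least two fixed terms.")
  }
  mm <- stats::model.matrix(
    stats::reformulate(fixed_terms),
    data = as.data.frame(data)
  )
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  map(seq_len(ncol(mm)), function(j) {
    xj <- mm[, j]
    others <- mm[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, others), xj)
    tss <- sum((xj - mean(xj))^2)
    if (tss == 0) {
      return(tibble(term = colnames(mm)[j], vif = NA_real_))
    }
    r2 <- 1 - sum(fit$residuals^2) / tss
    tibble(
      term = colnames(mm)[j],
      vif = if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
    )
  }) |>
    bind_rows()
}

#' Full and per-predictor likelihood-ratio tests with flag counts
#'
#' The reporting surface of the screen: fits the full specification, the
#' null specification lacking all test predictors, and one reduced fit per
#' test predictor; returns the full-null and per-predictor LRTs together
#' with the number of most-affected substances flagged for each significant
#' predictor.
#'
#' @param data Long data from [vectorise()].
#' @param spec Full `model_spec`.
#' @param alpha Significance level deciding which predictors are screened.
#' @return A tibble (`predictor`, `chisq`, `df`, `p`, `n_flagged`) with the
#'   fitted models in the `"fits"` attribute.
#' @export
lrt_table <- function(data, spec, alpha = 0.05) {
  full <- fit_lmm(data, spec, method = "ML")
  null_fit <- fit_lmm(data, drop_terms(spec), method = "ML")
  rows <- list(
    bind_cols(tibble(predictor = "full-null"), lrt(full, null_fit)) |>
      mutate(n_flagged = NA_integer_)
  )
  tp <- spec$terms$term_id[spec$terms$test_predictor]
  label <- function(id) {
    if (grepl("cycle_state", id)) {
      "cycle"
    } else if (grepl("age_z", id)) {
      "age"
    } else if (grepl("parity", id)) {
      "parity"
    } else {
      id
    }
  }
  for (id in tp) {
    red <- fit_lmm(data, drop_terms(spec, id), method = "ML")
    res <- lrt(full, red)
    pred <- label(id)
    n_flag <- if (res$p <= alpha && pred %in% c("cycle", "age", "parity")) {
      attr(screen_substances(full, pred), "n_flagged")
    } else {
      NA_integer_
    }
    rows <- c(rows, list(
      bind_cols(tibble(predictor = pred), res) |>
        mutate(n_flagged = n_flag)
    ))
  }
  out <- bind_rows(rows)
  attr(out, "fits") <- list(full = full, null = null_fit)
  out
}

#' @rdname autoplot-semioprofile
#' @export
autoplot.screen_result <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(substance = factor(.data$substance, levels = rev(.data$substance)))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$score, y = .data$substance, colour = .data$flagged)
  ) +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, xend = .data$score, yend = .data$substance),
      linewidth = 0.3
    ) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_vline(
      xintercept = attr(object, "threshold"),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey55")
    ) +
    ggplot2::labs(
      title = sprintf(
        "Most affected substances: %s", attr(object, "predictor")
      ),
      subtitle = sprintf(
        "threshold (mean + 2 SD) = %.3g; %d flagged",
        attr(object, "threshold"), attr(object, "n_flagged")
      ),
      x = "absolute slope score", y = NULL, colour = "flagged"
    ) +
    ggplot2::theme_minimal()
}

#' Plot one substance against a predictor
#'
#' Diagnostic view of a single substance's response: boxplots over cycle
#' states or parity levels, or a scatter against z-scored age.
#'
#' @param long Long data from [vectorise()].
#' @param substance Substance id to plot.
#' @param predictor `"cycle"`, `"age"` or `"parity"`.
#' @return A ggplot object.
#' @export
plot_substance_effect <- function(long, substance,
                                  predictor = c("cycle", "age", "parity")) {
  predictor <- match.arg(predictor)
  df <- long |> filter(.data$substance == !!substance)
  if (nrow(df) == 0) abort(sprintf("Unknown substance '%s'.", substance))
  if (predictor == "age") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$age_z, y = .data$y)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_smooth(
        method = "lm", formula = y ~ x, se = FALSE,
        linetype = "dashed", colour = "firebrick"
      ) +
      ggplot2::labs(
        title = substance, x = "age (z-scored years)", y = "response"
      ) +
      ggplot2::theme_minimal()
  } else {
    xvar <- if (predictor == "cycle") "cycle_state" else "parity"
    ggplot2::ggplot(
      df, ggplot2::aes(x = .data[[xvar]], y = .data$y)
    ) +
      ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
      ggplot2::labs(title = substance, x = xvar, y = "response") +
      ggplot2::theme_minimal()
  }
}
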