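#' Bray-Curtis dissimilarity matrix
#'
#' Computes pairwise Bray-Curtis dissimilarities
#' `d(i, j) = sum|x_i - x_j| / sum(x_i + x_j)` between sample profiles.
#' Inputs must be nonnegative; apply the `log1p` transform first when
#' comparing whole chemical profiles. A pair of all-zero profiles gets
#' dissimilarity 0.
#'
#' @param x A wide tibble (`sample_id` + numeric columns), a
#'   `transformed_response`/`relative_area_table`, or a numeric matrix with
#'   samples in rows.
#' @return A symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, and sample ids as dimnames; `"method"` attribute set to
#'   `"bray-curtis"`.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "transformed_response")) {
    wide_to_matrix(x$y)
  } else if (inherits(x, "relative_area_table")) {
    wide_to_matrix(x$rel)
  } else if (is.matrix(x)) {
    x
  } else {
    wide_to_matrix(x)
  }
  if (any(m < 0)) abort("Bray-Curtis requires nonnegative inputs.")
  num <- as.matrix(dist(m, method = "manhattan"))
  den <- outer(rowSums(m), rowSums(m), "+")
  d <- ifelse(den > 0, num / den, 0)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "method") <- "bray-curtis"
  d
}

#' ANOSIM R statistic
#'
#' Rank-based analysis-of-similarities statistic: all off-diagonal
#' dissimilarities are ranked (average ranks for ties) and
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` with
#' `M = n(n-1)/2`. `R` is 1 when all between-group dissimilarities exceed all
#' within-group ones and near 0 when grouping is unrelated to profile
#' similarity.
#'
#' @param d A dissimilarity matrix, e.g. from [bray_curtis()].
#' @param groups Group label per sample (recycled against `d`'s rows).
#' @return The scalar R statistic in `[-1, 1]`.
#' @export
anosim_statistic <- function(d, groups) {
  n <- nrow(d)
  groups <- as.character(groups)
  if (length(groups) != n) {
    abort("`groups` must have one label per sample in `d`.")
  }
  if (n_distinct(groups) < 2) {
    abort("ANOSIM needs at least two groups.")
  }
  lw <- lower.tri(d)
  r <- rank(d[lw])
  idx <- which(lw, arr.ind = TRUE)
  anosim_r_from_ranks(r, groups[idx[, 1]] != groups[idx[, 2]], n)
}

anosim_r_from_ranks <- function(ranks, between, n) {
  if (!any(between) || all(between)) {
    abort("ANOSIM needs both within- and between-group sample pairs.")
  }
  m <- n * (n - 1) / 2
  (mean(ranks[between]) - mean(ranks[!between])) / (m / 2)
}

# All distinct permutations of a label multiset (used for exhaustive
# restricted permutation tests on small designs).
multiset_perms <- function(labels) {
  if (length(labels) <= 1) {
    return(list(labels))
  }
  out <- list()
  for (u in unique(labels)) {
    rest <- labels[-match(u, labels)]
    out <- c(out, map(multiset_perms(rest), function(p) c(u, p)))
  }
  out
}

#' Restricted-permutation ANOSIM test
#'
#' ANOSIM whose null distribution respects repeated sampling of individuals.
#' Two permutation schemes are available:
#' * `within_individual` - group labels are shuffled only among the samples
#'   of the same individual, independently per individual. Appropriate for
#'   factors that vary within individuals (cycle state); it is an error when
#'   the factor is constant within every individual, because no
#'   exchangeability is left to exploit.
#' * `individual_level` - the individuals' factor values are permuted across
#'   individuals and propagated to all their samples. Appropriate for
#'   between-individual factors (age, parity), which must be constant within
#'   each individual.
#'
#' The p-value is one-sided on the upper tail of R with add-one correction,
#' `p = (#{R_perm >= R_obs} + 1) / (n_perm + 1)`; with `exact = TRUE` all
#' restricted permutations are enumerated instead and
#' `p = #{R_perm >= R_obs} / n_total` (the identity arrangement included).
#'
#' @param d A dissimilarity matrix.
#' @param groups Factor level per sample.
#' @param individuals Individual (female) id per sample.
#' @param scheme Permutation scheme, see above.
#' @param n_perm Number of Monte-Carlo permutations.
#' @param seed Seed for the permutation stream.
#' @param exact Enumerate all restricted permutations (feasible for small
#'   designs only; capped at 250,000 arrangements).
#' @param factor_name Label used in the result and error messages.
#' @return A one-row tibble of class `anosim_result` with `factor`, `scheme`,
#'   `R`, `p`, `n_perm` and `exact`; the permuted statistics are kept in the
#'   `"perm_R"` attribute.
#' @export
anosim_test <- function(d, groups, individuals,
                        scheme = c("within_individual", "individual_level"),
                        n_perm = 1000, seed = 1, exact = FALSE,
                        factor_name = "group") {
  scheme <- match.arg(scheme)
  n <- nrow(d)
  groups <- as.character(groups)
  individuals <- as.character(individuals)
  stopifnot(length(groups) == n, length(individuals) == n)

  by_ind <- split(seq_len(n), individuals)
  varies <- map_lgl(by_ind, function(ix) n_distinct(groups[ix]) > 1)
  if (scheme == "within_individual" && !any(varies)) {
    abort(sprintf(
      "Factor '%s' is constant within every individual; within-individual permutation has no exchangeability. Use scheme = 'individual_level'.",
      factor_name
    ))
  }
  if (scheme == "individual_level" && any(varies)) {
    abort(sprintf(
      "Factor '%s' varies within individual(s) %s; individual-level permutation requires it to be constant per individual.",
      factor_name,
      paste(names(by_ind)[varies], collapse = ", ")
    ))
  }

  lw <- which(lower.tri(d), arr.ind = TRUE)
  ranks <- rank(d[lower.tri(d)])
  r_of <- function(g) {
    anosim_r_from_ranks(ranks, g[lw[, 1]] != g[lw[, 2]], n)
  }
  r_obs <- r_of(groups)
  eps <- 1e-12

  if (exact) {
    if (scheme == "within_individual") {
      per_ind <- map(by_ind, function(ix) multiset_perms(groups[ix]))
      total <- prod(map_dbl(per_ind, length))
      if (total > 250000) {
        abort("Exhaustive enumeration infeasible (> 250,000 arrangements).")
      }
      combos <- expand.grid(
        map(per_ind, seq_along),
        KEEP.OUT.ATTRS = FALSE
      )
      perm_r <- map_dbl(seq_len(nrow(combos)), function(k) {
        g <- groups
        for (f in seq_along(by_ind)) {
          g[by_ind[[f]]] <- per_ind[[f]][[combos[k, f]]]
        }
        r_of(g)
      })
    } else {
      ind_levels <- names(by_ind)
      vals <- map_chr(by_ind, function(ix) groups[ix[1]])
      perms <- multiset_perms(unname(vals))
      if (length(perms) > 250000) {
        abort("Exhaustive enumeration infeasible (> 250,000 arrangements).")
      }
      perm_r <- map_dbl(perms, function(v) {
        g <- groups
        for (f in seq_along(ind_levels)) {
          g[by_ind[[f]]] <- v[f]
        }
        r_of(g)
      })
    }
    p <- mean(perm_r >= r_obs - eps)
    n_used <- length(perm_r)
  } else {
    set_stream(seed, "anosim")
    perm_r <- map_dbl(seq_len(n_perm), function(k) {
      g <- groups
      if (scheme == "within_individual") {
        for (ix in by_ind) {
          g[ix] <- g[ix][sample.int(length(ix))]
        }
      } else {
        vals <- map_chr(by_ind, function(ix) groups[ix[1]])
        vals <- vals[sample.int(length(vals))]
        for (f in seq_along(by_ind)) {
          g[by_ind[[f]]] <- vals[f]
        }
      }
      r_of(g)
    })
    p <- (sum(perm_r >= r_obs - eps) + 1) / (n_perm + 1)
    n_used <- n_perm
  }

  out <- tibble(
    factor = factor_name,
    scheme = scheme,
    R = r_obs,
    p = p,
    n_perm = n_used,
    exact = exact
  )
  attr(out, "perm_R") <- perm_r
  class(out) <- c("anosim_result", class(out))
  out
}

#' Whole-profile ANOSIM on relative areas
#'
#' Pipeline surface for the profile-similarity analysis: takes the relative
#' area table, applies the `log1p` transform, computes Bray-Curtis
#' dissimilarities over the animal samples and runs the restricted
#' permutation ANOSIM for one metadata factor.
#'
#' @param rel A `relative_area_table` (animal samples only).
#' @param metadata Design/metadata tibble with `sample_id`, `female_id` and
#'   the factor column.
#' @param factor Name of the metadata column to test (string).
#' @param scheme,n_perm,seed,exact Passed to [anosim_test()]; the default
#'   scheme is chosen automatically: `within_individual` when the factor
#'   varies within females, `individual_level` otherwise.
#' @return An `anosim_result`.
#' @export
profile_anosim <- function(rel, metadata, factor,
                           scheme = NULL, n_perm = 1000, seed = 1,
                           exact = FALSE) {
  wide <- if (inherits(rel, "relative_area_table")) rel$rel else rel
  meta <- metadata |>
    filter(!.data$is_blank, .data$sample_id %in% wide$sample_id)
  wide <- wide |> filter(.data$sample_id %in% meta$sample_id)
  meta <- meta[match(wide$sample_id, meta$sample_id), ]
  d <- bray_curtis(transform_response(wide, "log1p"))
  groups <- as.character(meta[[factor]])
  if (is.null(scheme)) {
    varies <- any(map_lgl(
      split(groups, meta$female_id),
      function(g) n_distinct(g) > 1
    ))
    scheme <- if (varies) "within_individual" else "individual_level"
  }
  anosim_test(d, groups, meta$female_id,
    scheme = scheme, n_perm = n_perm,
    seed = seed, exact = exact, factor_name = factor
  )
}

#' @export
tidy.anosim_result <- function(x, ...) {
  out <- x
  attr(out, "perm_R") <- NULL
  class(out) <- class(tibble())
  out
}

#' @rdname autoplot-semioprofile
#' @export
autoplot.anosim_result <- function(object, ...) {
  perm <- tibble(R = attr(object, "perm_R"))
  ggplot2::ggplot(perm, ggplot2::aes(x = .data$R)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(
      xintercept = object$R, colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::labs(
      title = sprintf(
        "ANOSIM: %s (%s permutation)", object$factor, object$scheme
      ),
      subtitle = sprintf(
        "R = %.3f, p = %.4g (%d permutations)",
        object$R, object$p, object$n_perm
      ),
      x = "permuted R", y = "count"
    ) +
    ggplot2::theme_minimal()
}
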