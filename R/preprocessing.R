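add_provenance <- function(x, step, detail) {
  x$provenance <- bind_rows(x$provenance, tibble(step = step, detail = detail))
  x
}

#' Remove known contaminants
#'
#' Excludes every range whose representative retention time falls inside a
#' contaminant entry's RT window *and* whose prominent m/z set intersects the
#' entry's characteristic m/z. Substances that merely co-elute with a
#' contaminant but share no fragments are retained.
#'
#' @param x An `aligned_table`.
#' @param contaminants A tibble with `rt_low`, `rt_high` and an `mz`
#'   list-column (or ";"-separated string), e.g. from [contaminant_list()]
#'   or [read_contaminants()]. An empty list leaves the table unchanged.
#' @return The filtered `aligned_table`; removed range ids are logged in the
#'   provenance.
#' @export
remove_contaminants <- function(x, contaminants) {
  stopifnot(inherits(x, "aligned_table"))
  if (nrow(contaminants) == 0) {
    return(add_provenance(x, "contaminant_filter", "empty list; no change"))
  }
  if (!is.list(contaminants$mz)) {
    contaminants$mz <- map(
      strsplit(as.character(contaminants$mz), ";", fixed = TRUE),
      as.integer
    )
  }
  hit <- map_lgl(seq_len(nrow(x$ranges)), function(i) {
    rt <- x$ranges$representative_rt[i]
    pmz <- x$ranges$prominent_mz[[i]]
    any(map_lgl(seq_len(nrow(contaminants)), function(j) {
      rt >= contaminants$rt_low[j] && rt <= contaminants$rt_high[j] &&
        length(intersect(pmz, contaminants$mz[[j]])) > 0
    }))
  })
  removed <- x$ranges$range_id[hit]
  x$ranges <- x$ranges[!hit, ]
  x$areas <- x$areas |> select("sample_id", dplyr::all_of(x$ranges$range_id))
  add_provenance(x, "contaminant_filter", sprintf(
    "removed %d range(s): %s", length(removed),
    paste(removed, collapse = ",")
  ))
}

#' Blank-based background exclusion
#'
#' Compares every substance's raw peak areas between blank and animal samples
#' and drops it when the blank statistic equals or exceeds the animal
#' statistic (ties go to exclusion). The comparison runs on raw areas, before
#' relative normalisation. Blanks are excluded from all downstream statistics
#' once filtering is done; set `drop_blanks = TRUE` to remove their rows here
#' (the default keeps them so the filter is idempotent on the substance set).
#'
#' @param x An `aligned_table`.
#' @param blank_ids Character vector of blank sample ids, or a design/metadata
#'   tibble with `sample_id` and `is_blank`.
#' @param statistic Aggregator over samples, `"mean"` (default) or
#'   `"median"`.
#' @param drop_blanks Also remove the blank rows from the table.
#' @return The filtered `aligned_table`.
#' @export
blank_filter <- function(x, blank_ids, statistic = c("mean", "median"),
                         drop_blanks = FALSE) {
  stopifnot(inherits(x, "aligned_table"))
  statistic <- match.arg(statistic)
  if (is.data.frame(blank_ids)) {
    blank_ids <- blank_ids$sample_id[blank_ids$is_blank]
  }
  m <- wide_to_matrix(x$areas)
  is_blank <- rownames(m) %in% blank_ids
  if (!any(is_blank)) {
    abort("No blank samples present; the blank filter cannot run.")
  }
  fun <- if (statistic == "mean") colMeans else function(z) apply(z, 2, median)
  blank_stat <- fun(m[is_blank, , drop = FALSE])
  animal_stat <- fun(m[!is_blank, , drop = FALSE])
  drop <- blank_stat >= animal_stat
  removed <- colnames(m)[drop]
  x$ranges <- x$ranges |> filter(!.data$range_id %in% removed)
  x$areas <- x$areas |> select("sample_id", dplyr::all_of(x$ranges$range_id))
  if (drop_blanks) {
    x$areas <- x$areas |> filter(!.data$sample_id %in% blank_ids)
  }
  add_provenance(x, "blank_filter", sprintf(
    "removed %d range(s) by %s comparison%s",
    length(removed), statistic,
    if (drop_blanks) sprintf("; %d blank row(s) dropped", sum(is_blank)) else ""
  ))
}

#' Relative peak areas
#'
#' Normalises each sample to its total included area: the relative area of a
#' substance is its peak area divided by the sum of all included peak areas,
#' times 100, so every sample's profile sums to 100 percent. All-zero samples
#' stay all-zero with a warning.
#'
#' @param x An `aligned_table` (filters already applied).
#' @return An object of class `relative_area_table` with the wide `rel`
#'   tibble (percent), the range metadata and the accumulated provenance.
#' @export
relative_areas <- function(x) {
  stopifnot(inherits(x, "aligned_table"))
  m <- wide_to_matrix(x$areas)
  totals <- rowSums(m)
  zero <- totals == 0
  if (any(zero)) {
    warn(sprintf(
      "%d sample(s) have zero total area and stay all-zero.", sum(zero)
    ))
    totals[zero] <- 1
  }
  rel <- 100 * m / totals
  structure(
    list(
      rel = matrix_to_wide(rel),
      ranges = x$ranges,
      provenance = bind_rows(x$provenance, tibble(
        step = "relative_areas",
        detail = sprintf("%d samples normalised to 100%%", nrow(m))
      ))
    ),
    class = "relative_area_table"
  )
}

#' @export
print.relative_area_table <- function(x, ...) {
  cat(sprintf(
    "<relative_area_table> %d samples x %d substances (percent)\n",
    nrow(x$rel), nrow(x$ranges)
  ))
  print(x$rel, ...)
  invisible(x)
}

#' Response transforms for the statistical models
#'
#' Produces the three response variants used downstream:
#' * `normalised` - each substance column centred to mean 0 and scaled to
#'   SD 1 (sample SD, n-1 denominator), so all substances carry the same
#'   weight and the models see changes between samples rather than relative
#'   to the rest of the profile; constant columns become all-zero with a
#'   warning.
#' * `log1p` - `ln(x + 1)` elementwise, the transform feeding the
#'   Bray-Curtis dissimilarities.
#' * `log_arcsine` - `ln(x + 0.001)`, rescaled linearly over the whole
#'   matrix to `[-1, 1]`, then arcsine-transformed; the composition is one
#'   documented reading of a log-plus-arcsine recipe and is not claimed to
#'   be the only one (the log output is negative, outside the arcsine
#'   domain, without such a rescale).
#'
#' @param x A `relative_area_table` (or wide tibble of relative areas).
#' @param mode One of `"normalised"`, `"log1p"`, `"log_arcsine"`.
#' @return An object of class `transformed_response` with the wide `y`
#'   tibble and the transform tag.
#' @export
transform_response <- function(x,
                               mode = c("normalised", "log1p", "log_arcsine")) {
  mode <- match.arg(mode)
  wide <- if (inherits(x, "relative_area_table")) x$rel else x
  m <- wide_to_matrix(wide)
  y <- switch(mode,
    normalised = {
      mu <- colMeans(m)
      s <- apply(m, 2, sd)
      const <- s == 0
      if (any(const)) {
        warn(sprintf(
          "%d constant column(s) set to zero under 'normalised'.",
          sum(const)
        ))
        s[const] <- 1
      }
      scale(m, center = mu, scale = s)[, , drop = FALSE]
    },
    log1p = log(m + 1),
    log_arcsine = {
      v <- log(m + 0.001)
      lo <- min(v)
      hi <- max(v)
      u <- if (hi > lo) 2 * (v - lo) / (hi - lo) - 1 else v * 0
      asin(u)
    }
  )
  attr(y, "scaled:center") <- NULL
  attr(y, "scaled:scale") <- NULL
  structure(
    list(
      y = matrix_to_wide(y),
      mode = mode,
      ranges = if (inherits(x, "relative_area_table")) x$ranges else NULL
    ),
    class = "transformed_response"
  )
}

#' Preprocess an aligned table end to end
#'
#' Applies the exclusion rules in the order contaminants, then blanks, and
#' computes relative areas.
#'
#' @param x An `aligned_table`.
#' @param contaminants Known-contaminant table (may be empty).
#' @param metadata Design/metadata tibble identifying blanks; pass `NULL` to
#'   skip the blank filter explicitly.
#' @param blank_statistic Aggregator of the blank comparison.
#' @return A `relative_area_table`.
#' @export
preprocess_profiles <- function(x, contaminants, metadata,
                                blank_statistic = "mean") {
  x <- remove_contaminants(x, contaminants)
  if (!is.null(metadata)) {
    x <- blank_filter(x, metadata,
      statistic = blank_statistic,
      drop_blanks = TRUE
    )
  }
  relative_areas(x)
}
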