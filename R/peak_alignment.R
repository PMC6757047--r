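#' Group peaks into retention-time ranges
#'
#' Pools the peaks of all samples, sorts them by retention time and starts a
#' new range whenever the gap to the previous peak exceeds `gap_tol` (gap
#' based 1-D clustering, equivalent to single-linkage at that threshold, so
#' no substance is split across a fixed bin boundary). Where a sample
#' contributed several peaks to one range, the peak closest to the range's
#' median retention time is kept (ties go to the larger area) and the rest
#' are logged and discarded, so every retained (sample, range) cell has at
#' most one source peak.
#'
#' @param peaks A peak tibble (`sample_id`, `rt`, `area`, `spectrum`), e.g.
#'   from [render_peak_lists()] or [read_peak_lists()].
#' @param gap_tol Retention-time gap (minutes) that separates two ranges.
#' @return An object of class `rt_ranges`: a list with a `ranges` tibble
#'   (`range_id`, `rt_low`, `rt_high`, `representative_rt`, `occurrence`,
#'   `n_members`), the member `peaks` tibble carrying `range_id`, and a `log`
#'   tibble of discarded duplicates.
#' @export
group_retention_times <- function(peaks, gap_tol = 0.05) {
  if (gap_tol <= 0) abort("`gap_tol` must be positive.")
  if (nrow(peaks) == 0) {
    return(structure(
      list(
        ranges = tibble(
          range_id = character(), rt_low = double(), rt_high = double(),
          representative_rt = double(), occurrence = integer(),
          n_members = integer()
        ),
        peaks = peaks,
        log = tibble(event = character(), detail = character())
      ),
      class = "rt_ranges"
    ))
  }
  ord <- peaks |> arrange(.data$rt, .data$sample_id)
  grp <- cumsum(c(TRUE, diff(ord$rt) > gap_tol))
  ord$range_id <- sprintf("R%04d", grp)

  med <- ord |>
    group_by(.data$range_id) |>
    summarise(med_rt = median(.data$rt), .groups = "drop")
  ord <- left_join(ord, med, by = "range_id")

  kept <- ord |>
    group_by(.data$range_id, .data$sample_id) |>
    arrange(abs(.data$rt - .data$med_rt), dplyr::desc(.data$area),
      .by_group = TRUE
    ) |>
    mutate(.keep_peak = row_number() == 1L) |>
    ungroup()
  n_dup <- sum(!kept$.keep_peak)
  log <- tibble(
    event = "duplicate_peaks_discarded",
    detail = sprintf("%d peaks beyond one-per-sample-per-range", n_dup)
  )
  members <- kept |>
    filter(.data$.keep_peak) |>
    select(-".keep_peak", -"med_rt")

  ranges <- members |>
    group_by(.data$range_id) |>
    summarise(
      rt_low = min(.data$rt),
      rt_high = max(.data$rt),
      representative_rt = median(.data$rt),
      occurrence = n_distinct(.data$sample_id),
      n_members = n(),
      .groups = "drop"
    ) |>
    arrange(.data$representative_rt)

  structure(
    list(ranges = ranges, peaks = members, log = log),
    class = "rt_ranges"
  )
}

#' @export
print.rt_ranges <- function(x, ...) {
  cat(sprintf(
    "<rt_ranges> %d ranges over %d peaks from %d samples\n",
    nrow(x$ranges), nrow(x$peaks), n_distinct(x$peaks$sample_id)
  ))
  print(x$ranges, ...)
  invisible(x)
}

#' Per-batch retention-time adjustment
#'
#' Removes chromatographic drift between measurement batches with a global
#' per-batch shift (no warping). Each batch's peaks are grouped on their own
#' first; ranges present in at least `anchor_presence` of the batch's
#' samples become its anchors. Anchors are matched to the reference batch's
#' anchors by nearest retention time within `max_shift`, and the batch is
#' shifted by minus the median anchor RT difference against the reference.
#' A batch without anchor matches keeps shift 0 with a warning.
#'
#' @param peaks A peak tibble.
#' @param batch_map A tibble (`sample_id`, `batch`) or a named character
#'   vector mapping sample ids to batches.
#' @param reference_batch Batch all others are aligned to; defaults to the
#'   batch with the most samples.
#' @param gap_tol Gap tolerance of the per-batch anchor-finding pass.
#' @param anchor_presence Minimum fraction of a batch's samples a range must
#'   occur in to act as an anchor.
#' @param max_shift Largest drift (minutes) considered when matching anchor
#'   ranges across batches.
#' @return The peak tibble with adjusted `rt` and the applied shifts in the
#'   `"rt_shifts"` attribute.
#' @export
adjust_rt_per_batch <- function(peaks, batch_map, reference_batch = NULL,
                                gap_tol = 0.05, anchor_presence = 0.8,
                                max_shift = 0.5) {
  if (!is.data.frame(batch_map)) {
    batch_map <- tibble(
      sample_id = names(batch_map),
      batch = unname(batch_map)
    )
  }
  missing <- setdiff(unique(peaks$sample_id), batch_map$sample_id)
  if (length(missing) > 0) {
    abort(sprintf(
      "No batch assignment for sample(s): %s",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  batch_sizes <- batch_map |>
    filter(.data$sample_id %in% peaks$sample_id) |>
    count(.data$batch, sort = TRUE)
  reference_batch <- reference_batch %||% batch_sizes$batch[1]
  if (!reference_batch %in% batch_sizes$batch) {
    abort(sprintf("Reference batch '%s' has no samples.", reference_batch))
  }
  if (nrow(batch_sizes) == 1) {
    attr(peaks, "rt_shifts") <- tibble(
      batch = reference_batch, shift = 0, n_anchors = NA_integer_
    )
    return(peaks)
  }

  with_batch <- peaks |> left_join(batch_map, by = "sample_id")
  n_per_batch <- setNames(batch_sizes$n, batch_sizes$batch)

  # anchors per batch: ranges of a batch-local grouping pass present in
  # enough of the batch's samples
  batch_anchors <- function(b) {
    sub <- with_batch |> filter(.data$batch == b)
    g <- group_retention_times(
      sub[, c("sample_id", "rt", "area", "spectrum")],
      gap_tol = gap_tol
    )
    g$ranges |>
      filter(.data$occurrence >= anchor_presence * n_per_batch[[b]]) |>
      pull(.data$representative_rt)
  }
  ref_rt <- batch_anchors(reference_batch)

  shifts <- map(setdiff(batch_sizes$batch, reference_batch), function(b) {
    own <- batch_anchors(b)
    diffs <- map_dbl(own, function(rt) {
      i <- which.min(abs(ref_rt - rt))
      if (length(i) == 1 && abs(ref_rt[i] - rt) <= max_shift) {
        rt - ref_rt[i]
      } else {
        NA_real_
      }
    })
    diffs <- diffs[!is.na(diffs)]
    if (length(diffs) == 0) {
      warn(sprintf("Batch '%s' has no anchor matches; shift set to 0.", b))
      return(tibble(batch = b, shift = 0, n_anchors = 0L))
    }
    tibble(
      batch = b,
      shift = -median(diffs),
      n_anchors = length(diffs)
    )
  }) |>
    bind_rows() |>
    bind_rows(tibble(
      batch = reference_batch, shift = 0,
      n_anchors = length(ref_rt)
    ))

  shift_by_sample <- batch_map |>
    left_join(shifts, by = "batch")
  out <- peaks |>
    left_join(
      shift_by_sample |> select("sample_id", "shift"),
      by = "sample_id"
    ) |>
    mutate(rt = .data$rt + .data$shift) |>
    select(-"shift")
  attr(out, "rt_shifts") <- shifts
  out
}

#' Filter ranges by sample occurrence
#'
#' Keeps only the retention-time ranges that occur in at least
#' `min_occurrence` samples (default 14, the threshold used with 212 animal
#' samples), dropping their member peaks alongside.
#'
#' @param x An `rt_ranges` object.
#' @param min_occurrence Minimum number of distinct contributing samples.
#' @return The filtered `rt_ranges` object; retained/discarded counts are
#'   appended to its log.
#' @export
filter_by_occurrence <- function(x, min_occurrence = 14) {
  stopifnot(inherits(x, "rt_ranges"))
  if (min_occurrence < 1) abort("`min_occurrence` must be >= 1.")
  keep <- x$ranges$occurrence >= min_occurrence
  x$log <- bind_rows(x$log, tibble(
    event = "occurrence_filter",
    detail = sprintf(
      "retained %d of %d ranges (min occurrence %d)",
      sum(keep), length(keep), min_occurrence
    )
  ))
  x$ranges <- x$ranges[keep, ]
  x$peaks <- x$peaks |> filter(.data$range_id %in% x$ranges$range_id)
  x
}

# Mean pairwise Jaccard similarity of the members' top-k fragment sets,
# computed over unique sets with multiplicities (identical sets contribute
# similarity 1).
mean_pairwise_jaccard <- function(sets) {
  n <- length(sets)
  if (n < 2) {
    return(1)
  }
  keys <- map_chr(sets, function(s) paste(sort(s), collapse = ","))
  tab <- table(keys)
  uniq <- map(names(tab), function(k) as.integer(strsplit(k, ",")[[1]]))
  cnt <- as.integer(tab)
  total <- 0
  m <- length(uniq)
  for (i in seq_len(m)) {
    total <- total + choose(cnt[i], 2) # identical pairs, J = 1
    if (i < m) {
      for (j in seq((i + 1), m)) {
        inter <- length(intersect(uniq[[i]], uniq[[j]]))
        uni <- length(union(uniq[[i]], uniq[[j]]))
        total <- total + cnt[i] * cnt[j] * inter / uni
      }
    }
  }
  total / choose(n, 2)
}

#' Extract prominent masses and verify spectral consistency
#'
#' For every range, the `top_k` fragment m/z values by total intensity across
#' member peaks become the range's prominent masses (the substance-specific
#' m/z used for quantification). Consistency of the spectral pattern is
#' verified automatically: the mean pairwise Jaccard similarity of the
#' members' individual top-`top_k` fragment sets must reach `jaccard_min`
#' (an automated surrogate for manual inspection of the mass spectra);
#' single-member ranges are verified by convention.
#'
#' @param x An `rt_ranges` object.
#' @param top_k Number of prominent fragment ions to extract.
#' @param jaccard_min Minimum mean pairwise Jaccard similarity.
#' @return The `rt_ranges` object with `prominent_mz` (list-column),
#'   `mean_jaccard` and `verified` added to its `ranges` tibble.
#' @export
extract_and_verify_masses <- function(x, top_k = 5, jaccard_min = 0.5) {
  stopifnot(inherits(x, "rt_ranges"))
  if (top_k < 1) abort("`top_k` must be >= 1.")
  if (jaccard_min < 0 || jaccard_min > 1) {
    abort("`jaccard_min` must be in [0, 1].")
  }
  by_range <- split(x$peaks$spectrum, x$peaks$range_id)
  stats <- map(x$ranges$range_id, function(rid) {
    spectra <- by_range[[rid]]
    pooled <- unlist(spectra)
    totals <- tapply(pooled, names(pooled), sum)
    prominent <- as.integer(names(totals))[
      order(-as.vector(totals), as.integer(names(totals)))
    ][seq_len(min(top_k, length(totals)))]
    member_sets <- map(spectra, top_mz, k = top_k)
    list(
      prominent_mz = sort(prominent),
      mean_jaccard = mean_pairwise_jaccard(member_sets)
    )
  })
  x$ranges$prominent_mz <- map(stats, "prominent_mz")
  x$ranges$mean_jaccard <- map_dbl(stats, "mean_jaccard")
  x$ranges$verified <- x$ranges$mean_jaccard >= jaccard_min
  x$log <- bind_rows(x$log, tibble(
    event = "mass_verification",
    detail = sprintf(
      "%d of %d ranges verified (top_k %d, Jaccard >= %.2f)",
      sum(x$ranges$verified), nrow(x$ranges), top_k, jaccard_min
    )
  ))
  x
}

#' Quantify ranges into a samples-by-substances area table
#'
#' Builds the aligned area matrix: each cell is the member peak's summed
#' intensity over the range's prominent m/z (falling back to the peak's total
#' area when its spectrum shares none of them); samples without a peak in a
#' range get 0, because the downstream relative-area denominator is the sum
#' over all included peak areas. Unverified ranges are dropped.
#'
#' @param peaks The full peak tibble (defines the sample set, including
#'   samples that contributed no retained peak).
#' @param x An `rt_ranges` object with prominent masses extracted.
#' @return An object of class `aligned_table`: a list with the wide `areas`
#'   tibble (`sample_id` + one column per range) and the `ranges` metadata
#'   tibble.
#' @export
quantify_ranges <- function(peaks, x) {
  stopifnot(inherits(x, "rt_ranges"))
  if (is.null(x$ranges$prominent_mz)) {
    abort("Run `extract_and_verify_masses()` before quantifying.")
  }
  dropped <- sum(!x$ranges$verified)
  if (dropped > 0) {
    warn(sprintf("Dropping %d unverified range(s).", dropped))
  }
  ranges <- x$ranges |> filter(.data$verified)
  samples <- sort(unique(peaks$sample_id))
  mat <- matrix(0,
    nrow = length(samples), ncol = nrow(ranges),
    dimnames = list(samples, ranges$range_id)
  )
  members <- x$peaks |> filter(.data$range_id %in% ranges$range_id)
  prominent <- setNames(ranges$prominent_mz, ranges$range_id)
  vals <- pmap(
    list(members$spectrum, members$range_id),
    function(sp, rid) {
      hit <- names(sp) %in% as.character(prominent[[rid]])
      if (any(hit)) sum(sp[hit]) else sum(sp)
    }
  )
  mat[cbind(members$sample_id, members$range_id)] <- unlist(vals)
  structure(
    list(
      areas = matrix_to_wide(mat),
      ranges = ranges,
      provenance = tibble(
        step = "quantify",
        detail = sprintf(
          "%d ranges quantified over %d samples (%d unverified dropped)",
          nrow(ranges), length(samples), dropped
        )
      )
    ),
    class = "aligned_table"
  )
}

#' @export
print.aligned_table <- function(x, ...) {
  cat(sprintf(
    "<aligned_table> %d samples x %d ranges\n",
    nrow(x$areas), nrow(x$ranges)
  ))
  print(x$areas, ...)
  invisible(x)
}

#' Align peak lists end to end
#'
#' Convenience wrapper running batch RT adjustment (optional), gap grouping,
#' occurrence filtering, prominent-mass extraction and quantification.
#'
#' @param peaks A peak tibble.
#' @param batch_map Optional (`sample_id`, `batch`) mapping; when supplied,
#'   retention times are adjusted per batch first.
#' @param gap_tol,min_occurrence,top_k,jaccard_min Stage parameters.
#' @return An `aligned_table`.
#' @export
align_peaks <- function(peaks, batch_map = NULL, gap_tol = 0.05,
                        min_occurrence = 14, top_k = 5, jaccard_min = 0.5) {
  if (!is.null(batch_map)) {
    peaks <- adjust_rt_per_batch(peaks, batch_map, gap_tol = gap_tol)
  }
  grouped <- peaks |>
    group_retention_times(gap_tol = gap_tol) |>
    filter_by_occurrence(min_occurrence = min_occurrence) |>
    extract_and_verify_masses(top_k = top_k, jaccard_min = jaccard_min)
  quantify_ranges(peaks, grouped)
}
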