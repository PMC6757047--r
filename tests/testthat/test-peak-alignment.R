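test_that("gap rule splits pooled peaks into ranges", {
  peaks <- make_peaks(c("s1", "s2", "s1"), rt = c(1.00, 1.01, 5.00))
  g <- group_retention_times(peaks, gap_tol = 0.05)
  expect_equal(nrow(g$ranges), 2)
  expect_equal(g$ranges$occurrence, c(2, 1))
  expect_equal(nrow(g$peaks), 3)
  # empty input
  empty <- group_retention_times(make_peaks(character(), double()))
  expect_equal(nrow(empty$ranges), 0)
})

test_that("one peak per sample per range: nearest to median wins, ties by area", {
  peaks <- make_peaks(
    c("s1", "s1", "s2"),
    rt = c(1.00, 1.02, 1.01), area = c(5, 10, 1)
  )
  g <- group_retention_times(peaks, gap_tol = 0.05)
  expect_equal(nrow(g$ranges), 1)
  # median RT is 1.01: s1's peaks are equidistant, larger area (rt 1.02) kept
  s1 <- dplyr::filter(g$peaks, sample_id == "s1")
  expect_equal(nrow(s1), 1)
  expect_equal(s1$rt, 1.02)
  expect_match(g$log$detail[1], "1 peaks")
  # clear proximity case: nearer peak kept regardless of area
  peaks2 <- make_peaks(
    c("s1", "s1", "s2", "s3"),
    rt = c(1.00, 1.03, 1.00, 1.00), area = c(1, 100, 1, 1)
  )
  g2 <- group_retention_times(peaks2, gap_tol = 0.05)
  expect_equal(dplyr::filter(g2$peaks, sample_id == "s1")$rt, 1.00)
})

test_that("grouping recovers the planted substance count under small jitter", {
  spec <- effect_spec(
    n_substances = 25, n_contaminants = 0, n_cycle = 0, n_age = 0,
    n_parity = 0, seed = 21
  )
  st <- simulate_study(small_config(), spec,
    jitter_sd = 0.005,
    dropout_rate = 0.02, seed = 21
  )
  g <- group_retention_times(st$peaks, gap_tol = 0.05)
  expect_equal(nrow(g$ranges), 25)
})

test_that("grouping is order-invariant and monotone in gap_tol", {
  set.seed(22)
  peaks <- make_peaks(
    sample(sprintf("s%d", 1:6), 40, replace = TRUE),
    rt = runif(40, 0, 10), area = runif(40)
  )
  g1 <- group_retention_times(peaks, gap_tol = 0.3)
  g2 <- group_retention_times(peaks[sample.int(40), ], gap_tol = 0.3)
  expect_equal(g1$ranges, g2$ranges)

  tols <- c(0.01, 0.05, 0.1, 0.3, 1, 5)
  counts <- vapply(
    tols,
    function(tt) nrow(group_retention_times(peaks, tt)$ranges),
    integer(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("gap grouping matches single-linkage clustering on small inputs", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(10:30, 1)
    peaks <- make_peaks(
      sprintf("s%d", seq_len(n)),
      rt = round(runif(n, 0, 3), 3)
    )
    gap <- 0.12
    g <- group_retention_times(peaks, gap_tol = gap)
    got <- g$peaks |>
      dplyr::arrange(rt) |>
      dplyr::pull(range_id)
    hc <- stats::hclust(stats::dist(sort(peaks$rt)), method = "single")
    want <- stats::cutree(hc, h = gap)
    # same partition up to relabelling
    expect_equal(
      as.integer(factor(got, levels = unique(got))),
      as.integer(factor(want, levels = unique(want)))
    )
  }
})

test_that("every retained peak belongs to exactly one range", {
  spec <- small_spec(seed = 23)
  st <- simulate_study(small_config(), spec, seed = 23)
  g <- group_retention_times(st$peaks, gap_tol = 0.05)
  expect_equal(anyDuplicated(
    g$peaks[, c("sample_id", "range_id")]
  ), 0)
  expect_true(all(g$peaks$range_id %in% g$ranges$range_id))
})

test_that("occurrence filter keeps exactly the ranges at or above threshold", {
  # three clusters occurring in 13, 14 and 20 distinct samples
  occ <- c(13, 14, 20)
  peaks <- dplyr::bind_rows(purrr::map2(
    c(1, 5, 9), occ,
    function(rt, k) make_peaks(sprintf("s%02d", seq_len(k)), rep(rt, k))
  ))
  g <- group_retention_times(peaks, gap_tol = 0.05)
  expect_equal(sort(g$ranges$occurrence), occ)
  expect_equal(nrow(filter_by_occurrence(g, 14)$ranges), 2)
  expect_equal(nrow(filter_by_occurrence(g, 1)$ranges), 3)
  expect_equal(nrow(filter_by_occurrence(g, 21)$ranges), 0)
  expect_error(filter_by_occurrence(g, 0), ">= 1")
})

test_that("prominent-mass extraction and consistency verification", {
  sp <- stats::setNames(c(10, 5, 3, 2, 1), c(57, 71, 85, 99, 113))
  same <- make_peaks(c("s1", "s2", "s3"), c(1, 1.01, 1.02),
    spectrum = list(sp, sp, sp)
  )
  g <- extract_and_verify_masses(group_retention_times(same))
  expect_equal(g$ranges$mean_jaccard, 1)
  expect_true(g$ranges$verified)
  expect_equal(sort(g$ranges$prominent_mz[[1]]), c(57, 71, 85, 99, 113))

  other <- stats::setNames(c(10, 5, 3, 2, 1), c(30, 31, 32, 33, 34))
  mixed <- make_peaks(c("s1", "s2"), c(1, 1.01), spectrum = list(sp, other))
  g2 <- extract_and_verify_masses(group_retention_times(mixed))
  expect_equal(g2$ranges$mean_jaccard, 0)
  expect_false(g2$ranges$verified)

  # single member verified by convention
  single <- make_peaks("s1", 1, spectrum = list(sp))
  g3 <- extract_and_verify_masses(group_retention_times(single))
  expect_true(g3$ranges$verified)
})

test_that("planted inconsistent substances fail verification exactly", {
  spec <- effect_spec(
    n_substances = 20, n_contaminants = 0, n_inconsistent = 4,
    n_cycle = 0, n_age = 0, n_parity = 0, seed = 24
  )
  st <- simulate_study(small_config(), spec, seed = 24)
  g <- st$peaks |>
    group_retention_times(gap_tol = 0.05) |>
    extract_and_verify_masses()
  expect_equal(sum(!g$ranges$verified), 4)
  bad <- match_ranges(g, spec) |>
    dplyr::filter(range_id %in% g$ranges$range_id[!g$ranges$verified])
  expect_setequal(
    bad$substance,
    spec$substances$substance[spec$substances$inconsistent]
  )
})

test_that("quantification sums prominent-m/z intensities with zero fill", {
  spA <- stats::setNames(c(8, 2), c(57, 71))
  spB <- stats::setNames(c(6, 4), c(57, 71))
  spC <- stats::setNames(5, "200")
  peaks <- make_peaks(
    c("s1", "s2", "s1"), c(1, 1.01, 5),
    area = c(10, 10, 5), spectrum = list(spA, spB, spC)
  )
  g <- peaks |>
    group_retention_times() |>
    extract_and_verify_masses(top_k = 2)
  at <- quantify_ranges(peaks, g)
  m <- semioprofile:::wide_to_matrix(at$areas)
  expect_equal(m["s1", 1], 10) # 8 + 2
  expect_equal(m["s2", 1], 10)
  expect_equal(m["s2", 2], 0) # absent peak
  expect_equal(m["s1", 2], 5) # single-m/z spectrum
})

test_that("zero-noise round trip recovers the latent area matrix", {
  spec <- small_spec(seed = 25)
  st <- simulate_study(small_config(), spec,
    jitter_sd = 0, dropout_rate = 0,
    seed = 25
  )
  at <- align_peaks(st$peaks, min_occurrence = 1)
  mapping <- match_ranges(at, spec)
  expect_false(anyNA(mapping$substance))
  m <- semioprofile:::wide_to_matrix(at$areas)
  colnames(m) <- mapping$substance[match(colnames(m), mapping$range_id)]
  latent <- st$truth$areas |>
    tidyr::pivot_wider(names_from = "substance", values_from = "area")
  lm_ <- semioprofile:::wide_to_matrix(latent)
  expect_equal(
    m[rownames(lm_), colnames(lm_)], lm_,
    tolerance = 1e-9
  )
})

test_that("batch RT adjustment recovers a planted shift", {
  spec <- small_spec(seed = 26)
  design <- generate_design(small_config(), seed = 26)
  truth <- simulate_intensities(design, spec, seed = 26)
  target <- unique(design$batch[!design$is_blank])[2]
  peaks <- render_peak_lists(truth,
    jitter_sd = 0.003, dropout_rate = 0,
    batch_shifts = stats::setNames(0.10, target), seed = 26
  )
  batch_map <- design[, c("sample_id", "batch")]
  adj <- adjust_rt_per_batch(peaks, batch_map, gap_tol = 0.05)
  shifts <- attr(adj, "rt_shifts")
  expect_equal(
    shifts$shift[shifts$batch == target], -0.10,
    tolerance = 0.01
  )
  others <- shifts$shift[shifts$batch != target]
  expect_true(all(abs(others) < 0.01))
})

test_that("aligned batches and single batches are left untouched", {
  spec <- small_spec(seed = 27)
  st <- simulate_study(small_config(), spec, jitter_sd = 0, seed = 27)
  batch_map <- st$design[, c("sample_id", "batch")]
  adj <- adjust_rt_per_batch(st$peaks, batch_map)
  expect_true(all(abs(attr(adj, "rt_shifts")$shift) < 1e-9))

  one_batch <- dplyr::mutate(batch_map, batch = "b1")
  adj1 <- adjust_rt_per_batch(st$peaks, one_batch)
  expect_equal(adj1$rt, st$peaks$rt)
  expect_equal(attr(adj1, "rt_shifts")$shift, 0)
})
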