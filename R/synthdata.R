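#' Configure a synthetic scent-sampling study design
#'
#' Describes the sampling layout of a longitudinal scent-collection study on
#' female marmosets: how many females, their age pool and parity mix, how many
#' ovarian cycles are followed in total, the number of animal samples required
#' per cycle state, and how many blank control tubes are measured. The
#' defaults reproduce the layout of the study this package models: 12 females
#' sampled over 27 cycles, 56 follicular + 104 peri-ovulatory + 52 luteal
#' samples, and 31 blanks (9 handling blanks, 22 room-air blanks).
#'
#' @param n_females Number of study females.
#' @param age_pool Ages (years) from which female ages are drawn; the default
#'   is the observed set of discrete ages, 1 to 11 years.
#' @param parity_fraction Fraction of females that are parous; parity is
#'   assigned independently of age so the two remain separately estimable.
#' @param n_rooms Number of housing rooms.
#' @param state_quota Named integer vector of animal-sample counts per cycle
#'   state (`follicular`, `peri-ovulatory`, `luteal`).
#' @param n_cycles Total number of sampled cycles across all females; each
#'   (female, cycle) pair is one sampling batch.
#' @param n_handling_blanks,n_air_blanks Blank tube counts by type.
#' @return A list of class `design_config`.
#' @export
design_config <- function(n_females = 12,
                          age_pool = c(1, 4, 5, 7, 8, 9, 10, 11),
                          parity_fraction = 0.5,
                          n_rooms = 3,
                          state_quota = c(
                            "follicular" = 56,
                            "peri-ovulatory" = 104,
                            "luteal" = 52
                          ),
                          n_cycles = 27,
                          n_handling_blanks = 9,
                          n_air_blanks = 22) {
  states <- c("follicular", "peri-ovulatory", "luteal")
  if (!setequal(names(state_quota), states)) {
    abort("`state_quota` must be named with the three cycle states.")
  }
  cfg <- list(
    n_females = as.integer(n_females),
    age_pool = age_pool,
    parity_fraction = parity_fraction,
    n_rooms = as.integer(n_rooms),
    state_quota = state_quota[states],
    n_cycles = as.integer(n_cycles),
    n_handling_blanks = as.integer(n_handling_blanks),
    n_air_blanks = as.integer(n_air_blanks)
  )
  structure(cfg, class = "design_config")
}

cycle_states <- function() c("follicular", "peri-ovulatory", "luteal")

# Spread `total` units over `n` slots as evenly as possible, assigning the
# remainder to randomly chosen slots (seeded by the caller).
spread_counts <- function(total, n) {
  base <- total %/% n
  counts <- rep(base, n)
  extra <- total - base * n
  if (extra > 0) {
    counts[sample.int(n, extra)] <- base + 1L
  }
  counts
}

#' Generate a study design table
#'
#' Builds the full sample-metadata table for a synthetic study: one row per
#' animal sample or blank, with female attributes (age, parity, room), cycle
#' state, sampling batch (the female x cycle combination), genital side,
#' ultrasound timing, and which one of four handling assistants was present.
#' Blanks carry no female attributes and sit in their own measurement batch.
#'
#' @param config A [design_config()].
#' @param seed Integer master seed; the same `(config, seed)` pair always
#'   yields an identical design.
#' @return A tibble of class `study_design` with one row per sample.
#' @examples
#' design <- generate_design(design_config(), seed = 1)
#' sum(!design$is_blank) # 212 animal samples
#' @export
generate_design <- function(config = design_config(), seed = 1) {
  stopifnot(inherits(config, "design_config"))
  quota <- config$state_quota
  n_animal <- sum(quota)
  if (n_animal > 0 && config$n_females < 1) {
    abort("Animal-sample quotas require at least one female.")
  }
  if (n_animal > 0 && config$n_cycles < config$n_females) {
    abort(sprintf(
      "Infeasible design: %d cycles cannot cover %d females (each female needs at least one cycle).",
      config$n_cycles, config$n_females
    ))
  }
  set_stream(seed, "design")

  females <- tibble(
    female_id = sprintf("F%02d", seq_len(config$n_females)),
    age = sample(config$age_pool, config$n_females, replace = TRUE),
    parity = sample(c(
      rep("parous", round(config$parity_fraction * config$n_females)),
      rep("nulliparous", config$n_females -
        round(config$parity_fraction * config$n_females))
    )),
    room = sample(rep_len(
      sprintf("room%d", seq_len(config$n_rooms)),
      config$n_females
    ))
  )

  animal <- NULL
  if (n_animal > 0) {
    cycles_per_female <- spread_counts(config$n_cycles, config$n_females)
    batches <- tibble(
      female_id = rep(females$female_id, cycles_per_female),
      cycle_idx = unlist(map(cycles_per_female, seq_len), use.names = FALSE)
    ) |>
      mutate(batch = sprintf("%s.c%d", .data$female_id, .data$cycle_idx))

    per_state <- map(cycle_states(), function(st) {
      counts <- spread_counts(quota[[st]], nrow(batches))
      batches[rep(seq_len(nrow(batches)), counts), ] |>
        mutate(cycle_state = st)
    })
    animal <- bind_rows(per_state) |>
      left_join(females, by = "female_id") |>
      mutate(
        is_blank = FALSE,
        blank_type = NA_character_
      )
    # Randomise per-sample nuisance covariates; exactly one assistant is
    # present for each sampling event.
    n <- nrow(animal)
    assistant <- sample.int(4, n, replace = TRUE)
    animal <- animal |>
      mutate(
        side = sample(c("left", "right"), n, replace = TRUE),
        ultrasound = sample(c("before", "after"), n, replace = TRUE),
        a1 = ifelse(assistant == 1, "yes", "no"),
        a2 = ifelse(assistant == 2, "yes", "no"),
        a3 = ifelse(assistant == 3, "yes", "no"),
        a4 = ifelse(assistant == 4, "yes", "no")
      ) |>
      arrange(.data$female_id, .data$cycle_idx, .data$cycle_state)
    animal$sample_id <- sprintf("S%03d", seq_len(n))
  }

  n_blank <- config$n_handling_blanks + config$n_air_blanks
  blanks <- NULL
  if (n_blank > 0) {
    blanks <- tibble(
      sample_id = sprintf("BL%02d", seq_len(n_blank)),
      female_id = NA_character_,
      age = NA_real_,
      parity = NA_character_,
      room = NA_character_,
      cycle_state = NA_character_,
      cycle_idx = NA_integer_,
      batch = "blank",
      side = NA_character_,
      ultrasound = NA_character_,
      a1 = NA_character_, a2 = NA_character_,
      a3 = NA_character_, a4 = NA_character_,
      is_blank = TRUE,
      blank_type = rep(
        c("handling", "room_air"),
        c(config$n_handling_blanks, config$n_air_blanks)
      )
    )
  }

  design <- bind_rows(animal, blanks) |>
    select(
      "sample_id", "female_id", "age", "parity", "room",
      "cycle_state", "cycle_idx", "batch", "side", "ultrasound",
      "a1", "a2", "a3", "a4", "is_blank", "blank_type"
    )
  attr(design, "config") <- config
  class(design) <- c("study_design", class(design))
  design
}

#' Specify per-substance generative effects
#'
#' Defines the latent chemistry of a synthetic study: every substance gets a
#' retention time, a characteristic fragment (m/z) pattern and a baseline
#' log-area; a configured number of substances carry cycle-state, age or
#' parity effects (disjoint sets, so ground truth is unambiguous); all
#' substances carry small nuisance effects of genital side, ultrasound timing
#' and assistant identity; contaminant substances originate from the sampling
#' material and appear at full intensity in blanks. Default planted counts
#' (6 cycle-, 11 age-, 7 parity-affected of 160 substances) mirror the scale
#' of effects reported for real marmoset profiles; effect magnitudes and the
#' log-normal intensity model are tooling choices, documented in the vignette.
#'
#' @param n_substances Number of true (animal-derived) substances.
#' @param n_contaminants Number of contaminant substances.
#' @param n_inconsistent Number of true substances rendered with an unstable
#'   fragment pattern (fails the spectral consistency check downstream).
#' @param n_cycle,n_age,n_parity Planted counts of affected substances.
#' @param cycle_effect Log-area bump of the elevated cycle state (the three
#'   state effects are centred to mean zero per substance).
#' @param age_effect Absolute log-area slope per z-scored year for
#'   age-affected substances.
#' @param parity_effect Absolute log-area shift of parous females for
#'   parity-affected substances.
#' @param prop_age_negative,prop_parity_negative Fraction of affected
#'   substances whose intensity decreases with age / in parous females.
#' @param baseline_mean,baseline_sd Distribution of baseline log-areas.
#' @param sigma_id,sigma_batch,sigma_e Female-level, batch-level and residual
#'   SDs on the log scale (all must be nonnegative).
#' @param nuisance_sd SD of per-substance side/ultrasound/assistant effects.
#' @param carryover Fraction of a substance's baseline intensity that leaks
#'   into blank tubes (trace carryover).
#' @param contaminant_animal_fraction Intensity of contaminants in animal
#'   samples relative to blanks (< 1: blanks see the background undiluted).
#' @param rt_min,rt_max Retention-time window (minutes) over which substances
#'   are laid out on a jittered grid, guaranteeing chromatographic spacing.
#' @param n_fragments Fragment ions per substance.
#' @param mz_range Scan range of fragment m/z values.
#' @param seed Seed for the substance-level draws.
#' @return A list of class `effect_spec` with a `substances` tibble and the
#'   scalar parameters.
#' @export
effect_spec <- function(n_substances = 160,
                        n_contaminants = 10,
                        n_inconsistent = 0,
                        n_cycle = 6,
                        n_age = 11,
                        n_parity = 7,
                        cycle_effect = 1.6,
                        age_effect = 1.2,
                        parity_effect = 1.2,
                        prop_age_negative = 8 / 11,
                        prop_parity_negative = 5 / 7,
                        baseline_mean = log(1e6),
                        baseline_sd = 1.5,
                        sigma_id = 0.4,
                        sigma_batch = 0.25,
                        sigma_e = 0.4,
                        nuisance_sd = 0.05,
                        carryover = 0.01,
                        contaminant_animal_fraction = 0.5,
                        rt_min = 2,
                        rt_max = 48,
                        n_fragments = 5,
                        mz_range = c(30, 300),
                        seed = 1) {
  if (any(c(sigma_id, sigma_batch, sigma_e, nuisance_sd) < 0)) {
    abort("Random-effect and residual SDs must be nonnegative.")
  }
  if (n_cycle + n_age + n_parity > n_substances) {
    abort("Planted effect sets exceed the number of true substances.")
  }
  if (n_inconsistent > n_substances) {
    abort("`n_inconsistent` exceeds the number of true substances.")
  }
  set_stream(seed, "effect_spec")

  n_total <- n_substances + n_contaminants
  # Jittered RT grid: spacing floor of half the grid step keeps neighbouring
  # substances resolvable by gap clustering at the default tolerance.
  step <- (rt_max - rt_min) / n_total
  rt <- sort(rt_min + (seq_len(n_total) - 0.5) * step +
    runif(n_total, -0.25 * step, 0.25 * step))

  substances <- tibble(
    substance = sprintf("sub%03d", seq_len(n_total)),
    rt = rt,
    baseline = rnorm(n_total, baseline_mean, baseline_sd),
    is_contaminant = seq_len(n_total) %in%
      sample.int(n_total, n_contaminants)
  )
  substances$mz <- map(seq_len(n_total), function(i) {
    mz <- sort(sample(seq(mz_range[1], mz_range[2]), n_fragments))
    w <- sort(runif(n_fragments), decreasing = TRUE)
    setNames(w / sum(w), mz)
  })

  true_idx <- which(!substances$is_contaminant)
  planted <- sample(true_idx, n_cycle + n_age + n_parity)
  cyc_idx <- planted[seq_len(n_cycle)]
  age_idx <- planted[n_cycle + seq_len(n_age)]
  par_idx <- planted[n_cycle + n_age + seq_len(n_parity)]

  substances$c_follicular <- substances$c_periovulatory <-
    substances$c_luteal <- rep(0, n_total)
  if (n_cycle > 0) {
    high <- sample(cycle_states(), n_cycle, replace = TRUE)
    for (j in seq_len(n_cycle)) {
      e <- c(
        "follicular" = 0, "peri-ovulatory" = 0, "luteal" = 0
      )
      e[high[j]] <- cycle_effect
      e <- e - mean(e)
      substances$c_follicular[cyc_idx[j]] <- e[["follicular"]]
      substances$c_periovulatory[cyc_idx[j]] <- e[["peri-ovulatory"]]
      substances$c_luteal[cyc_idx[j]] <- e[["luteal"]]
    }
  }

  substances$age_slope <- rep(0, n_total)
  if (n_age > 0) {
    n_neg <- round(prop_age_negative * n_age)
    signs <- sample(c(rep(-1, n_neg), rep(1, n_age - n_neg)))
    substances$age_slope[age_idx] <- signs * age_effect
  }

  substances$parity_shift <- rep(0, n_total)
  if (n_parity > 0) {
    n_neg <- round(prop_parity_negative * n_parity)
    signs <- sample(c(rep(-1, n_neg), rep(1, n_parity - n_neg)))
    substances$parity_shift[par_idx] <- signs * parity_effect
  }

  for (col in c("side_eff", "us_eff", "a1_eff", "a2_eff", "a3_eff", "a4_eff")) {
    substances[[col]] <- ifelse(
      substances$is_contaminant, 0, rnorm(n_total, 0, nuisance_sd)
    )
  }

  substances$inconsistent <- FALSE
  if (n_inconsistent > 0) {
    substances$inconsistent[sample(true_idx, n_inconsistent)] <- TRUE
  }

  structure(
    list(
      substances = substances,
      cycle_substances = substances$substance[cyc_idx],
      age_substances = substances$substance[age_idx],
      parity_substances = substances$substance[par_idx],
      sigma_id = sigma_id,
      sigma_batch = sigma_batch,
      sigma_e = sigma_e,
      carryover = carryover,
      contaminant_animal_fraction = contaminant_animal_fraction,
      n_fragments = n_fragments,
      mz_range = mz_range
    ),
    class = "effect_spec"
  )
}

#' Simulate latent substance intensities
#'
#' Draws the latent area matrix of a synthetic study under a log-normal
#' intensity model: for animal samples the log-area of substance `s` is its
#' baseline plus cycle-state, age (per z-scored year), parity and nuisance
#' effects, a female-level and a batch-level random intercept, and residual
#' noise. Blanks receive contaminants at full intensity and true substances
#' only at the configured trace-carryover fraction; contaminants appear in
#' animal samples attenuated by `contaminant_animal_fraction`.
#'
#' @param design A [generate_design()] table.
#' @param spec An [effect_spec()].
#' @param seed Integer master seed.
#' @return A list of class `synthetic_truth` holding the long `areas` tibble
#'   (`sample_id`, `substance`, `area`), the design, the spec, the planted
#'   substance sets and all random-effect draws.
#' @export
simulate_intensities <- function(design, spec, seed = 1) {
  stopifnot(inherits(design, "study_design"), inherits(spec, "effect_spec"))
  set_stream(seed, "intensities")
  sub <- spec$substances
  n_sub <- nrow(sub)
  n_smp <- nrow(design)

  females <- design |>
    filter(!.data$is_blank) |>
    distinct(.data$female_id, .data$age)
  if (nrow(females) > 1 && sd(females$age) > 0) {
    z_age <- (females$age - mean(females$age)) / sd(females$age)
  } else {
    z_age <- rep(0, nrow(females))
  }
  names(z_age) <- females$female_id

  u_id <- setNames(rnorm(nrow(females), 0, spec$sigma_id), females$female_id)
  batches <- setdiff(unique(design$batch), "blank")
  u_batch <- setNames(rnorm(length(batches), 0, spec$sigma_batch), batches)

  state_eff <- rbind(
    "follicular" = sub$c_follicular,
    "peri-ovulatory" = sub$c_periovulatory,
    "luteal" = sub$c_luteal
  )

  log_area <- matrix(rep(sub$baseline, each = n_smp), nrow = n_smp)
  eps <- matrix(rnorm(n_smp * n_sub, 0, spec$sigma_e), nrow = n_smp)

  is_blank <- design$is_blank
  is_cont <- sub$is_contaminant
  if (any(!is_blank)) {
    ai <- which(!is_blank)
    d <- design[ai, ]
    fx <- state_eff[d$cycle_state, , drop = FALSE] +
      outer(z_age[d$female_id], sub$age_slope) +
      outer(as.numeric(d$parity == "parous"), sub$parity_shift) +
      outer(as.numeric(d$side == "right"), sub$side_eff) +
      outer(as.numeric(d$ultrasound == "after"), sub$us_eff) +
      outer(as.numeric(d$a1 == "yes"), sub$a1_eff) +
      outer(as.numeric(d$a2 == "yes"), sub$a2_eff) +
      outer(as.numeric(d$a3 == "yes"), sub$a3_eff) +
      outer(as.numeric(d$a4 == "yes"), sub$a4_eff) +
      u_id[d$female_id] + u_batch[d$batch]
    # Contaminants are environmental: no biological or handling effects.
    fx[, is_cont] <- log(spec$contaminant_animal_fraction)
    log_area[ai, ] <- log_area[ai, , drop = FALSE] + fx
  }
  if (any(is_blank)) {
    bi <- which(is_blank)
    blank_fx <- matrix(log(spec$carryover), nrow = length(bi), ncol = n_sub)
    blank_fx[, is_cont] <- 0
    log_area[bi, ] <- log_area[bi, , drop = FALSE] + blank_fx
  }
  log_area <- log_area + eps

  areas <- tibble(
    sample_id = rep(design$sample_id, times = n_sub),
    substance = rep(sub$substance, each = n_smp),
    area = exp(as.vector(log_area))
  ) |>
    arrange(.data$sample_id, .data$substance)

  structure(
    list(
      areas = areas,
      design = design,
      spec = spec,
      z_age = z_age,
      u_id = u_id,
      u_batch = u_batch,
      cycle_substances = spec$cycle_substances,
      age_substances = spec$age_substances,
      parity_substances = spec$parity_substances,
      contaminant_substances = sub$substance[is_cont]
    ),
    class = "synthetic_truth"
  )
}

#' Render per-sample peak lists from latent intensities
#'
#' Emulates the output of spectral deconvolution: every latent substance area
#' becomes one peak at its true retention time plus Gaussian jitter, carrying
#' the substance's fragment pattern scaled to the peak area. Peaks are dropped
#' independently with `dropout_rate`, optional per-batch retention-time shifts
#' emulate drift between measurement batches, and substances flagged as
#' `inconsistent` get a freshly drawn fragment set for every peak.
#'
#' @param truth A [simulate_intensities()] result.
#' @param jitter_sd Retention-time jitter SD in minutes (>= 0).
#' @param dropout_rate Probability that a peak is missed (0 <= rate < 1).
#' @param batch_shifts Optional named numeric vector of RT shifts (minutes)
#'   per batch, added to all peaks of that batch's samples.
#' @param seed Integer master seed.
#' @return A tibble of peaks (`sample_id`, `rt`, `area`, `spectrum`), ordered
#'   by ascending retention time within each sample, with the dropped
#'   (sample, substance) pairs recorded in the `"dropped"` attribute.
#' @export
render_peak_lists <- function(truth, jitter_sd = 0.005, dropout_rate = 0.02,
                              batch_shifts = NULL, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (jitter_sd < 0) abort("`jitter_sd` must be nonnegative.")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must be in [0, 1).")
  }
  set_stream(seed, "render")
  sub <- truth$spec$substances
  peaks <- truth$areas |>
    left_join(
      sub |> select("substance", "rt", "mz", "inconsistent"),
      by = "substance"
    ) |>
    left_join(
      truth$design |> select("sample_id", "batch"),
      by = "sample_id"
    )

  n <- nrow(peaks)
  shift <- rep(0, n)
  if (!is.null(batch_shifts)) {
    hit <- peaks$batch %in% names(batch_shifts)
    shift[hit] <- batch_shifts[peaks$batch[hit]]
  }
  peaks$rt <- peaks$rt + rnorm(n, 0, jitter_sd) + shift

  keep <- runif(n) >= dropout_rate
  dropped <- peaks[!keep, c("sample_id", "substance")]
  peaks <- peaks[keep, ]

  if (any(peaks$inconsistent)) {
    idx <- which(peaks$inconsistent)
    nf <- truth$spec$n_fragments
    rng <- truth$spec$mz_range
    peaks$mz[idx] <- map(idx, function(i) {
      mz <- sort(sample(seq(rng[1], rng[2]), nf))
      w <- sort(runif(nf), decreasing = TRUE)
      setNames(w / sum(w), mz)
    })
  }

  peaks$spectrum <- map2(peaks$mz, peaks$area, function(p, a) p * a)
  out <- peaks |>
    select("sample_id", "substance", "rt", "area", "spectrum") |>
    arrange(.data$sample_id, .data$rt)
  attr(out, "dropped") <- dropped
  out
}

#' Export the known-contaminant list of a synthetic study
#'
#' Produces the contaminant reference table consumed by
#' [remove_contaminants()]: one row per known contaminant with a retention
#' time window and its characteristic m/z values. Restricting `which` to a
#' subset emulates an incomplete contaminant library, leaving the remainder
#' for the blank filter to catch.
#'
#' @param spec An [effect_spec()].
#' @param window Half-width of the RT window in minutes.
#' @param which Indices of contaminants to include (default all).
#' @return A tibble with `rt_low`, `rt_high` and an `mz` list-column.
#' @export
contaminant_list <- function(spec, window = 0.05, which = NULL) {
  stopifnot(inherits(spec, "effect_spec"))
  cont <- spec$substances |> filter(.data$is_contaminant)
  if (!is.null(which)) cont <- cont[which, ]
  tibble(
    substance = cont$substance,
    rt_low = cont$rt - window,
    rt_high = cont$rt + window,
    mz = map(cont$mz, function(m) as.integer(names(m)))
  )
}

#' View latent intensities as an aligned table
#'
#' Bypasses peak rendering and alignment: exposes the latent area matrix of
#' a [simulate_intensities()] result in the `aligned_table` form consumed by
#' the preprocessing stage, with one pseudo-range per substance. Useful for
#' testing the statistical stages against ground truth without
#' chromatographic noise.
#'
#' @param truth A `synthetic_truth`.
#' @return An `aligned_table` whose column ids are the substance ids.
#' @export
truth_area_table <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  wide <- truth$areas |>
    tidyr::pivot_wider(names_from = "substance", values_from = "area")
  sub <- truth$spec$substances
  structure(
    list(
      areas = wide,
      ranges = tibble(
        range_id = sub$substance,
        rt_low = sub$rt,
        rt_high = sub$rt,
        representative_rt = sub$rt,
        occurrence = nrow(wide),
        n_members = nrow(wide),
        prominent_mz = map(sub$mz, function(m) as.integer(names(m))),
        mean_jaccard = 1,
        verified = TRUE
      ),
      provenance = tibble(
        step = "truth_area_table",
        detail = "latent areas exposed without rendering"
      )
    ),
    class = "aligned_table"
  )
}

#' Match recovered ranges to ground-truth substances
#'
#' Assigns every retention-time range to the generator substance with the
#' nearest true retention time (within `tol` minutes), enabling sensitivity
#' and false-flag computations against the planted truth.
#'
#' @param ranges The `ranges` tibble of an `rt_ranges`/`aligned_table`, or
#'   either object itself.
#' @param spec The [effect_spec()] that generated the data.
#' @param tol Maximum |RT difference| in minutes for a match.
#' @return A tibble (`range_id`, `substance`, `rt_diff`); unmatched ranges
#'   get `NA` substance.
#' @export
match_ranges <- function(ranges, spec, tol = 0.05) {
  stopifnot(inherits(spec, "effect_spec"))
  if (inherits(ranges, "rt_ranges") || inherits(ranges, "aligned_table")) {
    ranges <- ranges$ranges
  }
  sub <- spec$substances
  hits <- map(ranges$representative_rt, function(rt) {
    i <- which.min(abs(sub$rt - rt))
    if (abs(sub$rt[i] - rt) <= tol) {
      list(substance = sub$substance[i], rt_diff = sub$rt[i] - rt)
    } else {
      list(substance = NA_character_, rt_diff = NA_real_)
    }
  })
  tibble(
    range_id = ranges$range_id,
    substance = map_chr(hits, "substance"),
    rt_diff = map_dbl(hits, "rt_diff")
  )
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_design()],
#' [simulate_intensities()] and [render_peak_lists()].
#'
#' @param config A [design_config()].
#' @param spec An [effect_spec()].
#' @param jitter_sd,dropout_rate,batch_shifts Passed to
#'   [render_peak_lists()].
#' @param seed Integer master seed shared by all stages.
#' @return A list with `design`, `truth`, `peaks` and the full `contaminants`
#'   reference table.
#' @export
simulate_study <- function(config = design_config(), spec = effect_spec(),
                           jitter_sd = 0.005, dropout_rate = 0.02,
                           batch_shifts = NULL, seed = 1) {
  design <- generate_design(config, seed = seed)
  truth <- simulate_intensities(design, spec, seed = seed)
  peaks <- render_peak_lists(truth,
    jitter_sd = jitter_sd, dropout_rate = dropout_rate,
    batch_shifts = batch_shifts, seed = seed
  )
  list(
    design = design,
    truth = truth,
    peaks = peaks,
    contaminants = contaminant_list(spec)
  )
}
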