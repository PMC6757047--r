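# Shared fixtures: all synthetic data is built in code at test time.

small_config <- function(n_females = 4,
                         quota = c(
                           "follicular" = 6, "peri-ovulatory" = 8,
                           "luteal" = 6
                         ),
                         n_cycles = 8, n_handling = 2, n_air = 2) {
  design_config(
    n_females = n_females, state_quota = quota, n_cycles = n_cycles,
    n_handling_blanks = n_handling, n_air_blanks = n_air
  )
}

small_spec <- function(...) {
  effect_spec(
    n_substances = 20, n_contaminants = 3, n_cycle = 2, n_age = 3,
    n_parity = 2, ...
  )
}

# Hand-built peak tibble from parallel vectors; spectra default to a single
# dominant fragment so quantification is transparent.
make_peaks <- function(sample_id, rt, area = 1, spectrum = NULL) {
  n <- length(rt)
  area <- rep_len(area, n)
  if (is.null(spectrum)) {
    spectrum <- lapply(area, function(a) stats::setNames(a, "100"))
  }
  tibble::tibble(
    sample_id = rep_len(sample_id, n),
    rt = rt, area = area, spectrum = spectrum
  )
}

# Aligned table built directly from a sample x substance matrix, with ranges
# at the given retention times and single-fragment prominent m/z.
make_aligned <- function(m, rts = NULL, prominent = NULL) {
  rts <- rts %||% seq_len(ncol(m))
  prominent <- prominent %||% replicate(ncol(m), 100L, simplify = FALSE)
  colnames(m) <- colnames(m) %||% sprintf("R%03d", seq_len(ncol(m)))
  rownames(m) <- rownames(m) %||% sprintf("s%02d", seq_len(nrow(m)))
  structure(
    list(
      areas = semioprofile:::matrix_to_wide(m),
      ranges = tibble::tibble(
        range_id = colnames(m),
        rt_low = rts, rt_high = rts, representative_rt = rts,
        occurrence = nrow(m), n_members = nrow(m),
        prominent_mz = prominent,
        mean_jaccard = 1, verified = TRUE
      ),
      provenance = tibble::tibble(step = character(), detail = character())
    ),
    class = "aligned_table"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force ANOSIM R: plain double loop over the formula.
brute_force_anosim_r <- function(d, groups) {
  n <- nrow(d)
  vals <- c()
  between <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      vals <- c(vals, d[i, j])
      between <- c(between, groups[i] != groups[j])
    }
  }
  r <- rank(vals)
  (mean(r[between]) - mean(r[!between])) / (length(vals) / 2)
}

# All permutations of a vector (recursive, independent of package internals).
all_perms <- function(v) {
  if (length(v) <= 1) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}
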