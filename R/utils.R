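# Internal helpers shared across modules.

# One RNG stream per pipeline stage: a stage-specific seed derived from the
# master seed so stages can be regenerated independently of each other.
stream_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(op)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(seed) * 48271 + h * 1103) %% 2147483629)
}

set_stream <- function(seed, op) {
  set.seed(stream_seed(seed, op))
}

# Population (n-denominator) standard deviation; used by the screening
# threshold, where the n-1 convention would make a homogeneous affected
# subset at 20% prevalence unreachable even without noise.
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Spectrum columns are list-columns of named numeric vectors: names are
# integer m/z values, entries fragment intensities.
spectrum_to_string <- function(sp) {
  map_chr(sp, function(s) {
    paste(sprintf("%s:%.17g", names(s), unname(s)), collapse = ";")
  })
}

string_to_spectrum <- function(x) {
  map(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(setNames(numeric(0), character(0)))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    setNames(
      vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
      vapply(parts, `[`, character(1), 1)
    )
  })
}

top_mz <- function(sp, k) {
  ord <- order(-sp, as.integer(names(sp)))
  as.integer(names(sp))[ord][seq_len(min(k, length(sp)))]
}

# Matrix view of a wide (sample_id + numeric columns) tibble.
wide_to_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

matrix_to_wide <- function(m) {
  bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
}
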