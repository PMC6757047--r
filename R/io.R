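#' Read and write peak lists
#'
#' Tab-separated peak-list dialect shared with deconvolution-tool exports:
#' columns `sample_id`, `rt_min`, `area` and `mz_list`, the latter encoding
#' the fragment spectrum as `m1:i1;m2:i2;...`.
#'
#' @param peaks A peak tibble with a `spectrum` list-column.
#' @param path File path.
#' @return `read_peak_lists()` returns the peak tibble;
#'   `write_peak_lists()` returns `path` invisibly.
#' @export
write_peak_lists <- function(peaks, path) {
  out <- tibble(
    sample_id = peaks$sample_id,
    rt_min = peaks$rt,
    area = peaks$area,
    mz_list = spectrum_to_string(peaks$spectrum)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_peak_lists
#' @export
read_peak_lists <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  tibble(
    sample_id = as.character(raw$sample_id),
    rt = raw$rt_min,
    area = raw$area,
    spectrum = string_to_spectrum(raw$mz_list)
  )
}

#' Read a known-contaminant list
#'
#' CSV dialect with columns `rt_low`, `rt_high` and `mz_list`
#' (";"-separated integer m/z).
#'
#' @param path File path.
#' @return A tibble suitable for [remove_contaminants()].
#' @export
read_contaminants <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  tibble(
    rt_low = raw$rt_low,
    rt_high = raw$rt_high,
    mz = map(
      strsplit(as.character(raw$mz_list), ";", fixed = TRUE),
      as.integer
    )
  )
}

#' Write an aligned or relative-area table
#'
#' Writes the wide sample-by-substance matrix as TSV together with a
#' `<path>.ranges.tsv` sidecar of per-range metadata (retention-time window,
#' representative RT, occurrence, prominent m/z).
#'
#' @param x An `aligned_table` or `relative_area_table`.
#' @param path File path of the matrix TSV.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(x, path) {
  wide <- if (inherits(x, "relative_area_table")) x$rel else x$areas
  readr::write_tsv(wide, path)
  ranges <- x$ranges
  if (!is.null(ranges$prominent_mz)) {
    ranges$prominent_mz <- map_chr(
      ranges$prominent_mz,
      function(m) paste(m, collapse = ";")
    )
  }
  readr::write_tsv(ranges, paste0(path, ".ranges.tsv"))
  invisible(path)
}

#' Autoplot methods for semioprofile results
#'
#' @param object A result object (`anosim_result`, `screen_result`).
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-semioprofile
NULL
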