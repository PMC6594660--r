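# Flat YAML-subset configuration: `key: value` scalars with `#` comments.
# Kept dependency-free on purpose; the config is a flat map of thresholds.

#' Default analysis configuration
#'
#' All tunable thresholds of the pipeline with their study defaults: the gene
#' pre-filter (total TPM >= 5, zero fraction < 0.25), the Bonferroni cycling
#' alpha 0.05, the amplitude-difference threshold 3 TPM, the phase-change
#' threshold 2 h (one sampling interval), promoter length 2000 bp, k-mer range
#' 3..8 with raw p < 0.05, the signed-network soft powers (WW 7, DR 10) and
#' merge heights (0.01, 0.15), and the interaction-network score thresholds
#' (WW 0.47, DR 0.52).
#'
#' @return named list of scalar settings.
#' @export
default_config <- function() {
  list(
    min_total_tpm = 5,
    max_zero_fraction = 0.25,
    period = 24,
    alpha = 0.05,
    amp_threshold = 3,
    phase_threshold = 2,
    promoter_length = 2000,
    kmin = 3,
    kmax = 8,
    element_alpha = 0.05,
    beta_ww = 7,
    beta_dr = 10,
    merge_height_ww = 0.01,
    merge_height_dr = 0.15,
    min_module_size = 10,
    cut_height = 0.85,
    net_threshold_ww = 0.47,
    net_threshold_dr = 0.52,
    dpi_tolerance = 0.1
  )
}

#' Read a flat YAML configuration file
#'
#' Supports the `key: value` scalar subset of YAML (comments and blank lines
#' allowed). Unknown keys are kept; missing keys fall back to
#' [default_config()].
#'
#' @param path file path.
#' @return named list of settings.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' Write a flat YAML configuration file
#' @param cfg named list of scalars.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(vapply(names(cfg), function(k) {
    sprintf("%s: %s", k, format(cfg[[k]], scientific = FALSE))
  }, ""), path)
  invisible(path)
}
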