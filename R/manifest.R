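# Dataset manifests: a YAML list of dataset entries (label, species, path,
# optional per-dataset thresholds and eligibility metadata), resolved into
# the manifest tibble run_cocoa() consumes.

#' Read a dataset manifest
#'
#' The YAML file holds a top-level `datasets:` sequence; each entry needs
#' `label`, `species` and `path`, and may carry `min_abs_log2fc`,
#' `max_padj`, `direction`, `genus`, `compound_molar_mass`,
#' `exposure_days`. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Path to the YAML manifest.
#' @return A manifest tibble, one row per dataset.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  doc <- yaml::read_yaml(path)
  entries <- doc$datasets %||% doc
  if (length(entries) == 0L) abort("manifest lists no datasets")
  out <- purrr::map_dfr(entries, function(e) {
    if (is.null(e$label) || is.null(e$species)) {
      abort("each manifest entry needs 'label' and 'species'")
    }
    tibble(label = e$label, species = e$species,
           path = e$path %||% NA_character_,
           min_abs_log2fc = e$min_abs_log2fc %||% 1,
           max_padj = e$max_padj %||% 0.05,
           direction = e$direction %||% "up")
  })
  if (anyDuplicated(out$label)) abort("duplicate dataset labels in manifest")
  base <- dirname(path)
  out |>
    mutate(path = ifelse(!is.na(.data$path) & !grepl("^(/|[A-Za-z]:)", .data$path),
                         file.path(base, .data$path), .data$path))
}
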