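# Differential-expression tables are consumed, not produced: rows carry a
# gene id, a log2 fold change and an adjusted p-value from whatever pipeline
# generated them (typically DESeq2 results).

#' Read a differential-expression result table
#'
#' Reads a TSV or CSV (gzip accepted transparently) and standardises the
#' mapped columns to `gene_id`, `log2fc`, `padj`. Non-numeric fold-change or
#' p-value cells become `NA` with an informative message counting them.
#'
#' @param path File path; `.csv`/`.csv.gz` parsed as comma-separated,
#'   anything else as tab-separated.
#' @param column_map Named character vector with entries `gene`, `log2fc`,
#'   `padj` giving the source column names.
#' @return Tibble with columns `gene_id`, `log2fc`, `padj`; row count equals
#'   the input row count.
#' @export
read_deg_table <- function(path,
                           column_map = c(gene = "gene",
                                          log2fc = "log2FoldChange",
                                          padj = "padj")) {
  need <- c("gene", "log2fc", "padj")
  if (!all(need %in% names(column_map))) {
    abort("`column_map` must name 'gene', 'log2fc' and 'padj' columns")
  }
  is_csv <- grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)
  reader <- if (is_csv) readr::read_csv else readr::read_tsv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  miss <- setdiff(unname(column_map[need]), names(raw))
  if (length(miss) > 0L) {
    abort(sprintf("mapped column(s) %s not found; available: %s",
                  paste(sQuote(miss), collapse = ", "),
                  paste(names(raw), collapse = ", ")))
  }
  out <- tibble(
    gene_id = raw[[column_map[["gene"]]]],
    log2fc = suppressWarnings(as.numeric(raw[[column_map[["log2fc"]]]])),
    padj = suppressWarnings(as.numeric(raw[[column_map[["padj"]]]]))
  )
  n_bad_fc <- sum(is.na(out$log2fc) & !is_na_like(raw[[column_map[["log2fc"]]]]))
  n_bad_p <- sum(is.na(out$padj) & !is_na_like(raw[[column_map[["padj"]]]]))
  if (n_bad_fc + n_bad_p > 0L) {
    inform(sprintf("parsed as missing: %d non-numeric log2fc, %d non-numeric padj cells",
                   n_bad_fc, n_bad_p))
  }
  bad_p <- !is.na(out$padj) & (out$padj < 0 | out$padj > 1)
  if (any(bad_p)) abort("adjusted p-values outside [0, 1]")
  out
}

is_na_like <- function(x) is.na(x) | toupper(trimws(x)) %in% c("NA", "NAN", "")

# Accept either the standardized shape (gene_id/log2fc/padj) or a table in
# the source dialect named by `column_map`.
standardize_deg_table <- function(degs, column_map) {
  if (all(c("gene_id", "log2fc", "padj") %in% names(degs))) {
    return(dplyr::select(degs, "gene_id", "log2fc", "padj"))
  }
  miss <- setdiff(unname(column_map[c("gene", "log2fc", "padj")]), names(degs))
  if (length(miss) > 0L) {
    abort(sprintf("DEG table lacks column(s) %s; available: %s",
                  paste(sQuote(miss), collapse = ", "),
                  paste(names(degs), collapse = ", ")))
  }
  tibble(gene_id = as.character(degs[[column_map[["gene"]]]]),
         log2fc = as.numeric(degs[[column_map[["log2fc"]]]]),
         padj = as.numeric(degs[[column_map[["padj"]]]]))
}

#' Filter a DEG table to significant genes
#'
#' Applies the up-regulation criterion: a gene is kept when its log2 fold
#' change strictly exceeds `min_abs_log2fc` (for `direction = "up"`) and its
#' adjusted p-value is present and strictly below `max_padj`. Genes with
#' missing `padj` are never kept (significance cannot be certified). When a
#' gene id occurs on several rows, the row with the smallest `padj` is used.
#'
#' @param degs Tibble with columns `gene_id`, `log2fc`, `padj` (as produced
#'   by [read_deg_table()]).
#' @param min_abs_log2fc Minimum absolute log2 fold change, strict (default 1).
#' @param max_padj Significance cutoff, strict (default 0.05).
#' @param direction One of `"up"`, `"down"`, `"both"`.
#' @return Sorted character vector of unique significant gene ids.
#' @export
filter_degs <- function(degs, min_abs_log2fc = 1, max_padj = 0.05,
                        direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  stopifnot(min_abs_log2fc >= 0, max_padj > 0, max_padj <= 1)
  if (nrow(degs) == 0L) return(character(0))
  best <- degs |>
    arrange(.data$gene_id, .data$padj) |>
    distinct(.data$gene_id, .keep_all = TRUE)
  sig <- !is.na(best$padj) & best$padj < max_padj & !is.na(best$log2fc)
  keep <- switch(direction,
    up = sig & best$log2fc > min_abs_log2fc,
    down = sig & best$log2fc < -min_abs_log2fc,
    both = sig & abs(best$log2fc) > min_abs_log2fc)
  sort(unique(best$gene_id[keep]))
}

#' Check dataset eligibility
#'
#' A transcriptome dataset qualifies for cross-species integration when its
#' organism's genus is on the allowed list, the exposure lasted strictly
#' less than six days, and the tested compound's molar mass is strictly
#' below 500 g/mol. All failing rules are reported.
#'
#' @param meta Tibble (or data frame) with columns `label`, `genus`,
#'   `compound_molar_mass` (g/mol) and `exposure_days`.
#' @param allowed_genera Character vector of allowed genera
#'   (default `"Aspergillus"`).
#' @param max_exposure_days Strict upper bound on exposure (default 6).
#' @param max_molar_mass Strict upper bound on molar mass in g/mol
#'   (default 500).
#' @return The input tibble with logical column `eligible` and character
#'   column `reasons` (semicolon-joined failing rules, `""` when eligible).
#' @export
validate_dataset <- function(meta, allowed_genera = "Aspergillus",
                             max_exposure_days = 6, max_molar_mass = 500) {
  need <- c("label", "genus", "compound_molar_mass", "exposure_days")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L) {
    abort(sprintf("`meta` lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  as_tibble(meta) |>
    mutate(
      reasons = purrr::pmap_chr(
        list(.data$genus, .data$compound_molar_mass, .data$exposure_days),
        function(g, mm, ed) {
          r <- character(0)
          if (!g %in% allowed_genera) r <- c(r, "genus not allowed")
          if (!is.finite(ed) || ed >= max_exposure_days) r <- c(r, "exposure period")
          if (!is.finite(mm) || mm >= max_molar_mass) r <- c(r, "molar mass")
          paste(r, collapse = "; ")
        }),
      eligible = !nzchar(.data$reasons))
}
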