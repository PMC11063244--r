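# Protein-domain annotations in the InterProScan tab-separated dialect:
# >=11 columns per row; column 1 the protein accession, 4-6 the member-db
# signature, and optional columns 12-13 the integrated InterPro accession
# and description ("-" when the signature maps to no InterPro entry).

#' Read an InterProScan-style TSV
#'
#' @param path Path to the TSV (no header).
#' @param id_transform Optional regular expression removed from protein ids
#'   to obtain gene ids (e.g. `"-T\\d+$"` strips transcript suffixes);
#'   `NULL` keeps ids as-is.
#' @return Domain annotation tibble with columns `gene_id`, `signature_db`,
#'   `signature_acc`, `interpro_acc` (`NA` for signature-only hits),
#'   `description`; one row per distinct (gene, signature, accession) hit,
#'   in file order. Rows with fewer than 11 columns are skipped and their
#'   line numbers reported.
#' @export
read_interproscan_tsv <- function(path, id_transform = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_annotation())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 11L
  if (any(short)) {
    inform(sprintf("skipped %d malformed row(s) with <11 columns (line %s)",
                   sum(short), paste(which(short), collapse = ", ")))
    fields <- fields[!short]
  }
  if (length(fields) == 0L) return(empty_annotation())
  get <- function(i) purrr::map_chr(fields, ~ if (length(.x) >= i) .x[[i]] else NA_character_)
  dash_na <- function(x) ifelse(is.na(x) | x == "-" | !nzchar(x), NA_character_, x)
  ann <- tibble(
    gene_id = get(1),
    signature_db = get(4),
    signature_acc = get(5),
    interpro_acc = dash_na(get(12)),
    description = dash_na(get(13)))
  if (!is.null(id_transform)) {
    ann <- mutate(ann, gene_id = sub(id_transform, "", .data$gene_id))
  }
  bad <- !is.na(ann$interpro_acc) & !grepl("^IPR\\d{6}$", ann$interpro_acc)
  if (any(bad)) {
    abort(sprintf("malformed InterPro accession: %s", ann$interpro_acc[bad][1]))
  }
  distinct(ann, .data$gene_id, .data$signature_acc, .data$interpro_acc,
           .keep_all = TRUE)
}

empty_annotation <- function() {
  tibble(gene_id = character(0), signature_db = character(0),
         signature_acc = character(0), interpro_acc = character(0),
         description = character(0))
}

#' Read a compact gene-to-domains map
#'
#' Fixture-friendly two-column TSV: gene id and a semicolon-joined list of
#' InterPro accessions (empty for genes with no integrated domain).
#'
#' @param path Path to the TSV with header columns `gene_id`, `interpro_accs`.
#' @return A domain annotation tibble in the same shape as
#'   [read_interproscan_tsv()] (signature columns `NA`).
#' @export
read_domain_map <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("gene_id", "interpro_accs") %in% names(raw))) {
    abort("domain map must have columns 'gene_id' and 'interpro_accs'")
  }
  ann <- raw |>
    mutate(interpro_acc = purrr::map(.data$interpro_accs,
                                     ~ if (is.na(.x) || !nzchar(.x)) character(0)
                                       else trimws(strsplit(.x, ";")[[1]]))) |>
    dplyr::select("gene_id", "interpro_acc") |>
    tidyr::unnest("interpro_acc") |>
    mutate(signature_db = NA_character_, signature_acc = NA_character_,
           description = NA_character_) |>
    dplyr::select("gene_id", "signature_db", "signature_acc",
                  "interpro_acc", "description") |>
    distinct(.data$gene_id, .data$interpro_acc, .keep_all = TRUE)
  bad <- !grepl("^IPR\\d{6}$", ann$interpro_acc)
  if (any(bad)) abort(sprintf("malformed InterPro accession: %s",
                              ann$interpro_acc[bad][1]))
  ann
}

#' Domains annotated on one gene
#'
#' @param annotation Domain annotation tibble.
#' @param gene_id Gene to look up.
#' @return Tibble with columns `interpro_acc`, `description`, deduplicated
#'   in first-occurrence order; zero rows for unannotated genes.
#' @export
domains_for <- function(annotation, gene_id) {
  annotation |>
    filter(.data$gene_id == !!gene_id, !is.na(.data$interpro_acc)) |>
    distinct(.data$interpro_acc, .keep_all = TRUE) |>
    dplyr::select("interpro_acc", "description")
}

#' Attach domain annotations to a conservation report
#'
#' Adds semicolon-joined `interpro_accs` and `interpro_descs` columns to the
#' report (row order, gene set and `k` values untouched) and computes a
#' domain frequency table counting *genes* (not hits) per accession among
#' the reported genes. The frequency table is attached as attribute
#' `domain_freq` and retrievable with [domain_frequency()].
#'
#' @param report Conservation report tibble (from [genes_in_at_least()]).
#' @param annotation Domain annotation tibble.
#' @return The report with the two extra columns.
#' @export
annotate_report <- function(report, annotation) {
  ann <- annotation |>
    filter(!is.na(.data$interpro_acc)) |>
    distinct(.data$gene_id, .data$interpro_acc, .keep_all = TRUE)
  per_gene <- ann |>
    group_by(.data$gene_id) |>
    summarise(
      interpro_accs = paste(.data$interpro_acc, collapse = ";"),
      interpro_descs = paste(ifelse(is.na(.data$description), "",
                                    .data$description), collapse = ";"),
      .groups = "drop")
  out <- report |>
    left_join(per_gene, by = "gene_id") |>
    mutate(across(c("interpro_accs", "interpro_descs"),
                  ~ tidyr::replace_na(.x, "")))
  freq <- ann |>
    semi_join(report, by = "gene_id") |>
    distinct(.data$gene_id, .data$interpro_acc, .keep_all = TRUE) |>
    count(.data$interpro_acc, .data$description, name = "n_genes") |>
    arrange(desc(.data$n_genes), .data$interpro_acc)
  attr(out, "domain_freq") <- freq
  out
}

#' Domain frequency table of an annotated report
#'
#' @param report An annotated conservation report (from [annotate_report()]).
#' @return Tibble with columns `interpro_acc`, `description`, `n_genes`.
#' @export
domain_frequency <- function(report) {
  freq <- attr(report, "domain_freq")
  if (is.null(freq)) abort("report carries no domain frequencies; run annotate_report() first")
  freq
}

#' Write a domain annotation as a compact gene-to-domains map
#'
#' Inverse of [read_domain_map()] on accession sets.
#'
#' @param annotation Domain annotation tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_domain_map <- function(annotation, path) {
  out <- annotation |>
    filter(!is.na(.data$interpro_acc)) |>
    group_by(.data$gene_id) |>
    summarise(interpro_accs = paste(unique(.data$interpro_acc), collapse = ";"),
              .groups = "drop")
  readr::write_tsv(out, path)
  invisible(path)
}
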