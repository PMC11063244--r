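# The core of the pipeline: re-express each species' up-regulated gene set
# in the gene space of a single "receiver" species via orthogroup
# membership, then decompose the transposed sets into exhaustive Venn
# regions and report genes supported by at least k datasets.

#' Transpose a gene set into receiver-species space
#'
#' Each source gene maps to every receiver-species member of its orthogroup
#' (one-to-many fan-out). Genes in no orthogroup, or in an orthogroup with
#' no receiver member, are recorded as unmapped with the reason. When the
#' source species *is* the receiver, the mapping defaults to the identity
#' restricted to the receiver inventory, so receiver genes sitting in
#' receiver-only or absent orthogroups are not dropped; set
#' `identity_for_receiver = FALSE` to force the orthology route instead.
#'
#' @param deg_genes Character vector of source-species gene ids.
#' @param source_species,receiver Species codes; both must exist in the
#'   species universe (orthogroup table plus inventory).
#' @param orthogroups Long orthogroup tibble (`og_id`, `species`, `gene_id`).
#' @param inventory Inventory tibble (`species`, `gene_id`).
#' @param label Optional dataset label carried into reports.
#' @param identity_for_receiver Use identity mapping when source == receiver
#'   (default `TRUE`).
#' @param collapse_to_og If `TRUE`, receiver genes are replaced by their
#'   orthogroup ids (membership collapses to one unit per orthogroup).
#' @return Object of class `transposed_dataset`: list with `label`,
#'   `source_species`, `receiver`, `genes` (sorted unique receiver gene
#'   ids), and `provenance` (tibble: `source_gene`, `receiver_gene`,
#'   `status` in mapped / no_orthogroup / no_receiver_member /
#'   not_in_inventory). `tidy()` returns the provenance table.
#' @export
transpose_dataset <- function(deg_genes, source_species, orthogroups, inventory,
                              receiver, label = source_species,
                              identity_for_receiver = TRUE,
                              collapse_to_og = FALSE) {
  species_universe <- union(unique(orthogroups$species), unique(inventory$species))
  for (sp in c(source_species, receiver)) {
    if (!sp %in% species_universe) abort(sprintf("unknown species code '%s'", sp))
  }
  deg_genes <- unique(deg_genes)

  if (identical(source_species, receiver) && identity_for_receiver) {
    inv_rec <- inventory |> filter(.data$species == receiver) |> pull(.data$gene_id)
    prov <- tibble(
      source_gene = as.character(deg_genes),
      receiver_gene = ifelse(deg_genes %in% inv_rec, deg_genes, NA_character_) |>
        as.character(),
      status = as.character(ifelse(deg_genes %in% inv_rec, "mapped",
                                   "not_in_inventory")))
  } else {
    src_og <- orthogroups |>
      filter(.data$species == source_species) |>
      dplyr::select(source_gene = "gene_id", "og_id")
    rec_members <- orthogroups |>
      filter(.data$species == receiver) |>
      dplyr::select("og_id", receiver_gene = "gene_id")
    base <- tibble(source_gene = deg_genes) |>
      left_join(src_og, by = "source_gene") |>
      left_join(rec_members, by = "og_id", relationship = "many-to-many")
    prov <- base |>
      mutate(status = dplyr::case_when(
        is.na(.data$og_id) ~ "no_orthogroup",
        is.na(.data$receiver_gene) ~ "no_receiver_member",
        TRUE ~ "mapped")) |>
      mutate(receiver_gene = if (collapse_to_og)
               ifelse(.data$status == "mapped", .data$og_id, NA_character_)
             else .data$receiver_gene) |>
      distinct(.data$source_gene, .data$receiver_gene, .data$status) |>
      dplyr::select("source_gene", "receiver_gene", "status")
  }
  structure(list(
    label = label,
    source_species = source_species,
    receiver = receiver,
    genes = sort(unique(as.character(prov$receiver_gene[prov$status == "mapped"]))),
    provenance = prov), class = "transposed_dataset")
}

#' @export
print.transposed_dataset <- function(x, ...) {
  cnt <- table(x$provenance$status)
  cat(sprintf("<transposed_dataset '%s': %s -> %s>\n", x$label,
              x$source_species, x$receiver))
  cat(sprintf("  %d source genes -> %d receiver genes (%s)\n",
              dplyr::n_distinct(x$provenance$source_gene), length(x$genes),
              paste(sprintf("%s: %d", names(cnt), cnt), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.transposed_dataset <- function(x, ...) x$provenance

#' Exhaustive Venn decomposition of gene sets
#'
#' Assigns every gene in the union of the input sets to exactly one region:
#' the subset of dataset labels whose sets contain it. Empty regions are
#' omitted, so at most `2^N - 1` regions appear. Signatures are
#' canonicalised by the input label order and joined with `"+"`.
#'
#' @param sets Named list of character vectors, or a list of
#'   `transposed_dataset` objects (labels taken from the objects). 1-12
#'   sets; labels must be unique.
#' @return Object of class `venn_decomposition`: list with `labels`,
#'   `membership` (tibble: `gene_id`, `signature`, `k`) and `regions`
#'   (tibble: `signature`, `k`, `n_genes`). `tidy()` returns the
#'   membership table.
#' @export
venn_decompose <- function(sets) {
  if (length(sets) > 0L && inherits(sets[[1]], "transposed_dataset")) {
    names(sets) <- purrr::map_chr(sets, "label")
    sets <- purrr::map(sets, "genes")
  }
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels))) abort("sets must be named")
  if (anyDuplicated(labels)) abort("duplicate dataset labels")
  if (length(sets) < 1L || length(sets) > 12L) abort("need between 1 and 12 sets")

  membership <- purrr::imap_dfr(sets, ~ tibble(gene_id = unique(.x), label = .y)) |>
    mutate(label = factor(.data$label, levels = labels)) |>
    group_by(.data$gene_id) |>
    summarise(signature = paste(sort(as.integer(.data$label)) |>
                                  (\(i) labels[i])() |> unique(),
                                collapse = "+"),
              k = dplyr::n_distinct(.data$label), .groups = "drop") |>
    arrange(desc(.data$k), .data$gene_id)
  regions <- membership |>
    count(.data$signature, .data$k, name = "n_genes") |>
    arrange(desc(.data$k), .data$signature)
  structure(list(labels = labels, membership = membership, regions = regions),
            class = "venn_decomposition")
}

#' @export
print.venn_decomposition <- function(x, ...) {
  cat(sprintf("<venn_decomposition: %d datasets, %d genes, %d non-empty regions>\n",
              length(x$labels), nrow(x$membership), nrow(x$regions)))
  print(x$regions)
  invisible(x)
}

#' @export
tidy.venn_decomposition <- function(x, ...) x$membership

#' Region-count bar chart for a Venn decomposition
#'
#' @param object A `venn_decomposition`.
#' @param ... Unused.
#' @return A ggplot: one bar per non-empty region, ordered by the number of
#'   supporting datasets.
#' @export
autoplot.venn_decomposition <- function(object, ...) {
  df <- object$regions |>
    mutate(signature = factor(.data$signature,
                              levels = rev(object$regions$signature)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_genes, y = .data$signature,
                                   fill = factor(.data$k))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "genes in region", y = NULL, fill = "datasets (k)") +
    ggplot2::theme_minimal()
}

#' Genes present in at least k datasets
#'
#' @param venn A `venn_decomposition`.
#' @param k Minimum number of supporting datasets, `1 <= k <= N`.
#' @return A conservation report: tibble with columns `gene_id`, `datasets`
#'   (the `+`-joined signature), `k`, sorted by `k` descending then gene id.
#'   `k = 1` lists the full union; row counts are non-increasing in `k`.
#' @export
genes_in_at_least <- function(venn, k) {
  stopifnot(inherits(venn, "venn_decomposition"))
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > length(venn$labels)) {
    abort(sprintf("k must be in [1, %d]", length(venn$labels)))
  }
  venn$membership |>
    filter(.data$k >= !!k) |>
    dplyr::select("gene_id", datasets = "signature", "k") |>
    arrange(desc(.data$k), .data$gene_id)
}

#' Run the full cross-species co-expression analysis
#'
#' For each dataset in the manifest: read (or take) its DEG table, apply the
#' significance filter, transpose the resulting gene set into receiver
#' space; then Venn-decompose all transposed sets and report genes
#' supported by at least `min_datasets` datasets, optionally with protein
#' domains attached.
#'
#' @param manifest Tibble with columns `label`, `species`, and either
#'   `path` (DEG table files) or entries in `deg_tables`; optional per-row
#'   columns `min_abs_log2fc`, `max_padj`, `direction` override the filter
#'   defaults.
#' @param orthogroups Long orthogroup tibble.
#' @param inventory Inventory tibble.
#' @param receiver Receiver species code.
#' @param deg_tables Optional named list (by label) of in-memory DEG
#'   tibbles, used instead of reading `manifest$path`.
#' @param annotation Optional domain annotation tibble
#'   (see [read_interproscan_tsv()]).
#' @param min_datasets Minimum dataset support for the report (default 1).
#' @param identity_for_receiver Passed to [transpose_dataset()].
#' @param column_map Passed to [read_deg_table()] for file inputs.
#' @return Object of class `cocoa_result`: list with `report` (conservation
#'   report at `min_datasets`, annotated when `annotation` is given),
#'   `venn`, `transposed` (list of `transposed_dataset`), and
#'   `provenance_summary` (per-dataset tibble: input / mapped / unmapped
#'   counts and receiver-gene counts).
#' @export
run_cocoa <- function(manifest, orthogroups, inventory, receiver,
                      deg_tables = NULL, annotation = NULL, min_datasets = 1,
                      identity_for_receiver = TRUE,
                      column_map = c(gene = "gene", log2fc = "log2FoldChange",
                                     padj = "padj")) {
  need <- c("label", "species")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0L) abort(sprintf("manifest lacks column(s): %s",
                                       paste(miss, collapse = ", ")))
  if (anyDuplicated(manifest$label)) abort("duplicate dataset labels in manifest")

  transposed <- purrr::pmap(manifest, function(label, species, ...) {
    row <- list(...)
    degs <- if (!is.null(deg_tables)) {
      if (!label %in% names(deg_tables)) {
        abort(sprintf("[deg] no table supplied for dataset '%s'", label))
      }
      standardize_deg_table(deg_tables[[label]], column_map)
    } else {
      if (is.null(row$path)) abort(sprintf("[deg] dataset '%s': no path and no table", label))
      tryCatch(read_deg_table(row$path, column_map = column_map),
               error = function(e) abort(sprintf("[deg] dataset '%s': %s",
                                                 label, conditionMessage(e))))
    }
    genes <- filter_degs(degs,
                         min_abs_log2fc = row$min_abs_log2fc %||% 1,
                         max_padj = row$max_padj %||% 0.05,
                         direction = row$direction %||% "up")
    transpose_dataset(genes, species, orthogroups, inventory, receiver,
                      label = label,
                      identity_for_receiver = identity_for_receiver)
  })
  names(transposed) <- manifest$label

  venn <- venn_decompose(transposed)
  if (min_datasets > length(transposed)) {
    abort("min_datasets exceeds the number of datasets")
  }
  report <- genes_in_at_least(venn, min_datasets)
  if (!is.null(annotation)) report <- annotate_report(report, annotation)

  provenance_summary <- purrr::map_dfr(transposed, function(tr) {
    st <- tr$provenance$status
    tibble(label = tr$label,
           species = tr$source_species,
           n_input = dplyr::n_distinct(tr$provenance$source_gene),
           n_mapped = dplyr::n_distinct(tr$provenance$source_gene[st == "mapped"]),
           n_no_orthogroup = sum(st == "no_orthogroup"),
           n_no_receiver_member =
             dplyr::n_distinct(tr$provenance$source_gene[st == "no_receiver_member"]),
           n_receiver_genes = length(tr$genes))
  })
  structure(list(report = report, venn = venn, transposed = transposed,
                 provenance_summary = provenance_summary,
                 receiver = receiver, min_datasets = min_datasets),
            class = "cocoa_result")
}

#' @export
print.cocoa_result <- function(x, ...) {
  cat(sprintf("<cocoa_result: %d datasets -> receiver '%s'>\n",
              length(x$transposed), x$receiver))
  print(x$provenance_summary)
  cat(sprintf("Report (k >= %d): %d genes\n", x$min_datasets, nrow(x$report)))
  print(head(x$report, 10))
  invisible(x)
}

#' @export
tidy.cocoa_result <- function(x, ...) x$report

#' @export
glance.cocoa_result <- function(x, ...) {
  tibble(n_datasets = length(x$transposed),
         n_union = nrow(x$venn$membership),
         n_regions = nrow(x$venn$regions),
         n_reported = nrow(x$report),
         min_datasets = x$min_datasets)
}

#' Write the standard result files of a run
#'
#' Emits `conservation_report.tsv`, `venn_regions.json` and
#' `provenance_summary.json` into `dir`.
#'
#' @param result A `cocoa_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cocoa_result <- function(result, dir) {
  stopifnot(inherits(result, "cocoa_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$report, file.path(dir, "conservation_report.tsv"))
  jsonlite::write_json(
    purrr::set_names(as.list(result$venn$regions$n_genes),
                     result$venn$regions$signature),
    file.path(dir, "venn_regions.json"), auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(result$provenance_summary,
                       file.path(dir, "provenance_summary.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
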