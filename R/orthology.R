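# Orthogroup tables are held in long form: one row per gene, columns
# og_id / species / gene_id. A gene belongs to at most one orthogroup;
# genes present in an inventory but absent from the table are "unassigned"
# and still count in percentage denominators.

#' Read a genome inventory
#'
#' An inventory declares, per species, the full ordered set of gene
#' identifiers of that genome. Accepts a two-column TSV (species, gene_id),
#' or a FASTA file per species from which only the header ids are taken.
#'
#' @param path Path to a two-column TSV with columns `species` and `gene_id`
#'   (header optional when `col_names = FALSE`).
#' @param col_names Logical; does the file carry a header row?
#' @return A tibble with columns `species`, `gene_id`.
#' @export
read_inventory <- function(path, col_names = TRUE) {
  inv <- readr::read_tsv(path, col_names = col_names,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!col_names) names(inv) <- c("species", "gene_id")[seq_along(inv)]
  if (!all(c("species", "gene_id") %in% names(inv))) {
    abort("inventory must have columns 'species' and 'gene_id'")
  }
  inv <- dplyr::select(inv, "species", "gene_id")
  validate_inventory(inv)
  inv
}

#' Build an inventory from per-species FASTA files
#'
#' Only sequence headers are read; the first whitespace-delimited token of
#' each `>` line becomes the gene id.
#'
#' @param paths Named character vector: species code -> FASTA path.
#' @return A tibble with columns `species`, `gene_id`.
#' @export
inventory_from_fasta <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    abort("`paths` must be named by species code")
  }
  purrr::imap_dfr(paths, function(p, sp) {
    ln <- readLines(p)
    hdr <- ln[startsWith(ln, ">")]
    ids <- sub("\\s.*$", "", sub("^>", "", hdr))
    tibble(species = sp, gene_id = ids)
  }) |> validate_inventory()
}

validate_inventory <- function(inv) {
  stopifnot(all(c("species", "gene_id") %in% names(inv)))
  if (any(!nzchar(inv$gene_id))) abort("inventory contains empty gene ids")
  dup <- inv |> count(.data$species, .data$gene_id) |> filter(n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("duplicate gene id within a species: %s (%s)",
                  dup$gene_id[1], dup$species[1]))
  }
  invisible(inv)
}

#' Read an OrthoFinder-style orthogroup table
#'
#' Parses the tab-separated orthogroup dialect: header row
#' `Orthogroup<TAB>species1<TAB>...`, one row per orthogroup, each species
#' cell holding comma(+space)-separated gene ids, empty cell meaning the
#' orthogroup has no member in that species.
#'
#' @param path Path to the TSV.
#' @param inventory Optional inventory tibble (`species`, `gene_id`); when
#'   supplied, parsed genes are checked against it.
#' @param aliases Optional named character vector mapping file header names
#'   to species codes (e.g. `c("A_nidulans_FGSCA4" = "Anid")`).
#' @param on_missing What to do when a parsed gene is absent from the
#'   inventory: `"warn"` keeps the gene and reports a count, `"error"` stops.
#' @return A long tibble with columns `og_id`, `species`, `gene_id`.
#'   A gene appearing in more than one orthogroup is a hard error.
#' @export
read_orthogroups <- function(path, inventory = NULL, aliases = NULL,
                             on_missing = c("warn", "error")) {
  on_missing <- match.arg(on_missing)
  raw <- readr::read_tsv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2L) abort("orthogroup table needs an id column plus >=1 species column")
  names(raw)[1] <- "og_id"
  sp_cols <- names(raw)[-1]
  if (!is.null(aliases)) {
    hit <- sp_cols %in% names(aliases)
    sp_cols[hit] <- unname(aliases[sp_cols[hit]])
    names(raw) <- c("og_id", sp_cols)
  }
  long <- raw |>
    tidyr::pivot_longer(-"og_id", names_to = "species", values_to = "members") |>
    filter(!is.na(.data$members), nzchar(trimws(.data$members))) |>
    mutate(gene_id = strsplit(.data$members, ",\\s*")) |>
    tidyr::unnest("gene_id") |>
    mutate(gene_id = trimws(.data$gene_id)) |>
    filter(nzchar(.data$gene_id)) |>
    dplyr::select("og_id", "species", "gene_id")
  validate_orthogroups(long)
  if (!is.null(inventory)) {
    missing <- anti_join(long, inventory, by = c("species", "gene_id"))
    if (nrow(missing) > 0L) {
      msg <- sprintf("%d orthogroup gene(s) absent from the inventory (e.g. %s/%s)",
                     nrow(missing), missing$species[1], missing$gene_id[1])
      if (on_missing == "error") abort(msg) else warn(msg)
    }
  }
  long
}

validate_orthogroups <- function(og) {
  stopifnot(all(c("og_id", "species", "gene_id") %in% names(og)))
  dup <- og |> distinct(.data$og_id, .data$species, .data$gene_id) |>
    count(.data$species, .data$gene_id) |> filter(n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("gene assigned to more than one orthogroup: %s (%s)",
                  dup$gene_id[1], dup$species[1]))
  }
  invisible(og)
}

#' Summarise genome-level orthology statistics
#'
#' Computes, per species, the genome size, the percentage of genes assigned
#' to any orthogroup, and the number of species-specific orthogroups
#' (orthogroups whose members all come from that one species); globally, the
#' total number of orthogroups, the total number of species-specific
#' orthogroups, and the percentage of all genes that sit in species-specific
#' orthogroups. Unassigned genes count in every denominator. Percentages are
#' reported to one decimal place.
#'
#' @param orthogroups Long orthogroup tibble (`og_id`, `species`, `gene_id`).
#' @param inventory Inventory tibble (`species`, `gene_id`); its species set
#'   defines the analysis. A species with zero genes is an error.
#' @return An object of class `genome_summary`: list with `per_species`
#'   (tibble: `species`, `n_genes`, `n_in_orthogroups`, `pct_in_orthogroups`,
#'   `n_species_specific_ogs`) and `global` (one-row tibble: `n_orthogroups`,
#'   `n_species_specific_ogs`, `pct_genes_in_species_specific`,
#'   `pct_assigned_genes_in_species_specific`). `tidy()` returns the
#'   per-species table, `glance()` the global row.
#' @export
summarize_genomes <- function(orthogroups, inventory) {
  validate_inventory(inventory)
  validate_orthogroups(orthogroups)
  extra <- setdiff(orthogroups$species, inventory$species)
  if (length(extra) > 0L) {
    abort(sprintf("orthogroup table names species absent from the inventory: %s",
                  paste(extra, collapse = ", ")))
  }
  genome <- inventory |> count(.data$species, name = "n_genes")
  if (any(genome$n_genes == 0L)) abort("species with zero genes: percentage undefined")

  og_species <- orthogroups |>
    group_by(.data$og_id) |>
    summarise(n_species = dplyr::n_distinct(.data$species), .groups = "drop")
  ss_ogs <- og_species |> filter(.data$n_species == 1L) |> pull(.data$og_id)

  assigned <- orthogroups |> count(.data$species, name = "n_in_orthogroups")
  ss_by_species <- orthogroups |>
    filter(.data$og_id %in% ss_ogs) |>
    distinct(.data$og_id, .data$species) |>
    count(.data$species, name = "n_species_specific_ogs")

  per_species <- genome |>
    left_join(assigned, by = "species") |>
    left_join(ss_by_species, by = "species") |>
    mutate(dplyr::across(c("n_in_orthogroups", "n_species_specific_ogs"),
                         ~ tidyr::replace_na(.x, 0L)),
           pct_in_orthogroups = round(100 * .data$n_in_orthogroups / .data$n_genes, 1)) |>
    dplyr::select("species", "n_genes", "n_in_orthogroups", "pct_in_orthogroups",
                  "n_species_specific_ogs") |>
    arrange(.data$species)

  n_genes_ss <- orthogroups |> filter(.data$og_id %in% ss_ogs) |> nrow()
  total_genes <- sum(per_species$n_genes)
  total_assigned <- sum(per_species$n_in_orthogroups)
  global <- tibble(
    n_orthogroups = dplyr::n_distinct(orthogroups$og_id),
    n_species_specific_ogs = length(ss_ogs),
    pct_genes_in_species_specific = round(100 * n_genes_ss / total_genes, 1),
    pct_assigned_genes_in_species_specific =
      if (total_assigned > 0L) round(100 * n_genes_ss / total_assigned, 1) else NA_real_
  )
  structure(list(per_species = per_species, global = global),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("Genome orthology summary\n")
  cat(sprintf("  %d orthogroups, %d species-specific (%.1f%% of all genes)\n",
              x$global$n_orthogroups, x$global$n_species_specific_ogs,
              x$global$pct_genes_in_species_specific))
  print(x$per_species)
  invisible(x)
}

#' @export
tidy.genome_summary <- function(x, ...) x$per_species

#' @export
glance.genome_summary <- function(x, ...) x$global

#' Per-species size of one orthogroup
#'
#' @param orthogroups Long orthogroup tibble.
#' @param og_id Orthogroup id to profile.
#' @return A tibble with columns `species` and `n_genes`, one row per species
#'   holding members; the orthogroup's total size is `sum(n_genes)` and is
#'   attached as attribute `total`.
#' @export
og_size_by_species <- function(orthogroups, og_id) {
  validate_orthogroups(orthogroups)
  out <- orthogroups |>
    filter(.data$og_id == !!og_id) |>
    count(.data$species, name = "n_genes") |>
    arrange(.data$species)
  attr(out, "total") <- sum(out$n_genes)
  out
}

#' Read a gene tree from newick
#'
#' Thin validated wrapper over [ape::read.tree()]. Leaf labels follow the
#' `species<sep>gene_id` convention (configurable separator), which
#' [split_gene_labels()] decodes.
#'
#' @param newick Either a newick string or a path to a newick file.
#' @return An [ape::phylo] tree.
#' @export
read_gene_tree <- function(newick) {
  tr <- if (length(newick) == 1L && !file.exists(newick) && grepl("\\(", newick)) {
    tryCatch(ape::read.tree(text = newick), error = function(e) NULL,
             warning = function(w) NULL)
  } else {
    tryCatch(ape::read.tree(newick), error = function(e) NULL,
             warning = function(w) NULL)
  }
  if (is.null(tr)) abort("malformed newick: could not be parsed")
  if (anyDuplicated(tr$tip.label)) abort("gene tree leaf labels must be unique")
  tr
}

#' Decode `species|gene` leaf labels
#'
#' @param labels Character vector of leaf labels.
#' @param sep Separator between species code and gene id (default `"|"`).
#' @return Tibble with columns `label`, `species`, `gene_id`; labels lacking
#'   the separator get `NA` species and the whole label as gene id.
#' @export
split_gene_labels <- function(labels, sep = "|") {
  parts <- stringr::str_split_fixed(labels, stringr::fixed(sep), 2L)
  has_sep <- nzchar(parts[, 2])
  tibble(label = labels,
         species = ifelse(has_sep, parts[, 1], NA_character_),
         gene_id = ifelse(has_sep, parts[, 2], labels))
}

#' Partition gene-tree leaves into the root's child clades
#'
#' The deepest split of a rooted gene tree separates its leaves into one
#' cluster per root child — the clusters seen when an orthogroup's gene tree
#' resolves into distinct subfamilies.
#'
#' @param tree A rooted [ape::phylo] tree with at least 2 leaves.
#' @return Tibble with columns `label` and `cluster` (integer id of the root
#'   child clade, in root-child order). Clusters are disjoint and cover all
#'   leaves.
#' @export
root_split_clusters <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object")
  ntip <- length(tree$tip.label)
  if (ntip < 2L) abort("tree must have at least 2 leaves")
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  root <- ntip + 1L
  children <- tree$edge[tree$edge[, 1] == root, 2]
  purrr::imap_dfr(children, function(child, i) {
    tips <- if (child <= ntip) tree$tip.label[child]
            else ape::extract.clade(tree, child)$tip.label
    tibble(label = tips, cluster = i)
  })
}

#' Do two leaves fall in the same root clade?
#'
#' @param tree A rooted gene tree.
#' @param leaf1,leaf2 Leaf labels.
#' @return `TRUE` iff both leaves descend from the same child of the root.
#' @export
same_root_clade <- function(tree, leaf1, leaf2) {
  cl <- root_split_clusters(tree)
  for (lf in c(leaf1, leaf2)) {
    if (!lf %in% cl$label) abort(sprintf("leaf '%s' not in tree", lf))
  }
  cl$cluster[match(leaf1, cl$label)] == cl$cluster[match(leaf2, cl$label)]
}
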