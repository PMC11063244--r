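# Shared builders and independent oracles. Oracles are deliberately naive
# (per-row loops, brute-force enumeration) so they stay independent of the
# vectorised implementation paths they check.

build_og <- function(spec) {
  # spec: named list og_id -> named list species -> gene ids
  purrr::imap_dfr(spec, function(members, og) {
    purrr::imap_dfr(members, function(genes, sp) {
      tibble::tibble(og_id = og, species = sp, gene_id = genes)
    })
  })
}

build_inventory <- function(spec) {
  # spec: named list species -> gene ids
  purrr::imap_dfr(spec, function(genes, sp) {
    tibble::tibble(species = sp, gene_id = genes)
  })
}

write_og_tsv <- function(rows, path = withr::local_tempfile(fileext = ".tsv",
                                                            .local_envir = parent.frame())) {
  # rows: character vector of tab-separated lines incl. header
  writeLines(rows, path)
  path
}

# Brute-force Venn signature oracle: per gene, scan every set.
venn_oracle <- function(sets) {
  genes <- sort(unique(unlist(sets)))
  purrr::map_dfr(genes, function(g) {
    inset <- names(sets)[purrr::map_lgl(sets, ~ g %in% .x)]
    tibble::tibble(gene_id = g,
                   signature = paste(names(sets)[names(sets) %in% inset],
                                     collapse = "+"),
                   k = length(inset))
  })
}

# Brute-force genome-summary oracle: recount row by row.
summary_oracle <- function(og, inv) {
  species <- sort(unique(inv$species))
  per <- purrr::map_dfr(species, function(sp) {
    genes <- inv$gene_id[inv$species == sp]
    assigned <- 0L
    for (g in genes) assigned <- assigned + any(og$species == sp & og$gene_id == g)
    ss <- 0L
    for (o in unique(og$og_id)) {
      sps <- unique(og$species[og$og_id == o])
      if (length(sps) == 1L && sps == sp) ss <- ss + 1L
    }
    tibble::tibble(species = sp, n_genes = length(genes),
                   n_in_orthogroups = assigned,
                   pct_in_orthogroups = round(100 * assigned / length(genes), 1),
                   n_species_specific_ogs = ss)
  })
  n_ss_genes <- 0L
  for (o in unique(og$og_id)) {
    sps <- unique(og$species[og$og_id == o])
    if (length(sps) == 1L) n_ss_genes <- n_ss_genes + sum(og$og_id == o)
  }
  list(per_species = per,
       n_orthogroups = length(unique(og$og_id)),
       n_species_specific_ogs = sum(per$n_species_specific_ogs),
       pct_genes_in_species_specific = round(100 * n_ss_genes / sum(per$n_genes), 1))
}

# Random small orthogroup table + inventory for property tests.
random_og_instance <- function(n_species = 3, n_genes = 30) {
  species <- LETTERS[seq_len(n_species)]
  inv <- purrr::map_dfr(species, function(sp) {
    tibble::tibble(species = sp,
                   gene_id = sprintf("%s_g%02d", sp, seq_len(sample(3:ceiling(n_genes / n_species), 1))))
  })
  assigned <- inv[runif(nrow(inv)) < 0.8, ]
  n_og <- max(1L, ceiling(nrow(assigned) / 3))
  assigned$og_id <- sprintf("OG%03d", sample(n_og, nrow(assigned), replace = TRUE))
  list(og = dplyr::select(assigned, og_id, species, gene_id), inv = inv)
}

gompertz_series <- function(A, s, m, xs) {
  tibble::tibble(concentration = xs, response = A * exp(-exp(s * (xs - m))))
}

`%||%` <- rlang::`%||%`
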