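test_that("read_orthogroups parses the tab-separated dialect", {
  path <- write_og_tsv(c("Orthogroup\tA\tB",
                         "OG1\ta1, a2\tb1",
                         "OG2\t\tb2"))
  og <- read_orthogroups(path)
  expect_equal(sort(unique(og$og_id)), c("OG1", "OG2"))
  expect_equal(sum(og$og_id == "OG1"), 3L)
  expect_equal(sum(og$og_id == "OG2"), 1L)
  expect_equal(og$species[og$og_id == "OG2"], "B")
})

test_that("read_orthogroups handles empty tables and alias maps", {
  path <- write_og_tsv("Orthogroup\tA_nidulans_FGSCA4\tB")
  og <- read_orthogroups(path, aliases = c(A_nidulans_FGSCA4 = "Anid"))
  expect_equal(nrow(og), 0L)
  expect_identical(names(og), c("og_id", "species", "gene_id"))

  path2 <- write_og_tsv(c("Orthogroup\tA_nidulans_FGSCA4", "OG1\tAN1"))
  og2 <- read_orthogroups(path2, aliases = c(A_nidulans_FGSCA4 = "Anid"))
  expect_equal(og2$species, "Anid")
})

test_that("a gene repeated across orthogroups is a hard error naming it", {
  path <- write_og_tsv(c("Orthogroup\tA\tB",
                         "OG1\ta1\tb1",
                         "OG2\ta1\t"))
  expect_error(read_orthogroups(path), "a1")
})

test_that("genes absent from the inventory warn by default and can error", {
  path <- write_og_tsv(c("Orthogroup\tA", "OG1\ta1, a9"))
  inv <- build_inventory(list(A = "a1"))
  expect_warning(og <- read_orthogroups(path, inventory = inv), "absent")
  expect_equal(nrow(og), 2L)  # warn-and-keep
  expect_error(read_orthogroups(path, inventory = inv, on_missing = "error"),
               "absent")
})

test_that("summarize_genomes matches hand counts on a 2-species example", {
  inv <- build_inventory(list(A = paste0("g", 1:4), B = paste0("h", 1:3)))
  og <- build_og(list(OG1 = list(A = "g1", B = "h1"),
                      OG2 = list(A = c("g2", "g3"))))
  s <- summarize_genomes(og, inv)
  expect_equal(s$global$n_orthogroups, 2L)
  expect_equal(s$global$n_species_specific_ogs, 1L)
  a <- s$per_species[s$per_species$species == "A", ]
  b <- s$per_species[s$per_species$species == "B", ]
  expect_equal(a$pct_in_orthogroups, 75.0)
  expect_equal(a$n_species_specific_ogs, 1L)
  expect_equal(b$pct_in_orthogroups, 33.3)
  expect_equal(b$n_species_specific_ogs, 0L)
  # OG2 holds 2 of 7 genes overall
  expect_equal(s$global$pct_genes_in_species_specific, round(100 * 2 / 7, 1))
})

test_that("a saturated 1:1 table gives 100% assignment and no species-specific groups", {
  inv <- build_inventory(list(A = c("a1", "a2"), B = c("b1", "b2")))
  og <- build_og(list(OG1 = list(A = "a1", B = "b1"),
                      OG2 = list(A = "a2", B = "b2")))
  s <- summarize_genomes(og, inv)
  expect_true(all(s$per_species$pct_in_orthogroups == 100.0))
  expect_equal(s$global$n_species_specific_ogs, 0L)
})

test_that("summarize_genomes rejects a species with zero genes", {
  inv <- build_inventory(list(A = "a1"))
  inv <- dplyr::bind_rows(inv, tibble::tibble(species = character(0),
                                              gene_id = character(0)))
  og <- build_og(list(OG1 = list(A = "a1", B = "zz")))
  expect_error(summarize_genomes(og, inv), "inventory")
})

test_that("summarize_genomes agrees with a brute-force recount on random tables", {
  withr::local_seed(42)
  for (i in 1:12) {
    inst <- random_og_instance(n_species = sample(2:4, 1), n_genes = 50)
    got <- summarize_genomes(inst$og, inst$inv)
    want <- summary_oracle(inst$og, inst$inv)
    expect_equal(as.data.frame(got$per_species), as.data.frame(want$per_species))
    expect_equal(got$global$n_orthogroups, want$n_orthogroups)
    expect_equal(got$global$n_species_specific_ogs, want$n_species_specific_ogs)
    expect_equal(got$global$pct_genes_in_species_specific,
                 want$pct_genes_in_species_specific)
  }
})

test_that("partition property: member total equals distinct assigned genes", {
  withr::local_seed(7)
  for (i in 1:8) {
    inst <- random_og_instance()
    expect_equal(nrow(inst$og),
                 nrow(dplyr::distinct(inst$og, species, gene_id)))
  }
})

test_that("og_size_by_species totals per-species counts", {
  og <- build_og(list(OG1 = list(A = c("a1", "a2"), B = "b1"),
                      OG2 = list(B = "b2")))
  sz <- og_size_by_species(og, "OG1")
  expect_equal(sz$n_genes[sz$species == "A"], 2L)
  expect_equal(attr(sz, "total"), sum(sz$n_genes))
  expect_equal(attr(og_size_by_species(og, "OG2"), "total"), 1L)

  # the conserved NmrA-like orthogroup: per-species counts across the eight
  # genomes sum to 25
  counts <- c(Aacu = 4L, Afla = 4L, Afum = 2L, Anid = 2L,
              Anig = 2L, Asyd = 4L, Ater = 3L, Aver = 4L)
  og25 <- purrr::imap_dfr(counts, function(n, sp) {
    tibble::tibble(og_id = "OG_NMRA", species = sp,
                   gene_id = sprintf("%s_%d", sp, seq_len(n)))
  })
  sz25 <- og_size_by_species(og25, "OG_NMRA")
  expect_equal(unname(setNames(sz25$n_genes, sz25$species)[names(counts)]),
               unname(counts))
  expect_equal(attr(sz25, "total"), 25L)
})

test_that("read_gene_tree parses, validates and round-trips newick", {
  tr <- read_gene_tree("((a1,b1),(a2,b2));")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("a1", "a2", "b1", "b2"))
  expect_equal(length(read_gene_tree("(a1);")$tip.label), 1L)
  expect_error(read_gene_tree("((a1,b1,(a2);"), "malformed")
})

test_that("newick round-trip preserves topology (RF distance 0)", {
  skip_if_not_installed("phangorn")
  withr::local_seed(11)
  for (i in 1:6) {
    tr <- ape::rtree(10)
    back <- read_gene_tree(ape::write.tree(tr))
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(back)), 0)
  }
})

test_that("root_split_clusters partitions leaves by root child clades", {
  cl <- root_split_clusters(read_gene_tree("((a1,b1),(a2,b2));"))
  expect_setequal(cl$label, c("a1", "b1", "a2", "b2"))
  expect_equal(dplyr::n_distinct(cl$cluster), 2L)
  grp <- split(cl$label, cl$cluster)
  expect_true(setequal(grp[[1]], c("a1", "b1")) || setequal(grp[[1]], c("a2", "b2")))

  cl2 <- root_split_clusters(read_gene_tree("((a1,b1),c1);"))
  expect_equal(sort(table(cl2$cluster), decreasing = TRUE)[[1]], 2L)
  expect_true(all(cl2$cluster[cl2$label %in% c("a1", "b1")] ==
                    cl2$cluster[cl2$label == "a1"]))

  # caterpillar: deepest split isolates the last-added leaf
  cl3 <- root_split_clusters(read_gene_tree("((((a,b),c),d),e);"))
  grp3 <- split(cl3$label, cl3$cluster)
  sizes <- sort(lengths(grp3))
  expect_equal(unname(sizes), c(1L, 4L))
  expect_equal(grp3[[which(lengths(grp3) == 1L)]], "e")
})

test_that("same_root_clade follows the root split", {
  tr <- read_gene_tree("((a1,b1),(a2,b2));")
  expect_true(same_root_clade(tr, "a1", "b1"))
  expect_false(same_root_clade(tr, "a1", "a2"))
  expect_error(same_root_clade(tr, "a1", "zz"), "zz")
  expect_error(root_split_clusters(read_gene_tree("(a1);")), "2 leaves")
})

test_that("split_gene_labels decodes species|gene labels", {
  got <- split_gene_labels(c("Anid|AN9181", "plain"))
  expect_equal(got$species, c("Anid", NA))
  expect_equal(got$gene_id, c("AN9181", "plain"))
})
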