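test_that("the neutral limit yields one 1:1 orthogroup per root family", {
  fam <- simulate_gene_families(50, dup_rate = 0, loss_rate = 0, gain_rate = 0,
                                seed = 3)
  expect_equal(dplyr::n_distinct(fam$orthogroups$og_id), 50L)
  sizes <- dplyr::count(fam$orthogroups, og_id, species)
  expect_true(all(sizes$n == 1L))
  per_og <- dplyr::count(fam$orthogroups, og_id)
  expect_true(all(per_og$n == 8L))
  s <- summarize_genomes(fam$orthogroups, fam$inventory)
  expect_true(all(s$per_species$pct_in_orthogroups == 100.0))
  expect_equal(s$global$n_species_specific_ogs, 0L)
})

test_that("families gained on terminal branches are species-specific", {
  fam <- simulate_gene_families(0, dup_rate = 0, loss_rate = 0, gain_rate = 3,
                                seed = 9)
  tree <- default_species_tree()
  ntip <- length(tree$tip.label)
  terminal_nodes <- seq_len(ntip)
  gained_terminal <- fam$events$og_id[!is.na(fam$events$og_id) &
                                        fam$events$origin_node %in% terminal_nodes]
  sp_per_og <- fam$orthogroups |>
    dplyr::group_by(og_id) |>
    dplyr::summarise(n_sp = dplyr::n_distinct(species))
  expect_gt(length(gained_terminal), 0L)
  expect_true(all(sp_per_og$n_sp[sp_per_og$og_id %in% gained_terminal] == 1L))
})

test_that("loss-only survival matches the closed-form per-branch product", {
  mu <- 0.6
  tree <- default_species_tree()
  # expected species presence per root family: sum over tips of the product
  # of exp(-mu * t) along the root-to-tip path
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  expected <- sum(exp(-mu * depths[seq_len(ntip)]))
  fam <- simulate_gene_families(500, dup_rate = 0, loss_rate = mu,
                                gain_rate = 0, seed = 5)
  # count species presence over all 500 root families, extinct ones included
  presence <- fam$orthogroups |>
    dplyr::distinct(og_id, species) |>
    nrow()
  mean_presence <- presence / 500
  # tips are independent only approximately (shared internal branches), so a
  # conservative binomial-style bound on the SE of the per-family species count
  se <- sqrt(expected * (1 - expected / ntip) / 500)
  expect_lt(abs(mean_presence - expected), 3 * max(se, 0.05))
})

test_that("simulators are byte-identical under a fixed seed and leave the RNG alone", {
  a <- simulate_cocoa_bundle(n_root_families = 100, seed = 42)
  set.seed(1); before <- runif(1)
  b <- simulate_cocoa_bundle(n_root_families = 100, seed = 42)
  expect_identical(a$orthogroups, b$orthogroups)
  expect_identical(a$deg_tables, b$deg_tables)
  expect_identical(a$annotation, b$annotation)
  c <- simulate_cocoa_bundle(n_root_families = 100, seed = 43)
  expect_false(identical(a$deg_tables, c$deg_tables))
  set.seed(1)
  expect_identical(runif(1), before)  # local_seed restored the outer state
})

test_that("every simulated table satisfies the one-orthogroup-per-gene partition", {
  for (sd in c(2, 4, 6)) {
    fam <- simulate_gene_families(200, seed = sd)
    expect_silent(cocoar:::validate_orthogroups(fam$orthogroups))
    expect_equal(nrow(fam$orthogroups), nrow(fam$inventory))
    expect_setequal(fam$orthogroups$gene_id, fam$inventory$gene_id)
  }
})

test_that("planted orthogroups respond in every dataset; p=0 gives a clean intersection", {
  fam <- simulate_gene_families(150, seed = 12)
  design <- default_dataset_design(p = 0)
  cover <- fam$orthogroups |>
    dplyr::group_by(og_id) |>
    dplyr::summarise(ok = all(c("Anid", "Afla", "Afum") %in% species)) |>
    dplyr::filter(ok)
  planted <- cover$og_id[1]
  sim <- simulate_deg_datasets(fam$orthogroups, fam$inventory, design,
                               planted = planted, seed = 4)
  res <- run_cocoa(design, fam$orthogroups, fam$inventory, receiver = "Anid",
                   deg_tables = sim$deg_tables, min_datasets = 5)
  expect_setequal(res$report$gene_id, sim$truth$planted_receiver_genes)
})

test_that("p=1 saturates: the intersection is every receiver gene reachable from all datasets", {
  fam <- simulate_gene_families(40, dup_rate = 0, loss_rate = 0, gain_rate = 0,
                                seed = 2)
  design <- default_dataset_design(p = 1)
  sim <- simulate_deg_datasets(fam$orthogroups, fam$inventory, design, seed = 4)
  res <- run_cocoa(design, fam$orthogroups, fam$inventory, receiver = "Anid",
                   deg_tables = sim$deg_tables, min_datasets = 5)
  # 1:1 orthology, every gene responds in every dataset -> all receiver genes
  receiver_genes <- fam$inventory$gene_id[fam$inventory$species == "Anid"]
  expect_setequal(res$report$gene_id, receiver_genes)
})

test_that("a planted orthogroup missing a dataset species errors before sampling", {
  og <- build_og(list(OG1 = list(Anid = "AN00001", Afum = "Afum00001")))
  inv <- build_inventory(list(Anid = "AN00001", Afum = "Afum00001",
                              Afla = "Afla00001"))
  expect_error(
    simulate_deg_datasets(og, inv, default_dataset_design(),
                          planted = "OG1", seed = 1),
    "no member in species: Afla")
  expect_error(
    simulate_deg_datasets(og, inv, default_dataset_design(),
                          planted = "OG_NOPE", seed = 1),
    "not found")
})

test_that("domain simulation follows its Poisson mean and vocabulary", {
  inv <- build_inventory(list(A = sprintf("a%02d", 1:10)))
  expect_equal(nrow(simulate_domain_annotation(inv, "IPR000001",
                                               hits_per_gene = 0, seed = 1)), 0L)
  one <- simulate_domain_annotation(inv, "IPR000001", hits_per_gene = 5, seed = 1)
  expect_true(all(one$interpro_acc == "IPR000001"))
  expect_lte(max(table(one$gene_id)), 1L)  # without replacement, vocab of 1

  vocab <- sprintf("IPR%06d", 1:100)
  totals <- purrr::map_int(1:30, function(sd) {
    nrow(simulate_domain_annotation(inv, vocab, hits_per_gene = 2, seed = sd))
  })
  # 10 genes x mean 2: mean total 20, se sqrt(20)/sqrt(30)
  expect_lt(abs(mean(totals) - 20), 3 * sqrt(20 / 30))
  expect_error(simulate_domain_annotation(inv, character(0), 2, 1), "non-empty")
  expect_error(simulate_domain_annotation(inv, vocab, -1, 1), ">= 0")
})

test_that("write_cocoa_bundle emits files the readers parse back", {
  b <- simulate_cocoa_bundle(n_root_families = 60, seed = 14)
  dir <- withr::local_tempdir()
  write_cocoa_bundle(b, dir)
  og <- read_orthogroups(file.path(dir, "orthogroups.tsv"))
  expect_setequal(og$gene_id, b$orthogroups$gene_id)
  inv <- read_inventory(file.path(dir, "inventory.tsv"))
  expect_equal(nrow(inv), nrow(b$inventory))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(truth$planted, b$planted)
})
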