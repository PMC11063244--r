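# Synthetic data with known ground truth: orthogroup tables produced by a
# gene-family birth-death process on a species tree, differential-expression
# tables with a planted conserved-responder orthogroup over independent
# background responders, and random domain annotations. Every generator is
# seed-reproducible and leaves the caller's RNG state untouched.

#' Default eight-taxon species tree
#'
#' An ultrametric eight-species tree with unit root-to-tip depth, shaped
#' like a typical *Aspergillus* phylogeny; the receiver species is coded
#' `Anid`.
#'
#' @return An [ape::phylo] tree with tip labels
#'   `Aacu, Afla, Afum, Anid, Anig, Asyd, Ater, Aver`.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((Anid:0.4,(Aver:0.2,Asyd:0.2):0.2):0.3,(Afum:0.35,Ater:0.35):0.35):0.3,",
    "((Anig:0.3,Aacu:0.3):0.4,Afla:0.7):0.3);"))
}

#' Simulate orthogroups by gene-family birth-death on a species tree
#'
#' Each of `n_root_families` families starts as a single gene at the root.
#' Along a branch of length `t`, every gene survives with probability
#' `exp(-loss_rate * t)` and each survivor accrues
#' `Poisson(dup_rate * t)` duplicate copies; new families arise along each
#' branch as `Poisson(gain_rate * t)` and start with one gene at the
#' branch's lower end. Every surviving gene at the tips belongs to exactly
#' one orthogroup: the clan of its founding family. A family gained on a
#' terminal branch therefore yields a species-specific orthogroup.
#'
#' @param n_root_families Number of families present at the root.
#' @param tree Species tree with branch lengths
#'   (default [default_species_tree()]).
#' @param dup_rate,loss_rate,gain_rate Events per gene (families for gain)
#'   per unit branch length; all >= 0.
#' @param receiver Species whose gene ids get the `AN`-style prefix
#'   (default `"Anid"`).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return List with `orthogroups` (long tibble `og_id`, `species`,
#'   `gene_id`), `inventory` (tibble `species`, `gene_id`), and `events`
#'   (per-family log: `family`, `origin_node`, per-tip gene counts).
#' @export
simulate_gene_families <- function(n_root_families, tree = default_species_tree(),
                                   dup_rate = 0.05, loss_rate = 0.05,
                                   gain_rate = 0.02, receiver = "Anid",
                                   seed = 1L) {
  stopifnot(n_root_families >= 0, dup_rate >= 0, loss_rate >= 0, gain_rate >= 0)
  if (is.null(tree$edge.length)) abort("species tree must have branch lengths")
  withr::local_seed(seed)

  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  edges <- tree$edge
  elen <- tree$edge.length

  # gained families: decide counts per edge first so the count matrix can be
  # allocated once; a gained family enters at the child node of its edge
  gains_per_edge <- rpois(nrow(edges), gain_rate * elen)
  n_fam <- n_root_families + sum(gains_per_edge)
  if (n_fam == 0L) {
    return(list(orthogroups = tibble(og_id = character(0), species = character(0),
                                     gene_id = character(0)),
                inventory = tibble(species = character(0), gene_id = character(0)),
                events = tibble(family = integer(0), origin_node = integer(0))))
  }
  cnt <- matrix(0L, nrow = n_fam, ncol = nnode)
  origin <- integer(n_fam)
  if (n_root_families > 0L) {
    cnt[seq_len(n_root_families), root] <- 1L
    origin[seq_len(n_root_families)] <- root
  }
  nxt <- n_root_families
  gain_ids <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    g <- gains_per_edge[e]
    if (g > 0L) {
      ids <- nxt + seq_len(g)
      cnt[ids, edges[e, 2]] <- 1L
      origin[ids] <- edges[e, 2]
      nxt <- nxt + g
    }
  }

  p_surv <- exp(-loss_rate * elen)
  for (e in seq_len(nrow(edges))) {
    n_par <- cnt[, edges[e, 1]]
    surv <- rbinom(n_fam, n_par, p_surv[e])
    dups <- rpois(n_fam, dup_rate * elen[e] * surv)
    cnt[, edges[e, 2]] <- cnt[, edges[e, 2]] + surv + dups
  }

  tip_counts <- cnt[, seq_len(ntip), drop = FALSE]
  colnames(tip_counts) <- tree$tip.label
  alive <- rowSums(tip_counts) > 0L

  # gene ids: per-species running counter, receiver gets the AN-style prefix
  long <- purrr::map_dfr(seq_len(ntip), function(ti) {
    sp <- tree$tip.label[ti]
    fams <- which(tip_counts[, ti] > 0L)
    if (length(fams) == 0L) return(NULL)
    n <- tip_counts[fams, ti]
    idx <- seq_len(sum(n))
    prefix <- if (identical(sp, receiver)) "AN" else sp
    tibble(family = rep(fams, n), species = sp,
           gene_id = sprintf("%s%05d", prefix, idx))
  })
  og_ids <- sprintf("OG%06d", cumsum(alive))  # ids only for surviving families
  long <- long |>
    mutate(og_id = og_ids[.data$family]) |>
    arrange(.data$og_id, .data$species, .data$gene_id)

  events <- as_tibble(tip_counts) |>
    mutate(family = dplyr::row_number(), origin_node = origin,
           og_id = ifelse(alive, og_ids, NA_character_)) |>
    dplyr::select("family", "og_id", "origin_node", dplyr::everything())

  list(orthogroups = dplyr::select(long, "og_id", "species", "gene_id"),
       inventory = long |> dplyr::select("species", "gene_id") |>
         arrange(.data$species, .data$gene_id),
       events = events)
}

#' Simulate per-dataset differential-expression tables
#'
#' Every member of a planted orthogroup in a dataset's species draws from
#' the responder model — `log2fc ~ Uniform(1.5, 4)`,
#' `padj ~ Uniform(1e-6, 1e-3)` — and therefore passes the standard
#' up-regulation filter with certainty. Every other gene of that species is
#' independently a background responder with the dataset's probability
#' `p`; non-responders draw `log2fc ~ Normal(0, 0.3)` and
#' `padj ~ Uniform(0.05, 1)`, which the filter always rejects.
#'
#' @param orthogroups,inventory As produced by [simulate_gene_families()].
#' @param datasets Tibble with columns `label`, `species`, `p` (background
#'   responder probability in `[0, 1]`).
#' @param planted Character vector of orthogroup ids forced up-regulated in
#'   every dataset. Each must have at least one member in every dataset
#'   species and at least one member in the receiver species (checked
#'   before any sampling).
#' @param receiver Receiver species code used for the coverage check.
#' @param seed Integer seed.
#' @return List with `deg_tables` (named list of tibbles `gene`,
#'   `log2FoldChange`, `padj` — valid [read_deg_table()] shape) and `truth`
#'   (list: `responders` per dataset, `planted_genes` per species,
#'   `planted_receiver_genes`).
#' @export
simulate_deg_datasets <- function(orthogroups, inventory, datasets,
                                  planted = character(0), receiver = "Anid",
                                  seed = 1L) {
  stopifnot(all(c("label", "species", "p") %in% names(datasets)))
  if (anyDuplicated(datasets$label)) abort("duplicate dataset labels")
  stopifnot(all(datasets$p >= 0 & datasets$p <= 1))
  need_species <- union(unique(datasets$species), receiver)
  for (og in planted) {
    memb <- orthogroups |> filter(.data$og_id == og)
    if (nrow(memb) == 0L) abort(sprintf("planted orthogroup '%s' not found", og))
    gap <- setdiff(need_species, unique(memb$species))
    if (length(gap) > 0L) {
      abort(sprintf("planted orthogroup '%s' has no member in species: %s",
                    og, paste(gap, collapse = ", ")))
    }
  }
  withr::local_seed(seed)
  planted_members <- orthogroups |> filter(.data$og_id %in% planted)

  deg_tables <- vector("list", nrow(datasets))
  responders <- vector("list", nrow(datasets))
  for (i in seq_len(nrow(datasets))) {
    sp <- datasets$species[i]
    genes <- inventory |> filter(.data$species == sp) |> pull(.data$gene_id)
    is_planted <- genes %in% planted_members$gene_id[planted_members$species == sp]
    is_responder <- is_planted | runif(length(genes)) < datasets$p[i]
    n_resp <- sum(is_responder)
    log2fc <- rnorm(length(genes), 0, 0.3)
    padj <- runif(length(genes), 0.05, 1)
    log2fc[is_responder] <- runif(n_resp, 1.5, 4)
    padj[is_responder] <- runif(n_resp, 1e-6, 1e-3)
    deg_tables[[i]] <- tibble(gene = genes, log2FoldChange = log2fc, padj = padj)
    responders[[i]] <- sort(genes[is_responder])
  }
  names(deg_tables) <- datasets$label
  names(responders) <- datasets$label
  list(deg_tables = deg_tables,
       truth = list(
         responders = responders,
         planted_genes = split(planted_members$gene_id, planted_members$species),
         planted_receiver_genes =
           sort(planted_members$gene_id[planted_members$species == receiver])))
}

#' Simulate a random domain annotation
#'
#' Each gene receives `Poisson(hits_per_gene)` domain hits (capped at the
#' vocabulary size), drawn without replacement from the accession
#' vocabulary.
#'
#' @param inventory Inventory tibble (`species`, `gene_id`).
#' @param vocabulary Non-empty character vector of InterPro-style accessions.
#' @param hits_per_gene Poisson mean number of hits per gene; must be >= 0.
#' @param seed Integer seed.
#' @return Domain annotation tibble (same shape as
#'   [read_interproscan_tsv()]); descriptions are synthetic placeholders.
#' @export
simulate_domain_annotation <- function(inventory, vocabulary, hits_per_gene = 2,
                                       seed = 1L) {
  if (length(vocabulary) == 0L) abort("vocabulary must be non-empty")
  if (hits_per_gene < 0) abort("hits_per_gene must be >= 0")
  withr::local_seed(seed)
  genes <- inventory$gene_id
  n_hits <- pmin(rpois(length(genes), hits_per_gene), length(vocabulary))
  keep <- n_hits > 0L
  if (!any(keep)) return(empty_annotation())
  tibble(gene_id = rep(genes[keep], n_hits[keep]),
         interpro_acc = unlist(purrr::map(n_hits[keep],
                                          ~ sample(vocabulary, .x, replace = FALSE)))) |>
    mutate(signature_db = "SYNTH", signature_acc = .data$interpro_acc,
           description = paste("synthetic domain", .data$interpro_acc)) |>
    dplyr::select("gene_id", "signature_db", "signature_acc",
                  "interpro_acc", "description")
}

#' Default dataset design of the synthetic study
#'
#' Five datasets across three species (one in the receiver, one in a close
#' relative, three in a third species), each with background responder
#' probability `p`.
#'
#' @param p Background responder probability shared by all datasets.
#' @return Tibble with columns `label`, `species`, `p`.
#' @export
default_dataset_design <- function(p = 0.05) {
  tibble(label = c("Sal", "RVT", "BaP", "BMQ", "IDQ"),
         species = c("Anid", "Afla", "Afum", "Afum", "Afum"),
         p = p)
}

#' Simulate a complete analysis bundle
#'
#' Runs the family, differential-expression and domain simulators with
#' sub-seeds derived from one master seed, planting one conserved-responder
#' orthogroup (the smallest orthogroup covering every dataset species and
#' the receiver, ties broken by id) unless told otherwise.
#'
#' @param n_root_families Families at the root (default 2000).
#' @param tree Species tree (default [default_species_tree()]).
#' @param dup_rate,loss_rate,gain_rate Birth-death rates (defaults 0.05,
#'   0.05, 0.02).
#' @param datasets Dataset design tibble (default [default_dataset_design()]).
#' @param n_planted Number of planted orthogroups (default 1).
#' @param receiver Receiver species code.
#' @param vocabulary Domain accession vocabulary (default 50 synthetic
#'   accessions).
#' @param hits_per_gene Poisson mean domain hits per gene.
#' @param seed Master seed (sub-seeds are `seed`, `seed + 1`, `seed + 2`).
#' @return List with `orthogroups`, `inventory`, `events`, `datasets`,
#'   `deg_tables`, `truth`, `annotation`, `planted`.
#' @export
simulate_cocoa_bundle <- function(n_root_families = 2000,
                                  tree = default_species_tree(),
                                  dup_rate = 0.05, loss_rate = 0.05,
                                  gain_rate = 0.02,
                                  datasets = default_dataset_design(),
                                  n_planted = 1, receiver = "Anid",
                                  vocabulary = sprintf("IPR%06d", 1:50),
                                  hits_per_gene = 2, seed = 1L) {
  stopifnot(seed + 2 < 2^31)
  fam <- simulate_gene_families(n_root_families, tree = tree,
                                dup_rate = dup_rate, loss_rate = loss_rate,
                                gain_rate = gain_rate, receiver = receiver,
                                seed = seed)
  need_species <- union(unique(datasets$species), receiver)
  cover <- fam$orthogroups |>
    group_by(.data$og_id) |>
    summarise(covered = all(need_species %in% .data$species),
              size = dplyr::n(), .groups = "drop") |>
    filter(.data$covered) |>
    arrange(.data$size, .data$og_id)
  if (nrow(cover) < n_planted) {
    abort("no simulated orthogroup covers every dataset species; increase n_root_families or lower loss_rate")
  }
  planted <- head(cover$og_id, n_planted)
  degs <- simulate_deg_datasets(fam$orthogroups, fam$inventory, datasets,
                                planted = planted, receiver = receiver,
                                seed = seed + 1L)
  ann <- simulate_domain_annotation(fam$inventory, vocabulary, hits_per_gene,
                                    seed = seed + 2L)
  list(orthogroups = fam$orthogroups, inventory = fam$inventory,
       events = fam$events, datasets = datasets, deg_tables = degs$deg_tables,
       truth = degs$truth, annotation = ann, planted = planted)
}

#' Write a simulated bundle to disk
#'
#' Emits the orthogroup table in the OrthoFinder-style wide TSV dialect, a
#' two-column inventory TSV, one DEG CSV per dataset, a compact domain map
#' TSV and a ground-truth JSON — the same formats the readers consume.
#'
#' @param bundle A list from [simulate_cocoa_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; files: `orthogroups.tsv`, `inventory.tsv`,
#'   `deg_<label>.csv`, `domains.tsv`, `truth.json`, `manifest.yaml`.
#' @export
write_cocoa_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wide <- bundle$orthogroups |>
    group_by(.data$og_id, .data$species) |>
    summarise(members = paste(.data$gene_id, collapse = ", "), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species", values_from = "members",
                       values_fill = "") |>
    rename(Orthogroup = "og_id") |>
    arrange(.data$Orthogroup)
  readr::write_tsv(wide, file.path(dir, "orthogroups.tsv"))
  readr::write_tsv(bundle$inventory, file.path(dir, "inventory.tsv"))
  for (lab in names(bundle$deg_tables)) {
    readr::write_csv(bundle$deg_tables[[lab]],
                     file.path(dir, sprintf("deg_%s.csv", lab)))
  }
  write_domain_map(bundle$annotation, file.path(dir, "domains.tsv"))
  jsonlite::write_json(list(planted = bundle$planted,
                            planted_receiver_genes =
                              bundle$truth$planted_receiver_genes,
                            responders = bundle$truth$responders),
                       file.path(dir, "truth.json"), auto_unbox = FALSE,
                       pretty = TRUE)
  manifest <- purrr::pmap(bundle$datasets, function(label, species, p) {
    list(label = label, species = species,
         path = sprintf("deg_%s.csv", label))
  })
  yaml::write_yaml(list(datasets = manifest), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
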