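test_that("generator config validates its fields", {
  expect_error(generator_config("suite1", seed = NULL), "seed")
  expect_error(generator_config("suite1", scale = 0, seed = 1), "scale")
  expect_error(generator_config("suite1", seed = 1, nonsense = 2), "unknown")
  expect_error(generator_config("suite1", seed = 1,
                                loss_prob = c(Mus_musculus = 1.2)),
               "loss probabilities")
  cfg <- generator_config("suite1", scale = 0.5, seed = 1)
  expect_equal(cfg$n_families, round(10441 * 0.5))
})

test_that("profile simulation is seed-deterministic and anchored", {
  cfg <- generator_config("suite1", scale = 0.05, seed = 19)
  s1 <- simulate_profiles(cfg)
  s2 <- simulate_profiles(cfg)
  expect_identical(s1$profiles$counts, s2$profiles$counts)
  expect_identical(s1$truth, s2$truth)
  expect_true(all(s1$profiles$counts[, "Homo_sapiens"] >= 1))
  expect_setequal(colnames(s1$profiles$counts), suite1_tree()$tip.label)
})

test_that("an infeasible anchor path is rejected", {
  lp <- orthotrace:::suite1_loss_probs()
  lp["Mammalia"] <- 1
  cfg <- generator_config("suite1", scale = 0.02, seed = 3, loss_prob = lp)
  expect_error(simulate_profiles(cfg), "anchor path")
})

test_that("no loss and no duplication give full single-copy clades", {
  cfg <- generator_config("suite1", scale = 0.03, seed = 23,
                          loss_prob = setNames(numeric(0), character(0)),
                          dup_prob = 0)
  sim <- simulate_profiles(cfg)
  tr <- suite1_tree()
  expect_true(all(sim$profiles$counts %in% c(0L, 1L)))
  for (f in sample(nrow(sim$profiles$counts), 25)) {
    below <- clade_tips(tr, sim$truth$gain[f])
    expect_equal(sort(names(which(sim$profiles$counts[f, ] == 1L))),
                 sort(below))
  }
  expect_true(all(sim$truth$losses == ""))
})

test_that("Dollo recovers the true gain when survivors span its children", {
  cfg <- generator_config("suite1", scale = 0.05, seed = 29)
  sim <- simulate_profiles(cfg)
  tr <- suite1_tree()
  idx <- orthotrace:::tree_index(tr)
  pres <- sim$profiles$counts[, tr$tip.label] >= 1
  rec <- orthotrace:::dollo_core(pres, idx)
  true_gain <- match(sim$truth$gain, idx$labels)
  # families whose surviving leaves span >= 2 children of the true gain
  spans <- vapply(seq_len(nrow(pres)), function(f) {
    kids <- idx$children[[true_gain[f]]]
    if (length(kids) == 0) return(TRUE)
    sum(vapply(kids, function(k) any(pres[f, ] & idx$clade[k, seq_len(idx$ntip)]),
               logical(1))) >= 2
  }, logical(1))
  expect_gt(mean(spans), 0.4)   # the regime is non-trivially populated
  expect_true(all(rec$gain[spans] == true_gain[spans]))
  # recovered gains are never deeper than the truth
  expect_true(all(idx$depth[rec$gain] >= idx$depth[true_gain]))
})

test_that("disease families originate deeper than non-disease families", {
  cfg <- generator_config("suite1", scale = 0.2, seed = 31)
  sim <- simulate_profiles(cfg)
  root_frac <- function(cl)
    mean(sim$truth$gain[sim$truth$class == cl] == "Bilateria")
  expect_gt(root_frac("disease"), root_frac("non_disease"))
})

test_that("pathway records obey the reaction conservation rule", {
  cfg <- generator_config("suite2", scale = 0.1, seed = 37)
  pw <- simulate_pathways(cfg)
  rec <- pw$records
  pres <- pw$sim$profiles$counts >= 1
  sp <- setdiff(colnames(pres), "Homo_sapiens")
  # spot check the rule: a reaction is conserved iff >= 1 member survives
  for (i in sample(nrow(rec), 10)) {
    fams <- pw$truth$members[[i]]
    for (s in sp[1:2]) {
      expect_equal(rec[[paste0(s, ":genes")]][i],
                   sum(pres[fams, s]))
      rx_ok <- vapply(pw$truth$reactions[[i]], function(r)
        any(pres[fams[r], s]), logical(1))
      expect_equal(rec[[paste0(s, ":reactions")]][i], sum(rx_ok))
    }
  }
  # cohort-level: reactions at least as conserved as genes, every species
  for (s in sp) {
    expect_gte(mean(conservation_percent(rec, s, "reactions")),
               mean(conservation_percent(rec, s, "genes")))
  }
})

test_that("fully conserved profiles give fully conserved pathways", {
  cfg <- generator_config("suite2", scale = 0.02, seed = 41,
                          loss_prob = setNames(numeric(0), character(0)),
                          dup_prob = 0,
                          origin_probs = list(
                            disease = c(Bilateria = 1),
                            non_disease = c(Bilateria = 1),
                            mixed = c(Bilateria = 1)))
  pw <- simulate_pathways(cfg)
  sp <- setdiff(colnames(pw$sim$profiles$counts), "Homo_sapiens")
  for (s in sp) {
    expect_true(all(conservation_percent(pw$records, s, "genes") == 100))
    expect_true(all(conservation_percent(pw$records, s, "reactions") == 100))
  }
})

test_that("gene sets carry their intended conservation bias", {
  cfg <- generator_config("suite1", scale = 0.1, seed = 43,
                          n_sets = c(conserved = 6, recent = 4, neutral = 5))
  sim <- simulate_profiles(cfg)
  gs <- simulate_gene_sets(cfg, sim)
  expect_equal(nrow(gs$truth), 15)
  H <- shannon_index(sim$profiles$counts)
  qs <- quantile(H, c(0.25, 0.75))
  for (k in seq_along(gs$genesets)) {
    fams <- unique(gs$gene_to_family[gs$genesets[[k]]])
    bias <- gs$truth$bias[gs$truth$set == names(gs$genesets)[k]]
    if (bias == "conserved") expect_true(all(H[fams] >= qs[2]))
    if (bias == "recent") expect_true(all(H[fams] <= qs[1]))
  }
  expect_error(simulate_gene_sets(
    generator_config("suite1", scale = 0.1, seed = 43,
                     set_size_range = c(0L, 10L)), sim),
    "sizes")
})

test_that("generator outputs feed every reader (round trip through files)", {
  cfg <- generator_config("suite1", scale = 0.03, seed = 47)
  sim <- simulate_profiles(cfg)
  gs <- simulate_gene_sets(cfg, sim)
  d <- withr::local_tempdir()
  write_profile_matrix(sim$profiles, file.path(d, "profiles.tsv"))
  write_gmt(gs$genesets, file.path(d, "sets.gmt"))
  pm <- read_profile_matrix(file.path(d, "profiles.tsv"))
  sets <- read_gmt(file.path(d, "sets.gmt"))
  rk <- rank_families(pm)
  os <- to_ortholog_sets(sets, sim$gene_to_family)
  expect_gt(length(os), 0)
  es <- vapply(os, function(s) preranked_es(rk, s), numeric(1))
  expect_true(all(is.finite(es)))

  cfg2 <- generator_config("suite2", scale = 0.05, seed = 48)
  pw <- simulate_pathways(cfg2)
  write_pathway_table(pw$records, file.path(d, "pathways.tsv"))
  back <- read_pathway_table(file.path(d, "pathways.tsv"))
  expect_equal(nrow(back), nrow(pw$records))
})
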