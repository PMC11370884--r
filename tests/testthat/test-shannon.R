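test_that("Shannon index matches closed forms and conventions", {
  expect_equal(shannon_index(rep(1, 12)), log(12))
  expect_equal(shannon_index(c(0, 0, 7)), 0)
  expect_equal(shannon_index(c(2, 1, 1)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  # dropping zero-count species never changes the index
  expect_equal(shannon_index(c(3, 1, 0, 0, 2)), shannon_index(c(3, 1, 2)))
  # bounded by log(S), attained only at uniformity
  set.seed(51)
  for (i in 1:20) {
    x <- rpois(6, 2) + c(1, 0, 0, 0, 0, 0)
    expect_lte(shannon_index(x), log(sum(x > 0)) + 1e-12)
  }
  expect_error(shannon_index(c(0, 0)), "all-zero")
  expect_error(shannon_index(c(-1, 2)), "non-negative")
})

test_that("ranking is descending with deterministic id tie-breaks", {
  counts <- rbind(b_fam = c(1, 1, 1), a_fam = c(1, 1, 1), c_fam = c(4, 0, 0),
                  d_fam = c(2, 1, 0))
  colnames(counts) <- c("s1", "s2", "s3")
  rk <- rank_families(counts)
  expect_equal(rk$family_id, c("a_fam", "b_fam", "d_fam", "c_fam"))
  expect_true(all(diff(rk$score) <= 0))
  expect_equal(nrow(rk), 4)
})

test_that("Shannon scores track species breadth on generated data", {
  cfg <- generator_config("suite1", scale = 0.1, seed = 61)
  sp <- simulate_profiles(cfg)
  H <- shannon_index(sp$profiles$counts)
  breadth <- rowSums(sp$profiles$counts >= 1)
  expect_gt(cor(H, breadth, method = "spearman"), 0.9)
})

test_that("GMT round trip and ortholog-set conversion honour size bounds", {
  sets <- list(big = sprintf("g%03d", 1:40), tiny = c("g001", "g002"),
               dead = c("zz1", "zz2", "zz3"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f, description = c(big = "a", tiny = "b", dead = "c"))
  back <- read_gmt(f)
  expect_identical(back$big, sets$big)
  expect_equal(attr(back, "description")[["tiny"]], "b")

  g2f <- setNames(paste0("F", rep(1:20, each = 2)), sprintf("g%03d", 1:40))
  expect_warning(os <- to_ortholog_sets(back, g2f), "no mappable")
  expect_named(os, "big")
  expect_equal(sort(os$big), sort(paste0("F", 1:20)))   # unique entries
  drop <- attr(os, "dropped")
  expect_equal(unname(drop["tiny"]), "too_small")       # maps to one family
  expect_equal(unname(drop["dead"]), "unmapped")
  # a 501-family set is excluded at the default maximum
  wide <- list(w = paste0("h", 1:501))
  g2f2 <- setNames(paste0("W", 1:501), paste0("h", 1:501))
  expect_equal(length(to_ortholog_sets(wide, g2f2)), 0L)
  expect_equal(unname(attr(to_ortholog_sets(wide, g2f2), "dropped")["w"]),
               "too_large")
  expect_error(to_ortholog_sets(list(), g2f), "empty")
})

test_that("enrichment score equals a brute-force running sum on all subsets", {
  brute_es <- function(scores, set, p = 1) {
    hit <- names(scores) %in% set
    w <- abs(scores)^p
    inc <- if (sum(w[hit]) > 0) w * hit / sum(w[hit])
           else hit / sum(hit)
    dec <- (!hit) / sum(!hit)
    run <- cumsum(inc - dec)
    hi <- max(c(0, run))
    lo <- min(c(0, run))
    # equal-magnitude extrema resolve to the positive side, the package's
    # documented tie convention
    unname(if (hi >= -lo) hi else lo)
  }
  scores <- setNames(c(5, 4, 3, 2, 1, 0.5), paste0("f", 1:6))
  # every non-empty proper subset of a 6-element list
  ids <- names(scores)
  for (code in 1:(2^6 - 2)) {
    set <- ids[as.logical(bitwAnd(code, 2^(0:5)))]
    expect_equal(preranked_es(scores, set), brute_es(scores, set),
                 info = paste(set, collapse = ","))
  }
  # spec'd hand case: the two top-ranked of six
  expect_equal(preranked_es(scores, c("f1", "f2")),
               brute_es(scores, c("f1", "f2")))
  # full universe and single top hit give ES = 1
  expect_equal(preranked_es(scores, ids), 1)
  expect_equal(preranked_es(scores, "f1"), 1)
  expect_error(preranked_es(scores, c("f1", "nope")), "missing")
})

test_that("enrichment score agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(71)
  scores <- sort(rexp(100), decreasing = TRUE)
  names(scores) <- sprintf("f%03d", 1:100)
  for (k in c(3, 10, 25)) {
    set <- sample(names(scores), k)
    mine <- preranked_es(scores, set)
    ref <- fgsea::calcGseaStat(scores, selectedStats = sort(match(set, names(scores))),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("permutation statistics are seed-deterministic and sane", {
  set.seed(81)
  scores <- sort(rexp(300), decreasing = TRUE)
  names(scores) <- sprintf("f%03d", 1:300)
  sets <- list(top = names(scores)[1:15],
               rand = sample(names(scores), 15))
  r1 <- permutation_stats(scores, sets, n_perm = 200, seed = 4)
  r2 <- permutation_stats(scores, sets, n_perm = 200, seed = 4)
  expect_identical(r1, r2)
  expect_true(all(abs(r1$ES) <= 1))
  expect_true(all(r1$p >= 0 & r1$p <= 1))
  expect_true(all(r1$q >= 0 & r1$q <= 1))
  # a maximally enriched set beats every permutation
  expect_lte(r1$p[r1$set == "top"], 1 / 201)
  expect_gt(r1$NES[r1$set == "top"], 1)
  expect_warning(
    permutation_stats(scores, list(huge = names(scores)[1:200]),
                      n_perm = 100, seed = 1),
    "half the universe")
  expect_error(permutation_stats(scores, sets, n_perm = 50, seed = 1),
               "n_perm")
})

test_that("random panel experiment separates a conserved panel from the universe", {
  cfg <- generator_config("suite1", scale = 0.1, seed = 91)
  sim <- simulate_profiles(cfg)
  rk <- rank_families(sim$profiles)
  H <- shannon_index(sim$profiles$counts)
  top_fams <- names(sort(H, decreasing = TRUE))[1:200]
  panel <- unlist(sim$family_genes[top_fams], use.names = FALSE)
  universe <- names(sim$gene_to_family)
  res <- random_panel_experiment(panel, universe, sim$gene_to_family, rk,
                                 n_sets = 12, set_size = 40, n_perm = 200,
                                 seed = 17)
  expect_gt(res$frac_panel, res$frac_universe)
  expect_gte(res$frac_panel, 0.8)
  # identical frames behave alike; empty request returns empty
  same <- random_panel_experiment(universe, universe, sim$gene_to_family, rk,
                                  n_sets = 6, set_size = 40, n_perm = 200,
                                  seed = 18)
  expect_lt(abs(same$frac_panel - same$frac_universe), 0.5)
  none <- random_panel_experiment(panel, universe, sim$gene_to_family, rk,
                                  n_sets = 0, set_size = 10, n_perm = 200,
                                  seed = 19)
  expect_length(none$panel_p, 0)
  expect_error(random_panel_experiment(panel, universe, sim$gene_to_family,
                                       rk, set_size = length(panel) + 1,
                                       n_perm = 200, seed = 1),
               "exceeds the panel")
  expect_error(random_panel_experiment(c(panel, "alien"), universe,
                                       sim$gene_to_family, rk, n_perm = 200,
                                       seed = 1),
               "subset")
})
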