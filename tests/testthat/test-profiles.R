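make_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("profile TSV reading validates and preserves order", {
  f <- make_tsv(c("family_id\tclass\tA\tB",
                  "F2\tdisease\t1\t0",
                  "F1\tnon_disease\t2\t3",
                  "F3\tmixed\t0\t1"))
  pm <- read_profile_matrix(f)
  expect_equal(family_ids(pm), c("F2", "F1", "F3"))
  expect_equal(unname(pm$counts["F1", ]), c(2L, 3L))
  expect_equal(unname(pm$class["F3"]), "mixed")

  expect_error(read_profile_matrix(make_tsv(
    c("family_id\tclass\tA", "F1\tdisease\t-1")), anchor = NULL),
    "row 1")
  expect_error(read_profile_matrix(make_tsv(
    c("family_id\tclass\tA", "F1\tdisease\t1.5")), anchor = NULL),
    "non-integer")
  expect_error(read_profile_matrix(make_tsv(
    c("family_id\tclass\tA", "F1\tdisease\t1", "F1\tdisease\t2"))),
    "duplicate family_id")
  expect_error(read_profile_matrix(make_tsv("family_id\tclass\tA")),
               "no data rows")
})

test_that("write/read round trip is lossless", {
  cfg <- generator_config("suite1", scale = 0.02, seed = 3)
  pm <- simulate_profiles(cfg)$profiles
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(pm, f)
  back <- read_profile_matrix(f)
  expect_identical(back$counts, pm$counts)
  expect_identical(back$class, pm$class)
})

test_that("anchor validation requires a human gene in every family", {
  m <- matrix(c(0L, 1L, 1L, 1L), 2, 2,
              dimnames = list(c("F1", "F2"),
                              c("Homo_sapiens", "Mus_musculus")))
  expect_error(profile_matrix(m), "anchor")
  expect_silent(profile_matrix(m, anchor = NULL))
})

test_that("classification follows the all/none/some morbid rule", {
  cls <- classify_families(
    list(f1 = c("g1", "g2"), f2 = c("g3", "g4"), f3 = "g5"),
    morbid_genes = c("g1", "g2", "g3"))
  expect_equal(unname(cls), c("disease", "mixed", "non_disease"))
  expect_equal(unname(classify_families(list(f = "g"), character(0))),
               "non_disease")
  expect_error(classify_families(list(f1 = character(0)), "g1"), "empty")
  # partition: every family gets exactly one label
  cfg <- generator_config("suite1", scale = 0.02, seed = 8)
  sim <- simulate_profiles(cfg)
  re <- classify_families(sim$family_genes, sim$morbid_genes)
  expect_identical(unname(re[family_ids(sim$profiles)]),
                   unname(sim$profiles$class))
})

test_that("binarize maps positives to one and is idempotent", {
  m <- matrix(c(0L, 3L, 1L, 7L, 0L, 2L), 2, 3,
              dimnames = list(c("F1", "F2"), c("A", "B", "C")))
  pm <- toy_profiles(m, c("disease", "mixed"))
  b <- binarize(pm)
  expect_equal(unname(b$counts[1, ]), c(0L, 1L, 0L))
  expect_identical(binarize(b)$counts, b$counts)
  expect_identical(b$class, pm$class)
  expect_identical((pm$counts >= 1L), (b$counts == 1L))
})

test_that("percentage rounds half-up at the requested precision", {
  expect_identical(percentage(414, 1597), 26)
  expect_identical(percentage(1327, 7446), 18)
  expect_identical(percentage(1133, 1597, 1), 70.9)
  expect_identical(percentage(0, 5), 0)
  expect_identical(percentage(1, 8, 1), 12.5)
  expect_identical(percentage(1, 16, 1), 6.3)   # 6.25 rounds up
  expect_error(percentage(1, 0), "denominator")
})

test_that("conservation summary agrees with a brute-force recount", {
  tr <- suite1_tree()
  set.seed(42)
  n <- 40
  counts <- matrix(rpois(n * 12, 0.9), n, 12,
                   dimnames = list(sprintf("F%02d", 1:n), tr$tip.label))
  counts[, "Homo_sapiens"] <- pmax(counts[, "Homo_sapiens"], 1L)
  cls <- sample(c("disease", "non_disease", "mixed"), n, replace = TRUE)
  pm <- profile_matrix(counts, cls)
  cs <- conservation_summary(pm, tr, "Vertebrata", "Ecdysozoa")

  vert <- clade_tips(tr, "Vertebrata")
  inv <- clade_tips(tr, "Ecdysozoa")
  other_vert <- setdiff(vert, "Homo_sapiens")
  tetr <- clade_tips(tr, "Tetrapoda")
  fish <- clade_tips(tr, "Fish")
  brute <- function(rows) {
    pres <- counts[rows, , drop = FALSE] >= 1
    cnt <- counts[rows, , drop = FALSE]
    c(total = length(rows),
      single_copy = sum(apply(cnt, 1, max) <= 1),
      in_all_species = sum(rowSums(pres) == 12),
      in_all_species_single_copy = sum(rowSums(pres) == 12 &
                                         apply(cnt, 1, max) <= 1),
      in_vert_and_invert = sum(apply(pres[, vert, drop = FALSE], 1, any) &
                                 apply(pres[, inv, drop = FALSE], 1, any)),
      in_vertebrate = sum(apply(pres[, other_vert, drop = FALSE], 1, any)),
      in_all_vertebrates = sum(apply(pres[, vert, drop = FALSE], 1, all)),
      only_in_vertebrate = sum(!apply(pres[, inv, drop = FALSE], 1, any) &
        (apply(pres[, tetr, drop = FALSE], 1, any) +
           apply(pres[, fish, drop = FALSE], 1, any)) >= 2),
      only_in_all_vertebrates = sum(!apply(pres[, inv, drop = FALSE], 1, any)))
  }
  for (cl in c("disease", "non_disease", "mixed")) {
    expect_equal(unname(cs[[cl]]), unname(brute(which(cls == cl))),
                 info = cl)
  }
  # class columns sum to the total column
  expect_equal(cs$disease + cs$non_disease + cs$mixed, cs$total)
  # nesting: in_all_species <= in_all_vertebrates
  grab <- function(cat) cs$total[cs$category == cat]
  expect_lte(grab("in_all_species"), grab("in_all_vertebrates"))
  expect_error(conservation_summary(pm, tr, "NoSuchClade", "Ecdysozoa"),
               "unknown clade")
})

test_that("hand-built families land in the expected categories", {
  tr <- suite1_tree()
  sp <- tr$tip.label
  counts <- rbind(
    everywhere_single = rep(1L, 12),
    homo_mus = as.integer(sp %in% c("Homo_sapiens", "Mus_musculus")))
  colnames(counts) <- sp
  cs <- conservation_summary(profile_matrix(counts, "unlabeled"), tr,
                             "Vertebrata", "Ecdysozoa")
  g <- function(cat) cs$total[cs$category == cat]
  expect_equal(g("total"), 2)
  expect_equal(g("single_copy"), 2)
  expect_equal(g("in_all_species"), 1)
  expect_equal(g("in_all_species_single_copy"), 1)
  expect_equal(g("in_vert_and_invert"), 1)
  expect_equal(g("in_vertebrate"), 2)
  # homo_mus: absent from all invertebrates, does not span Tetrapoda + Fish
  expect_equal(g("only_in_all_vertebrates"), 1)
  expect_equal(g("only_in_vertebrate"), 0)
})

test_that("per-species presence totals of a reference-sized matrix read back", {
  totals <- suite1_family_totals()
  n <- max(totals)
  counts <- matrix(0L, n, length(totals),
                   dimnames = list(sprintf("F%05d", 1:n), names(totals)))
  for (s in names(totals)) counts[seq_len(totals[[s]]), s] <- 1L
  pm <- profile_matrix(counts, "unlabeled")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(pm, f)
  back <- read_profile_matrix(f)
  expect_equal(colSums(back$counts >= 1L), totals)
})

test_that("species alias mapping canonicalises common shorthand", {
  expect_equal(canonical_species(c("Homo sapiens", "Dmel", "worm")),
               c("Homo_sapiens", "Drosophila_melanogaster",
                 "Caenorhabditis_elegans"))
  expect_equal(canonical_species("Tribolium_castaneum"),
               "Tribolium_castaneum")
})
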