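# Bundled reference trees and summary tables ------------------------------
#
# The two study trees and the published-style summary tables for the
# 12-species disease/non-disease gene-family survey are shipped as reference
# data so that the summary arithmetic (percentages, z-scores, one-sided 99%
# limits) can be validated without any external download.

SUITE1_NEWICK <- paste0(
  "((((Homo_sapiens,Mus_musculus)Mammalia,Xenopus_tropicalis)Tetrapoda,",
  "(Danio_rerio,Fundulus_heteroclitus)Fish)Vertebrata,",
  "((((Drosophila_melanogaster,Anopheles_gambiae)Diptera,",
  "Nasonia_vitripennis)Hexapoda,",
  "((Daphnia_magna,Daphnia_pulex)Cladocera,Hyalella_azteca)Crustacea)",
  "Arthropoda,Caenorhabditis_elegans)Ecdysozoa)Bilateria;")

SUITE2_NEWICK <- paste0(
  "((((((Mus_musculus,Rattus_norvegicus)Rodentia,Homo_sapiens)Mammalia,",
  "Gallus_gallus)Amniota,Xenopus_tropicalis)Tetrapoda,Danio_rerio)",
  "Vertebrata,(Drosophila_melanogaster,Caenorhabditis_elegans)Ecdysozoa)",
  "Bilateria;")

#' The 12-species gene-family study tree
#'
#' Skeletal animal phylogeny of the 12-species suite used for gene-family
#' profiles: mammals (*Homo*, *Mus*), tetrapods (mammals plus *Xenopus*),
#' fish (*Danio*, *Fundulus*), insects (*Drosophila*, *Anopheles*,
#' *Nasonia*), crustaceans (*Daphnia magna*, *Daphnia pulex*, *Hyalella*),
#' and *Caenorhabditis*, rooted at Bilateria. All internal nodes are
#' labelled (Bilateria, Vertebrata, Tetrapoda, Mammalia, Fish, Ecdysozoa,
#' Arthropoda, Hexapoda, Diptera, Crustacea, Cladocera).
#'
#' @return a rooted, fully labelled `phylo` with 12 tips.
#' @export
suite1_tree <- function() parse_newick(SUITE1_NEWICK)

#' The 8-species pathway study tree
#'
#' Phylogeny of the pathway-conservation suite: *Homo*, *Mus*, *Rattus*,
#' *Gallus*, *Xenopus*, *Danio*, *Drosophila* and *Caenorhabditis*, rooted
#' at Bilateria with labelled internal nodes.
#'
#' @return a rooted, fully labelled `phylo` with 8 tips.
#' @export
suite2_tree <- function() parse_newick(SUITE2_NEWICK)

#' Reference per-class family conservation counts
#'
#' Reference distribution of 10,441 human-anchored gene families over the
#' disease / non-disease / mixed classes and the nine conservation
#' categories of [conservation_summary()], for the 12-species suite.
#' Bundled for validating the summary and percentage arithmetic.
#'
#' @return data frame with columns `category`, `disease`, `non_disease`,
#'   `mixed`, `total`.
#' @export
disease_family_counts <- function() {
  data.frame(
    category = CONSERVATION_CATEGORIES,
    disease     = c(1597,  640,  414, 106, 1133, 1596, 1379,  372,  464),
    non_disease = c(7446, 3033, 1327, 324, 4391, 7430, 5380, 1869, 3055),
    mixed       = c(1398,    0,  571,   0, 1147, 1398, 1349,  230,  251),
    total       = c(10441, 3673, 2312, 430, 6671, 10424, 8108, 2471, 3770))
}

#' Reference branch statistics for the disease-vs-null comparison
#'
#' Observed disease-family branch statistics on the 12-species tree (leaf
#' presence, per-node gains, per-branch losses) together with the mean and
#' standard deviation of the matching statistic over 1000 random 1597-family
#' subsamples of the 7446 non-disease families, and the derived columns
#' (standard error, one-sided 99% upper limit, z-score) as printed at 2 and
#' 1 decimal places. Bundled for validating [null_moment_stats()].
#'
#' @return data frame with columns `statistic` (`"presence"`, `"gain"` or
#'   `"loss"`), `label` (leaf, node or branch label), `observed`, `mean`,
#'   `sd`, `se_printed`, `upper99_printed`, `z_printed` (`NA` where the
#'   source prints none).
#' @export
disease_branch_stats <- function() {
  df <- rbind(
    data.frame(statistic = "presence", label = c(
      "Homo_sapiens", "Mus_musculus", "Xenopus_tropicalis",
      "Fundulus_heteroclitus", "Danio_rerio", "Daphnia_magna",
      "Daphnia_pulex", "Anopheles_gambiae", "Hyalella_azteca",
      "Caenorhabditis_elegans", "Nasonia_vitripennis",
      "Drosophila_melanogaster"),
      observed = c(1597, 1583, 1476, 1458, 1469, 917, 963, 802, 967, 720,
                   887, 826),
      mean = c(1597.0, 1566.0, 1323.7, 1259.4, 1287.5, 713.0, 762.2, 625.0,
               771.3, 534.0, 716.1, 644.1),
      sd = c(0.00, 4.82, 13.02, 14.77, 13.89, 16.66, 17.16, 17.04, 17.54,
             16.49, 18.15, 17.44),
      se_printed = c(0, 0.15, 0.41, 0.47, 0.44, 0.53, 0.54, 0.54, 0.55,
                     0.52, 0.57, 0.55),
      upper99_printed = c(1597, 1566.4, 1324.7, 1260.5, 1288.5, 714.2,
                          763.5, 626.3, 772.6, 535.2, 717.4, 645.4),
      z_printed = c(NA, 3.53, 11.70, 13.44, 13.07, 12.24, 11.70, 10.39,
                    11.16, 11.28, 9.41, 10.43)),
    data.frame(statistic = "gain",
      label = c("Mammalia", "Tetrapoda", "Vertebrata", "Bilateria"),
      observed = c(59, 33, 372, 1133),
      mean = c(182.9, 71.5, 401.9, 940.7),
      sd = c(11.27, 7.26, 15.44, 16.92),
      se_printed = c(0.36, 0.23, 0.49, 0.53),
      upper99_printed = c(183.7, 72.0, 403.0, 941.9),
      z_printed = c(-11.00, -5.30, -1.94, 11.37)),
    data.frame(statistic = "loss", label = c(
      "Fish", "Cladocera", "Crustacea", "Diptera", "Hexapoda", "Arthropoda",
      "Mus_musculus", "Xenopus_tropicalis", "Fundulus_heteroclitus",
      "Danio_rerio", "Daphnia_magna", "Daphnia_pulex", "Anopheles_gambiae",
      "Hyalella_azteca", "Caenorhabditis_elegans", "Nasonia_vitripennis",
      "Drosophila_melanogaster"),
      observed = c(12, 62, 29, 63, 145, 20, 14, 62, 35, 24, 105, 59, 103,
                   117, 413, 81, 79),
      mean = c(23.7, 71.6, 35.6, 73.6, 139.8, 16.8, 31.0, 90.4, 59.6, 31.5,
               103.8, 54.6, 85.5, 117.0, 406.6, 68.0, 66.4),
      sd = c(4.30, 7.36, 5.36, 7.06, 9.93, 3.54, 4.82, 7.92, 6.71, 5.11,
             8.60, 6.55, 7.82, 8.99, 15.60, 6.92, 6.99),
      se_printed = c(0.14, 0.23, 0.17, 0.22, 0.31, 0.11, 0.15, 0.25, 0.21,
                     0.16, 0.27, 0.21, 0.25, 0.28, 0.49, 0.22, 0.22),
      upper99_printed = c(24.0, 72.1, 36.0, 74.1, 140.5, 17.1, 31.4, 91.0,
                          60.1, 31.9, 104.4, 55.1, 86.1, 117.7, 407.7,
                          68.5, 66.9),
      z_printed = c(-2.72, -1.30, -1.23, -1.50, 0.52, 0.90, -3.53, -3.59,
                    -3.67, -1.47, 0.14, 0.67, 2.24, 0.00, 0.41, 1.88,
                    1.80)))
  rownames(df) <- NULL
  df
}

#' Reference per-species family totals for the 12-species suite
#'
#' Number of human-anchored gene families with at least one member in each
#' species of the 12-species suite.
#'
#' @return named integer vector (species -> family count).
#' @export
suite1_family_totals <- function() {
  c(Homo_sapiens = 10441L, Mus_musculus = 10282L, Xenopus_tropicalis = 9018L,
    Fundulus_heteroclitus = 8694L, Danio_rerio = 8839L,
    Drosophila_melanogaster = 4683L, Anopheles_gambiae = 4589L,
    Nasonia_vitripennis = 5204L, Daphnia_magna = 5248L,
    Daphnia_pulex = 5560L, Hyalella_azteca = 5611L,
    Caenorhabditis_elegans = 4052L)
}

#' Canonicalise species names
#'
#' Maps common shorthand (e.g. `"Dmel"`, `"human"`, `"Homo sapiens"`) to the
#' canonical `Genus_species` labels used on the bundled trees. Unknown names
#' pass through unchanged; matching elsewhere in the package is exact-string
#' on the canonical form.
#'
#' @param x character vector of species names.
#' @return character vector of canonical names.
#' @export
canonical_species <- function(x) {
  aliases <- c(
    human = "Homo_sapiens", Hsap = "Homo_sapiens",
    mouse = "Mus_musculus", Mmus = "Mus_musculus",
    rat = "Rattus_norvegicus", Rnor = "Rattus_norvegicus",
    chicken = "Gallus_gallus", Ggal = "Gallus_gallus",
    zebrafish = "Danio_rerio", Drer = "Danio_rerio",
    killifish = "Fundulus_heteroclitus", Fhet = "Fundulus_heteroclitus",
    frog = "Xenopus_tropicalis", Xtro = "Xenopus_tropicalis",
    Dmel = "Drosophila_melanogaster", Agam = "Anopheles_gambiae",
    Nvit = "Nasonia_vitripennis", Dmag = "Daphnia_magna",
    Dpul = "Daphnia_pulex", Hazt = "Hyalella_azteca",
    Cele = "Caenorhabditis_elegans", worm = "Caenorhabditis_elegans")
  out <- gsub(" ", "_", x, fixed = TRUE)
  hit <- match(x, names(aliases))
  out[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  out
}
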