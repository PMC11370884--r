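# Family conservation summaries ------------------------------------------

CONSERVATION_CATEGORIES <- c(
  "total", "single_copy", "in_all_species", "in_all_species_single_copy",
  "in_vert_and_invert", "in_vertebrate", "in_all_vertebrates",
  "only_in_vertebrate", "only_in_all_vertebrates")

#' Per-class conservation summary of a profile matrix
#'
#' Tabulates, for each family class, the nine conservation categories used
#' to contrast disease and non-disease gene families across a vertebrate and
#' an invertebrate clade of the species tree. The categories are literal set
#' definitions over binary presence (copy count >= 1):
#'
#' * `total` - number of families of the class;
#' * `single_copy` - no species carries more than one copy;
#' * `in_all_species` - present in every species;
#' * `in_all_species_single_copy` - both of the above;
#' * `in_vert_and_invert` - present in at least one leaf of the vertebrate
#'   clade and at least one leaf of the invertebrate clade;
#' * `in_vertebrate` - present in at least one *non-anchor* leaf of the
#'   vertebrate clade (the anchor species trivially carries every family, so
#'   it is excluded from this category);
#' * `in_all_vertebrates` - present in every leaf of the vertebrate clade;
#' * `only_in_vertebrate` - absent from every invertebrate leaf, with the
#'   present leaves spanning at least two children of the vertebrate clade
#'   root (equivalently, the Dollo gain falls exactly on that node);
#' * `only_in_all_vertebrates` - absent from every invertebrate leaf.
#'
#' Categories overlap by design (e.g. `only_in_vertebrate` is a subset of
#' `only_in_all_vertebrates` under these definitions); the only set
#' inclusions guaranteed are `in_all_species <= in_all_vertebrates <=
#' total`.
#'
#' @param x a `profile_matrix` whose species equal the tips of `tree`.
#' @param tree a labelled rooted `phylo` (see [parse_newick()]).
#' @param vert_clade,invert_clade labels of the internal nodes delimiting
#'   the vertebrate and invertebrate clades.
#' @param anchor the anchor species (default `"Homo_sapiens"`); used only
#'   for the `in_vertebrate` category.
#' @return a data frame with one row per category and one column per class
#'   present in `x`, plus a `total` column summing across classes.
#' @export
conservation_summary <- function(x, tree, vert_clade, invert_clade,
                                 anchor = "Homo_sapiens") {
  stopifnot(inherits(x, "profile_matrix"))
  idx <- tree_index(tree)
  if (!setequal(colnames(x$counts), tree$tip.label))
    stop("profile species must equal the tree's tips")
  for (lab in c(vert_clade, invert_clade))
    if (!lab %in% idx$labels) stop("unknown clade label: ", lab)

  cnt <- x$counts[, tree$tip.label, drop = FALSE]
  pres <- cnt >= 1L
  vert_tips <- clade_tips(tree, vert_clade)
  invert_tips <- clade_tips(tree, invert_clade)
  other_vert <- setdiff(vert_tips, anchor)
  if (length(other_vert) == 0L) other_vert <- vert_tips
  vnode <- match(vert_clade, idx$labels)
  vchildren <- idx$children[[vnode]]

  any_of <- function(tips) {
    if (length(tips) == 0L) return(rep(FALSE, nrow(pres)))
    rowSums(pres[, tips, drop = FALSE]) > 0L
  }
  all_of <- function(tips) rowSums(pres[, tips, drop = FALSE]) == length(tips)

  single <- apply(cnt, 1L, max) <= 1L
  in_all <- rowSums(pres) == ncol(pres)
  in_vi <- any_of(vert_tips) & any_of(invert_tips)
  in_vert <- any_of(other_vert)
  in_all_vert <- all_of(vert_tips)
  no_invert <- !any_of(invert_tips)
  # presence spans >= 2 children of the vertebrate clade root
  span <- if (length(vchildren) == 0L) {
    rep(FALSE, nrow(pres))
  } else {
    nspan <- Reduce(`+`, lapply(vchildren, function(ch)
      as.integer(any_of(tree$tip.label[idx$clade[ch, ]]))))
    nspan >= 2L
  }

  flags <- cbind(
    total = rep(TRUE, nrow(pres)),
    single_copy = single,
    in_all_species = in_all,
    in_all_species_single_copy = in_all & single,
    in_vert_and_invert = in_vi,
    in_vertebrate = in_vert,
    in_all_vertebrates = in_all_vert,
    only_in_vertebrate = no_invert & span,
    only_in_all_vertebrates = no_invert)

  classes <- intersect(FAMILY_CLASSES, unique(x$class))
  out <- data.frame(category = CONSERVATION_CATEGORIES)
  for (cl in classes)
    out[[cl]] <- colSums(flags[x$class == cl, , drop = FALSE])
  out$total <- colSums(flags)
  out
}
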