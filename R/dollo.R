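# Dollo parsimony reconstruction ------------------------------------------
#
# Under Dollo's law a binary character (family presence) is gained exactly
# once and can only be lost thereafter. On a rooted tree the minimum-loss
# single-gain solution is unique: the gain falls on the most recent common
# ancestor of the present leaves, and the losses are the root edges of the
# maximal all-absent subtrees inside the gain clade. (Moving the gain above
# the MRCA only adds losses; placing any loss higher or lower than the root
# of an all-absent subtree either strands a present leaf or splits one loss
# into several.)

# Vectorised core: pres is a families x tips logical matrix with columns in
# tree tip order. Returns gain node ids, a families x nodes loss incidence
# matrix (TRUE at the child node of each loss branch) and per-node presence
# counts.
dollo_core <- function(pres, idx) {
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = 1)
  tot <- rowSums(pres)
  if (any(tot == 0L))
    stop("all-absent profile cannot be reconstructed (family ",
         if (!is.null(rownames(pres))) rownames(pres)[which(tot == 0)[1]]
         else which(tot == 0)[1], ")")
  # per-node counts of present leaves in each subtree
  pc <- pres %*% t(idx$clade * 1)                      # families x nodes
  # gain = deepest node whose subtree holds all present leaves
  full <- sweep(pc, 1L, tot, `==`)
  score <- sweep(full * 1, 2L, idx$depth + 1L, `*`)
  gain <- max.col(score, ties.method = "first")
  # loss at branch (parent -> v) iff v's subtree is empty, the parent's is
  # not, and the parent lies inside the gain clade
  anc_gain <- idx$anc[gain, , drop = FALSE]            # families x nodes
  loss <- matrix(FALSE, nrow(pres), idx$nv)
  for (v in seq_len(idx$nv)) {
    if (v == idx$root) next
    p <- idx$parent[v]
    loss[, v] <- pc[, v] == 0 & pc[, p] > 0 & anc_gain[, p]
  }
  list(gain = gain, loss = loss, pc = pc, tot = tot)
}

#' Dollo reconstruction of one binary presence profile
#'
#' Computes the unique minimum-loss single-gain (Dollo) explanation of a
#' presence/absence profile on a rooted species tree: the gain node is the
#' most recent common ancestor of the present leaves, and each loss branch
#' is the root edge of a maximal all-absent subtree within the gain clade.
#'
#' @param profile named 0/1 (or logical) vector over the tree's tips; at
#'   least one leaf must be present.
#' @param tree a labelled rooted `phylo` (see [parse_newick()]).
#' @return a list with elements `gain` (node label) and `losses` (character
#'   vector of loss branches, each named by its child node; possibly empty).
#' @examples
#' tr <- suite1_tree()
#' prof <- setNames(as.integer(tr$tip.label %in%
#'   c("Homo_sapiens", "Drosophila_melanogaster")), tr$tip.label)
#' dollo_reconstruct(prof, tr)   # gain at Bilateria, 7 losses
#' @export
dollo_reconstruct <- function(profile, tree) {
  idx <- tree_index(tree)
  if (is.null(names(profile)) || !setequal(names(profile), tree$tip.label))
    stop("`profile` must be named by the tree's tips")
  if (!all(profile %in% c(0, 1)))
    stop("`profile` must be binary presence/absence")
  pres <- matrix(as.logical(profile[tree$tip.label]), nrow = 1)
  res <- dollo_core(pres, idx)
  list(gain = idx$labels[res$gain],
       losses = idx$labels[which(res$loss[1, ])])
}

#' Aggregate Dollo gains and losses per branch for a family class
#'
#' Reconstructs every family of the requested class under Dollo parsimony
#' and aggregates the events: per-node gain counts, per-branch loss counts
#' (branches named by their child node) and per-leaf presence counts. Gains
#' summed over nodes equal the number of families reconstructed.
#'
#' @param x a binarized `profile_matrix` (see [binarize()]) whose species
#'   equal the tree's tips.
#' @param tree a labelled rooted `phylo`.
#' @param class optional family class to restrict to (`"disease"`,
#'   `"non_disease"`, `"mixed"`, `"unlabeled"`); `NULL` uses all families.
#' @return a data frame of class `"dollo_events"` with columns `label`,
#'   `type` (`"internal"`/`"leaf"`), `gains`, `losses` (`NA` for the root,
#'   which has no parent branch) and `presence` (`NA` for internal nodes).
#'   Internal branches are listed before terminal branches, each group in
#'   preorder. Attributes `n_families` and `class` record the input.
#' @export
branch_event_table <- function(x, tree, class = NULL) {
  stopifnot(inherits(x, "profile_matrix"))
  if (!is_binary(x))
    stop("profiles must be binarized first; see binarize()")
  idx <- tree_index(tree)
  if (!setequal(colnames(x$counts), tree$tip.label))
    stop("profile species must equal the tree's tips")
  keep <- if (is.null(class)) rep(TRUE, nrow(x$counts)) else x$class == class
  if (!any(keep)) {
    warning("no families of class '", class, "'; returning empty table")
    res <- NULL
  } else {
    pres <- x$counts[keep, tree$tip.label, drop = FALSE] >= 1L
    res <- dollo_core(pres, idx)
  }
  ord <- c(idx$preorder[idx$preorder > idx$ntip],
           idx$preorder[idx$preorder <= idx$ntip])
  out <- data.frame(
    label = idx$labels[ord],
    type = ifelse(ord > idx$ntip, "internal", "leaf"),
    gains = if (is.null(res)) 0L else tabulate(res$gain, idx$nv)[ord],
    losses = if (is.null(res)) 0L else colSums(res$loss)[ord],
    presence = NA_integer_)
  out$losses[ord == idx$root] <- NA_integer_
  if (!is.null(res)) {
    leaf_rows <- match(seq_len(idx$ntip), ord)
    out$presence[leaf_rows] <- colSums(matrix(
      x$counts[keep, tree$tip.label, drop = FALSE] >= 1L, sum(keep)))
  } else {
    out$presence[out$type == "leaf"] <- 0L
  }
  structure(out, class = c("dollo_events", "data.frame"),
            n_families = if (is.null(res)) 0L else sum(keep),
            family_class = class)
}

#' @export
print.dollo_events <- function(x, ...) {
  cat("Dollo branch events for", attr(x, "n_families"), "families",
      if (!is.null(attr(x, "family_class")))
        paste0("(class ", attr(x, "family_class"), ")"), "\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
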