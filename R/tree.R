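# Rooted species trees ----------------------------------------------------
#
# Species trees are ordinary `ape` "phylo" objects, constrained to be rooted
# with unique labels on every node. Internal nodes without a newick label are
# auto-named "N<preorder index>" so that event tables are comparable across
# runs of the same topology.

#' Parse a rooted, fully labelled species tree from newick
#'
#' Reads a newick string (or a path to a newick file) into an [ape::phylo]
#' object, validates that it is rooted with unique leaf labels, and assigns
#' deterministic names (`"N<preorder index>"`) to any internal node that the
#' newick text leaves unlabelled. Polytomies are permitted.
#'
#' @param text a single newick string, or the path of a file containing one.
#' @return a rooted `phylo` object whose tips and internal nodes all carry
#'   unique labels.
#' @examples
#' tr <- parse_newick("((A,B)AB,C)R;")
#' tr$tip.label
#' clade_tips(tr, "AB")
#' @seealso [clade_tips()], [suite1_tree()]
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single newick string or a file path")
  if (!grepl(";", text, fixed = TRUE)) {
    if (file.exists(text)) {
      text <- paste(readLines(text, warn = FALSE), collapse = "")
    } else {
      stop("newick parse error: no terminating ';' and no such file: ", text)
    }
  }
  check_parentheses(text)
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) stop("newick parse error: ", conditionMessage(e))
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("newick parse error: input could not be read as a tree")
  if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
  tree$node.label[is.na(tree$node.label)] <- ""
  # deterministic auto-names by preorder position among all nodes
  pre <- preorder_nodes(tree)
  blank <- which(tree$node.label == "")
  if (length(blank)) {
    node_ids <- blank + length(tree$tip.label)
    tree$node.label[blank] <- paste0("N", match(node_ids, pre))
  }
  labs <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(labs)) {
    dup <- unique(labs[duplicated(labs)])
    stop("duplicate node labels in tree: ", paste(dup, collapse = ", "))
  }
  validate_tree(tree)
  tree
}

check_parentheses <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L)
    stop("newick parse error: ", depth, " unclosed '(' at end of input")
  invisible(TRUE)
}

validate_tree <- function(tree) {
  child <- tree$edge[, 2]
  if (anyDuplicated(child))
    stop("invalid tree: a node has more than one parent")
  roots <- setdiff(tree$edge[, 1], child)
  if (length(roots) != 1L)
    stop("invalid tree: expected exactly one root, found ", length(roots))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("invalid tree: negative branch lengths")
  invisible(tree)
}

# Preorder sequence of node ids (root first, parents before children).
preorder_nodes <- function(tree) {
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  root <- setdiff(edge[, 1], edge[, 2])
  c(root, edge[, 2])
}

# Index structure shared by the reconstruction and simulation code.
# Node ids follow ape numbering: tips 1..ntip, internals ntip+1..ntip+nnode.
tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nv <- ntip + tree$Nnode
  labels <- c(tree$tip.label, tree$node.label)
  if (is.null(tree$node.label) || any(labels == ""))
    stop("tree must have labels on all nodes; use parse_newick()")
  parent <- integer(nv)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  po <- ape::reorder.phylo(tree, "postorder")$edge
  postorder <- c(po[, 2], root)
  preorder <- preorder_nodes(tree)
  depth <- integer(nv)
  for (v in preorder[-1]) depth[v] <- depth[parent[v]] + 1L
  children <- lapply(seq_len(nv), function(v) tree$edge[tree$edge[, 1] == v, 2])
  # clade membership: cl[v, t] TRUE iff tip t is in the subtree rooted at v
  cl <- matrix(FALSE, nv, ntip)
  cl[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (v in postorder) {
    for (c in children[[v]]) cl[v, ] <- cl[v, ] | cl[c, ]
  }
  # ancestor-or-self: anc[a, d] TRUE iff a lies on the root path of d
  anc <- diag(nv) > 0
  for (v in preorder[-1]) anc[, v] <- anc[, v] | anc[, parent[v]]
  list(ntip = ntip, nv = nv, labels = labels, parent = parent, root = root,
       children = children, postorder = postorder, preorder = preorder,
       depth = depth, clade = cl, anc = anc)
}

#' Tips descending from a named clade
#'
#' @param tree a labelled `phylo`, e.g. from [parse_newick()].
#' @param label the label of an internal node (or a tip, in which case the
#'   tip itself is returned).
#' @return character vector of tip labels in the clade.
#' @export
clade_tips <- function(tree, label) {
  idx <- tree_index(tree)
  v <- match(label, idx$labels)
  if (is.na(v)) stop("unknown clade label: ", label)
  tree$tip.label[idx$clade[v, ]]
}

# root -> node path as a vector of node ids (root first)
root_path <- function(idx, v) {
  path <- v
  while (path[1] != idx$root) path <- c(idx$parent[path[1]], path)
  path
}
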