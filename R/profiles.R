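# Phylogenetic profile matrices ------------------------------------------

FAMILY_CLASSES <- c("disease", "non_disease", "mixed", "unlabeled")

#' Construct a phylogenetic profile matrix
#'
#' A profile matrix stores per-species copy counts for a collection of gene
#' families (orthologous groups), together with a disease-class label per
#' family. All downstream stages (Dollo reconstruction, subsampling nulls,
#' Shannon ranking) consume this container.
#'
#' Every family is assumed to contain a gene of the anchor species (all
#' comparisons are made with respect to it); validation therefore requires a
#' positive anchor count when the anchor species is among the columns. Set
#' `anchor = NULL` to lift the constraint.
#'
#' @param counts integer matrix, families in rows (unique rownames = family
#'   ids), species in columns (unique colnames); entries are non-negative
#'   copy numbers.
#' @param class character vector of per-family labels among
#'   `"disease"`, `"non_disease"`, `"mixed"`, `"unlabeled"`; recycled if of
#'   length 1. Default `"unlabeled"`.
#' @param anchor species whose presence is required in every family
#'   (default `"Homo_sapiens"`); ignored when absent from the columns.
#' @return an object of class `"profile_matrix"`: a list with elements
#'   `counts` (integer matrix) and `class` (named character vector).
#' @examples
#' m <- matrix(c(1L, 2L, 0L, 1L), 2, 2,
#'             dimnames = list(c("F1", "F2"), c("A", "B")))
#' pm <- profile_matrix(m, class = c("disease", "non_disease"))
#' binarize(pm)
#' @export
profile_matrix <- function(counts, class = "unlabeled", anchor = "Homo_sapiens") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have family ids as rownames and species as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate family ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts))) stop("duplicate species names")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  n <- nrow(counts)
  if (length(class) == 1L) class <- rep(class, n)
  if (length(class) != n) stop("`class` must have one label per family")
  bad <- setdiff(unique(class), FAMILY_CLASSES)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  class <- setNames(as.character(class), rownames(counts))
  if (!is.null(anchor) && anchor %in% colnames(counts)) {
    absent <- rownames(counts)[counts[, anchor] < 1L]
    if (length(absent))
      stop("anchor species '", anchor, "' absent from ", length(absent),
           " famil", if (length(absent) == 1) "y" else "ies",
           " (first: ", absent[1], "); every family must contain an anchor gene")
  }
  structure(list(counts = counts, class = class), class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("profile_matrix:", nrow(x$counts), "families x", ncol(x$counts), "species\n")
  tab <- table(factor(x$class, levels = FAMILY_CLASSES))
  tab <- tab[tab > 0]
  if (length(tab))
    cat("classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("species:", paste(colnames(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$counts)

#' Species names of a profile matrix
#' @param x a `profile_matrix`.
#' @return character vector of species (column) names.
#' @export
profile_species <- function(x) colnames(x$counts)

#' Family identifiers of a profile matrix
#' @param x a `profile_matrix`.
#' @return character vector of family ids (row names).
#' @export
family_ids <- function(x) rownames(x$counts)

# subset families, keeping classes aligned
profile_subset <- function(x, i) {
  profile_matrix(x$counts[i, , drop = FALSE], x$class[i], anchor = NULL)
}

#' Read a profile matrix from TSV
#'
#' Expected layout: a header row `family_id<TAB>class<TAB><species1>...`,
#' then one row per family with integer copy counts. Row order is preserved.
#'
#' @param path file to read.
#' @param anchor passed to [profile_matrix()] (default `"Homo_sapiens"`;
#'   enforced only when that species is among the columns).
#' @return a [profile_matrix()].
#' @export
read_profile_matrix <- function(path, anchor = "Homo_sapiens") {
  raw <- tryCatch(
    read.delim(path, header = TRUE, colClasses = "character",
               check.names = FALSE, sep = "\t"),
    error = function(e) stop("cannot read profile TSV '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(raw) == 0L) stop("profile TSV '", path, "' contains no data rows")
  if (ncol(raw) < 3L || names(raw)[1] != "family_id" || names(raw)[2] != "class")
    stop("profile TSV must start with columns 'family_id', 'class'")
  sp <- names(raw)[-(1:2)]
  cnt <- as.matrix(raw[, -(1:2), drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cnt), nrow(cnt), ncol(cnt)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("profile TSV format error: non-integer or negative count at data row ",
         bad[1, 1], ", column '", sp[bad[1, 2]], "'")
  if (anyDuplicated(raw$family_id))
    stop("profile TSV format error: duplicate family_id '",
         raw$family_id[duplicated(raw$family_id)][1], "'")
  dimnames(num) <- list(raw$family_id, sp)
  profile_matrix(num, raw$class, anchor = anchor)
}

#' Write a profile matrix to TSV
#'
#' Inverse of [read_profile_matrix()]; a written file read back yields an
#' identical object.
#'
#' @param x a `profile_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(x, path) {
  stopifnot(inherits(x, "profile_matrix"))
  df <- data.frame(family_id = rownames(x$counts),
                   class = unname(x$class),
                   x$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify gene families by disease linkage of their human genes
#'
#' A family is `"disease"` if all of its human genes are in the morbid-gene
#' list, `"non_disease"` if none are, and `"mixed"` otherwise. This is the
#' all/none/some rule used to contrast disease and non-disease gene classes.
#'
#' @param family_genes named list: family id -> character vector of human
#'   gene ids (each family must have at least one gene).
#' @param morbid_genes character vector of disease-linked gene ids.
#' @return named character vector of class labels, one per family.
#' @examples
#' classify_families(list(f1 = c("g1", "g2"), f2 = "g3"), morbid_genes = "g1")
#' @export
classify_families <- function(family_genes, morbid_genes) {
  if (!is.list(family_genes) || is.null(names(family_genes)))
    stop("`family_genes` must be a named list of gene id vectors")
  n_genes <- lengths(family_genes)
  if (any(n_genes == 0L))
    stop("family with empty gene list: ",
         names(family_genes)[which(n_genes == 0L)[1]])
  hits <- vapply(family_genes, function(g) sum(g %in% morbid_genes), integer(1))
  cls <- ifelse(hits == n_genes, "disease",
                ifelse(hits == 0L, "non_disease", "mixed"))
  setNames(cls, names(family_genes))
}

#' Binarize copy counts to presence/absence
#'
#' Replaces every positive count by 1; class labels are preserved. The
#' operation is idempotent.
#'
#' @param x a `profile_matrix`.
#' @return a `profile_matrix` of 0/1 presence values.
#' @export
binarize <- function(x) {
  stopifnot(inherits(x, "profile_matrix"))
  b <- x$counts
  b[b > 0L] <- 1L
  profile_matrix(b, x$class, anchor = NULL)
}

is_binary <- function(x) all(x$counts %in% c(0L, 1L))
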