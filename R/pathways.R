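# Pathway conservation ----------------------------------------------------
#
# A pathway record stores, for one human pathway, the number of human genes
# and reactions plus the per-species counts of those genes/reactions that
# are conserved (orthologous). Records live in an ordinary data frame with
# columns `pathway_id`, `name`, `disease`, `n_genes`, `n_reactions`,
# `is_terminal`, then one `<species>:genes` and one `<species>:reactions`
# column per non-human species.

species_col <- function(species, element) paste0(species, ":", element)

pathway_species <- function(records) {
  cols <- grep(":genes$", names(records), value = TRUE)
  sub(":genes$", "", cols)
}

validate_pathway_table <- function(records) {
  need <- c("pathway_id", "name", "disease", "n_genes", "n_reactions",
            "is_terminal")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("pathway table lacks column(s): ", paste(miss, collapse = ", "))
  sp <- pathway_species(records)
  if (length(sp) == 0L) stop("pathway table has no '<species>:genes' columns")
  for (s in sp) {
    for (el in c("genes", "reactions")) {
      col <- species_col(s, el)
      if (!col %in% names(records)) stop("missing column '", col, "'")
      human <- if (el == "genes") records$n_genes else records$n_reactions
      if (any(records[[col]] > human))
        stop("conserved ", el, " exceed human count for species ", s)
      if (any(records[[col]] < 0)) stop("negative conserved count")
    }
  }
  invisible(records)
}

#' Read a pathway conservation table from TSV
#'
#' Expected columns: `pathway_id`, `name`, `disease` (0/1 or logical),
#' `n_genes`, `n_reactions`, `is_terminal`, then `<species>:genes` and
#' `<species>:reactions` integer columns for each non-human species.
#'
#' @param path file to read.
#' @return a validated data frame of pathway records.
#' @export
read_pathway_table <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE, sep = "\t")
  df$disease <- as.logical(df$disease)
  df$is_terminal <- as.logical(df$is_terminal)
  validate_pathway_table(df)
}

#' Write a pathway conservation table to TSV
#' @param records pathway data frame (see [read_pathway_table()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pathway_table <- function(records, path) {
  validate_pathway_table(records)
  out <- records
  out$disease <- as.integer(out$disease)
  out$is_terminal <- as.integer(out$is_terminal)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter pathways to terminal, mid-sized networks
#'
#' Keeps terminal pathways whose human gene count lies within
#' `[min_elements, max_elements]`. The defaults drop networks with fewer
#' than three elements and the one outsized generic-transcription network
#' of 1228 elements. Reactions never enter the size filter; "elements" are
#' human genes with identifiers.
#'
#' @param records pathway data frame.
#' @param min_elements,max_elements inclusive size bounds (defaults 3 and
#'   1227).
#' @return the retained rows, with attribute `"filter_log"`: a named vector
#'   `c(input, retained, removed_small, removed_large,
#'   removed_non_terminal)`. Rules are applied in the order non-terminal,
#'   too-small, too-large, so the log entries sum to the input count.
#' @export
filter_pathways <- function(records, min_elements = 3L, max_elements = 1227L) {
  validate_pathway_table(records)
  non_term <- !records$is_terminal
  small <- !non_term & records$n_genes < min_elements
  large <- !non_term & !small & records$n_genes > max_elements
  keep <- !(non_term | small | large)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- c(input = nrow(records), retained = sum(keep),
                               removed_small = sum(small),
                               removed_large = sum(large),
                               removed_non_terminal = sum(non_term))
  out
}

#' Per-species pathway conservation percentage
#'
#' `100 * conserved / human` for the chosen element type, vectorised over
#' pathways.
#'
#' @param records pathway data frame.
#' @param species one species name (matching the `<species>:...` columns).
#' @param element `"genes"` or `"reactions"`.
#' @return numeric vector of percentages, one per pathway.
#' @export
conservation_percent <- function(records, species,
                                 element = c("genes", "reactions")) {
  element <- match.arg(element)
  col <- species_col(species, element)
  if (!col %in% names(records)) stop("species absent from records: ", species)
  human <- if (element == "genes") records$n_genes else records$n_reactions
  if (any(human == 0))
    stop("human ", element, " count is zero for pathway ",
         records$pathway_id[which(human == 0)[1]])
  100 * records[[col]] / human
}

#' Mean conservation percentage over a species group
#'
#' Unweighted mean of [conservation_percent()] over the species in the
#' group, per pathway; invariant to the order of the group.
#'
#' @param records pathway data frame.
#' @param species_group non-empty character vector of species.
#' @param element `"genes"` or `"reactions"`.
#' @return numeric vector (one mean percentage per pathway).
#' @export
group_average <- function(records, species_group,
                          element = c("genes", "reactions")) {
  element <- match.arg(element)
  if (length(species_group) == 0L) stop("`species_group` must be non-empty")
  pct <- vapply(species_group,
                function(s) conservation_percent(records, s, element),
                numeric(nrow(records)))
  if (nrow(records) == 1L) pct <- matrix(pct, nrow = 1L)
  rowMeans(pct)
}

#' Fraction of conserved pathway genes linked to disease
#'
#' Given the disease flags of the pathway genes that a species conserves,
#' returns the percentage flagged as disease; `NA` (undefined) when no gene
#' is conserved.
#'
#' @param flags logical vector, one entry per conserved gene.
#' @return percentage in \[0, 100\], or `NA_real_` for an empty vector.
#' @export
disease_gene_fraction <- function(flags) {
  if (length(flags) == 0L) return(NA_real_)
  100 * mean(as.logical(flags))
}

#' GLM of invertebrate pathway conservation
#'
#' Fits the conservation model
#' `invertebrate ~ vertebrate + n_genes + vertebrate:n_genes`,
#' where the response is each pathway's mean proportion of human genes
#' conserved across the invertebrate group and the first predictor the mean
#' proportion across the vertebrate group. The default family is binomial
#' with logit link and pathway gene counts as weights (the response is a
#' proportion); a gaussian-identity mode is available for sensitivity
#' analysis.
#'
#' @param records pathway data frame (normally pre-filtered with
#'   [filter_pathways()]; fewer than 30 rows triggers a warning).
#' @param vert_species,invert_species species groups for the two averages.
#' @param family `"binomial"` (logit, weighted by `n_genes`) or
#'   `"gaussian"` (identity, unweighted).
#' @param element `"genes"` or `"reactions"`.
#' @return an object of class `"conservation_glm"` wrapping the `glm` fit,
#'   with a coefficient table (`$coefficients`: estimate, std. error,
#'   p-value) and metadata (`$family`, `$link`, `$n_obs`).
#' @export
fit_conservation_glm <- function(records, vert_species, invert_species,
                                 family = c("binomial", "gaussian"),
                                 element = "genes") {
  family <- match.arg(family)
  if (nrow(records) == 0L) stop("no pathway records to fit")
  if (nrow(records) < 30L)
    warning("only ", nrow(records), " pathways; GLM may be unstable")
  df <- data.frame(
    invertebrate = group_average(records, invert_species, element) / 100,
    vertebrate = group_average(records, vert_species, element) / 100,
    n_genes = records$n_genes)
  fit <- if (family == "binomial") {
    withCallingHandlers(
      glm(invertebrate ~ vertebrate * n_genes, data = df,
          family = binomial("logit"), weights = df$n_genes),
      warning = function(w) {
        if (grepl("non-integer #successes", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  } else {
    glm(invertebrate ~ vertebrate * n_genes, data = df,
        family = gaussian("identity"))
  }
  if (!fit$converged) stop("conservation GLM did not converge")
  sm <- summary(fit)$coefficients
  if (any(is.na(coef(fit))))
    stop("singular design: ", paste(names(coef(fit))[is.na(coef(fit))],
                                    collapse = ", "))
  structure(list(glm = fit,
                 coefficients = sm,
                 family = family,
                 link = if (family == "binomial") "logit" else "identity",
                 n_obs = nrow(df),
                 vert_species = vert_species,
                 invert_species = invert_species,
                 data = df),
            class = "conservation_glm")
}

#' @export
print.conservation_glm <- function(x, ...) {
  cat("Pathway conservation GLM (", x$family, ", ", x$link, " link, n = ",
      x$n_obs, ")\n", sep = "")
  printCoefmat(x$coefficients)
  invisible(x)
}

#' @export
coef.conservation_glm <- function(object, ...) coef(object$glm)

#' Predicted invertebrate conservation over a parameter lattice
#'
#' Evaluates the fitted [fit_conservation_glm()] model on a grid of
#' vertebrate conservation values and pathway sizes, on the response scale
#' (inverse link).
#'
#' @param model a `"conservation_glm"`.
#' @param vertebrate numeric vector of vertebrate mean conservation values,
#'   as percentages in \[0, 100\].
#' @param n_genes integer vector of human pathway sizes.
#' @return data frame of the full grid with columns `vertebrate`,
#'   `n_genes`, `predicted` (percent invertebrate conservation). Grid
#'   points outside the observed predictor range trigger an extrapolation
#'   warning but are still predicted.
#' @export
predict_surface <- function(model, vertebrate, n_genes) {
  stopifnot(inherits(model, "conservation_glm"))
  grid <- expand.grid(vertebrate = vertebrate / 100, n_genes = n_genes)
  rng_v <- range(model$data$vertebrate)
  rng_n <- range(model$data$n_genes)
  if (any(grid$vertebrate < rng_v[1] | grid$vertebrate > rng_v[2]) ||
      any(grid$n_genes < rng_n[1] | grid$n_genes > rng_n[2]))
    warning("grid extends beyond the observed predictor range (extrapolation)")
  grid$predicted <- 100 * predict(model$glm, newdata = grid,
                                  type = "response")
  grid$vertebrate <- 100 * grid$vertebrate
  grid
}
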