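# Shannon-index ranking and preranked ortholog-set enrichment -------------

#' Shannon index of a cross-species copy-count profile
#'
#' `H' = -sum(p_i * log(p_i))` over species with positive counts, where
#' `p_i` is the proportional abundance `count_i / sum(counts)` and the log
#' is natural (`0 * log 0` is taken as 0). A family spread evenly across
#' `S` species attains the maximum `log(S)`; a family private to one
#' species scores 0. The index is computed on copy counts, not presence, so
#' duplication skews as well as absences lower the score.
#'
#' @param counts non-negative numeric vector of per-species copy counts
#'   (sum > 0), or a matrix to score row-wise.
#' @return the index (or one value per row).
#' @examples
#' shannon_index(rep(1, 12))     # log(12) = 2.4849
#' shannon_index(c(2, 1, 1))     # 1.0397
#' @export
shannon_index <- function(counts) {
  if (is.matrix(counts)) return(apply(counts, 1L, shannon_index))
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) stop("all-zero profile has no Shannon index")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Rank gene families by Shannon index
#'
#' Scores every family of a profile matrix with [shannon_index()] and
#' returns them in descending order; ties are broken by ascending family id
#' so the ranking is deterministic. Note that large blocks of tied scores
#' (e.g. all single-copy universal families share `H' = log(S)`) make the
#' within-tie order arbitrary in principle; the id tie-break fixes it.
#'
#' @param x a `profile_matrix`, or a counts matrix with family rownames.
#' @return a data frame of class `"ranked_list"` with columns `family_id`
#'   and `score`, ordered by decreasing score.
#' @export
rank_families <- function(x) {
  counts <- if (inherits(x, "profile_matrix")) x$counts else as.matrix(x)
  H <- shannon_index(counts)
  ord <- order(-H, rownames(counts), method = "radix")
  structure(data.frame(family_id = rownames(counts)[ord], score = H[ord],
                       row.names = NULL),
            class = c("ranked_list", "data.frame"))
}

as_ranked <- function(ranked) {
  if (inherits(ranked, "ranked_list") ||
      (is.data.frame(ranked) && all(c("family_id", "score") %in% names(ranked)))) {
    ord <- order(-ranked$score, ranked$family_id, method = "radix")
    setNames(ranked$score[ord], ranked$family_id[ord])
  } else if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked[order(-ranked, names(ranked), method = "radix")]
  } else {
    stop("`ranked` must be a ranked_list or a named score vector")
  }
}

# GMT gene-set I/O ---------------------------------------------------------

#' Read gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member identifiers.
#'
#' @param path file to read.
#' @return a named list of character vectors, with per-set descriptions in
#'   attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT format error at line ", bad[1], ": need name, description, ",
         ">=1 member")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate set names in GMT: ",
         names(sets)[duplicated(names(sets))][1])
  attr(sets, "description") <- setNames(
    vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description optional per-set descriptions (defaults to the
#'   attribute left by [read_gmt()], else `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description))
    description <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description[[nm]], sets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Convert gene sets to ortholog (family) sets
#'
#' Replaces the gene identifiers of each set by their gene-family ids,
#' retaining only unique entries, and applies the enrichment size bounds:
#' sets mapping to fewer than `min_size` or more than `max_size` distinct
#' families are excluded. Sets with no mappable gene at all are dropped
#' with a warning.
#'
#' @param genesets named list of gene id vectors (e.g. from [read_gmt()]).
#' @param gene_to_family named character vector mapping gene id ->
#'   family id.
#' @param min_size,max_size inclusive bounds on the mapped set size
#'   (defaults 3 and 500).
#' @return named list of unique family-id vectors; attribute `"dropped"`
#'   records excluded sets and the reason (`"unmapped"`, `"too_small"`,
#'   `"too_large"`).
#' @export
to_ortholog_sets <- function(genesets, gene_to_family, min_size = 3L,
                             max_size = 500L) {
  if (length(genesets) == 0L) stop("empty gene-set collection")
  if (is.data.frame(gene_to_family))
    gene_to_family <- setNames(gene_to_family[[2]], gene_to_family[[1]])
  mapped <- lapply(genesets, function(g)
    unique(unname(gene_to_family[g[g %in% names(gene_to_family)]])))
  sizes <- lengths(mapped)
  reason <- ifelse(sizes == 0L, "unmapped",
                   ifelse(sizes < min_size, "too_small",
                          ifelse(sizes > max_size, "too_large", "ok")))
  if (any(reason == "unmapped"))
    warning(sum(reason == "unmapped"),
            " set(s) had no mappable genes and were dropped")
  out <- mapped[reason == "ok"]
  attr(out, "dropped") <- setNames(reason[reason != "ok"],
                                   names(genesets)[reason != "ok"])
  out
}

# Enrichment score ---------------------------------------------------------

# Running-sum enrichment score from sorted hit positions. Candidate extrema
# occur immediately after each hit (local maxima of the running sum) and
# immediately before each hit (local minima); positions between hits only
# drift down by the constant miss decrement.
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  if (k == N) return(1)          # no misses: the sum climbs to exactly 1
  W <- sum(w)
  inc <- if (W > 0) cumsum(w) / W else cumsum(rep(1 / k, k))
  miss <- (pos - seq_len(k)) / (N - k)   # misses encountered before hit i
  after <- inc - miss
  before <- c(0, inc[-k]) - miss
  hi <- max(after)
  lo <- min(0, before)
  unname(if (hi >= -lo) hi else lo)
}

#' Preranked enrichment score (weighted running sum)
#'
#' Walks the ranked list; at members of the set the running sum rises by
#' `|score|^p / sum(|score_set|^p)` and at non-members it falls by
#' `1 / (N - |set|)`. The enrichment score is the signed extremum of the
#' running sum, in `[-1, 1]`; when the positive and negative excursions
#' have exactly equal magnitude the positive one is reported. `weight_p =
#' 1` is the conventional weighted statistic; `weight_p = 0` gives the
#' classic (unweighted) Kolmogorov-Smirnov form.
#'
#' @param ranked a `"ranked_list"` (see [rank_families()]) or named score
#'   vector sorted in descending order.
#' @param set character vector of family ids; must be a subset of the
#'   ranked universe.
#' @param weight_p weighting exponent (default 1).
#' @return the enrichment score (numeric scalar).
#' @export
preranked_es <- function(ranked, set, weight_p = 1) {
  scores <- as_ranked(ranked)
  pos <- match(unique(set), names(scores))
  if (anyNA(pos))
    stop("set members missing from the ranked universe: ",
         paste(unique(set)[is.na(pos)], collapse = ", "))
  pos <- sort(pos)
  es_from_positions(pos, abs(scores[pos])^weight_p, length(scores))
}

# Permutation statistics ----------------------------------------------------

#' Permutation p-values, NES and FDR for ortholog sets
#'
#' For each set, draws `n_perm` random same-size family sets from the
#' ranked universe (gene-set permutation, the only null available for a
#' preranked analysis), and derives: the nominal p-value as the fraction of
#' same-sign null scores at least as extreme as the observed one (zero when
#' no null score reaches it), the normalised enrichment score `NES = ES /
#' mean(|null ES| of the same sign)`, and FDR q-values by the empirical
#' NES-ratio procedure (the proportion of null NES beyond the threshold
#' divided by the proportion of observed NES beyond it, capped at 1 and
#' made monotone).
#'
#' @param ranked a `"ranked_list"` or named descending score vector.
#' @param sets named list of family-id sets (e.g. [to_ortholog_sets()]).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed mandatory RNG seed; results are reproducible given the seed.
#' @param weight_p weighting exponent for the running sum (default 1).
#' @return data frame of class `"enrichment_result"`: `set`, `size`, `ES`,
#'   `NES`, `p`, `q`.
#' @export
permutation_stats <- function(ranked, sets, n_perm = 1000L, seed,
                              weight_p = 1) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  if (n_perm < 100L) stop("`n_perm` must be >= 100")
  scores <- as_ranked(ranked)
  N <- length(scores)
  absw <- abs(scores)^weight_p
  sizes <- vapply(sets, function(s) length(unique(s)), integer(1))
  if (any(sizes > N / 2))
    warning("set size exceeds half the universe; the permutation null is ",
            "poorly defined for: ",
            paste(names(sets)[sizes > N / 2], collapse = ", "))
  es_obs <- vapply(sets, function(s) preranked_es(scores, s, weight_p),
                   numeric(1))
  null_es <- matrix(NA_real_, n_perm, length(sets),
                    dimnames = list(NULL, names(sets)))
  with_seed(seed, {
    for (j in seq_along(sets)) {
      k <- sizes[j]
      for (r in seq_len(n_perm)) {
        pos <- sort(sample.int(N, k))
        null_es[r, j] <- es_from_positions(pos, absw[pos], N)
      }
    }
  })
  p <- numeric(length(sets))
  nes <- numeric(length(sets))
  null_nes <- null_es
  for (j in seq_along(sets)) {
    nl <- null_es[, j]
    pos_mean <- mean(abs(nl[nl >= 0]))
    neg_mean <- mean(abs(nl[nl < 0]))
    null_nes[, j] <- ifelse(nl >= 0,
                            if (is.finite(pos_mean) && pos_mean > 0) nl / pos_mean else 0,
                            if (is.finite(neg_mean) && neg_mean > 0) nl / neg_mean else 0)
    if (es_obs[j] >= 0) {
      same <- nl[nl >= 0]
      p[j] <- sum(same >= es_obs[j]) / max(1L, length(same))
      nes[j] <- if (is.finite(pos_mean) && pos_mean > 0)
        es_obs[j] / pos_mean else 0
    } else {
      same <- nl[nl < 0]
      p[j] <- sum(same <= es_obs[j]) / max(1L, length(same))
      nes[j] <- if (is.finite(neg_mean) && neg_mean > 0)
        es_obs[j] / neg_mean else 0
    }
  }
  q <- fdr_from_nes(nes, as.vector(null_nes))
  structure(data.frame(set = names(sets), size = sizes, ES = es_obs,
                       NES = nes, p = p, q = q, row.names = NULL),
            class = c("enrichment_result", "data.frame"),
            n_perm = n_perm, seed = seed)
}

# Empirical NES-ratio FDR: for a positive threshold NES*, q = P(null NES >=
# NES*) / P(observed NES >= NES*), capped at 1, then made monotone from the
# most extreme threshold inward; mirrored for the negative side.
fdr_from_nes <- function(nes, null_nes) {
  q <- rep(NA_real_, length(nes))
  null_pos <- null_nes[null_nes >= 0]
  null_neg <- null_nes[null_nes < 0]
  obs_pos <- nes[nes >= 0]
  obs_neg <- nes[nes < 0]
  for (j in seq_along(nes)) {
    if (nes[j] >= 0) {
      num <- if (length(null_pos)) mean(null_pos >= nes[j]) else 0
      den <- mean(obs_pos >= nes[j])
      q[j] <- min(1, if (den > 0) num / den else 1)
    } else {
      num <- if (length(null_neg)) mean(null_neg <= nes[j]) else 0
      den <- mean(obs_neg <= nes[j])
      q[j] <- min(1, if (den > 0) num / den else 1)
    }
  }
  # monotone cleanup: a more extreme NES never has a larger q
  for (side in c(1, -1)) {
    sel <- which(if (side > 0) nes >= 0 else nes < 0)
    if (length(sel) > 1) {
      ord <- sel[order(side * nes[sel], decreasing = TRUE)]
      q[ord] <- cummax(q[ord])
    }
  }
  q
}

#' Random-panel enrichment experiment
#'
#' Compares the enrichment behaviour of random gene subsets drawn from a
#' biomarker panel against subsets drawn from the whole gene universe:
#' draws `n_sets` subsets of `set_size` genes from each frame, maps them to
#' ortholog sets, computes permutation p-values against the supplied
#' ranking, and reports both p-value vectors and the fractions below 0.05.
#'
#' @param panel character vector of panel gene ids (subset of `universe`).
#' @param universe character vector of all gene ids.
#' @param gene_to_family named character vector mapping gene -> family id.
#' @param ranked a `"ranked_list"` or named descending score vector.
#' @param n_sets number of random subsets per frame (default 100).
#' @param set_size genes per subset (default 100).
#' @param n_perm,weight_p passed to [permutation_stats()].
#' @param seed mandatory RNG seed.
#' @return list with elements `panel_p`, `universe_p` (numeric vectors),
#'   `frac_panel`, `frac_universe` (fractions of p-values < 0.05).
#' @export
random_panel_experiment <- function(panel, universe, gene_to_family, ranked,
                                    n_sets = 100L, set_size = 100L,
                                    n_perm = 1000L, seed, weight_p = 1) {
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  if (!all(panel %in% universe)) stop("`panel` must be a subset of `universe`")
  if (set_size > length(panel))
    stop("`set_size` exceeds the panel size")
  if (n_sets == 0L)
    return(list(panel_p = numeric(0), universe_p = numeric(0),
                frac_panel = NA_real_, frac_universe = NA_real_))
  draw_sets <- function(pool, offset) {
    with_seed(seed + offset, {
      sets <- lapply(seq_len(n_sets), function(i) sample(pool, set_size))
      names(sets) <- sprintf("set%03d", seq_len(n_sets))
      sets
    })
  }
  run <- function(gsets, offset) {
    osets <- suppressWarnings(
      to_ortholog_sets(gsets, gene_to_family, min_size = 3L,
                       max_size = length(as_ranked(ranked))))
    if (length(osets) == 0L) return(numeric(0))
    permutation_stats(ranked, osets, n_perm = n_perm, seed = seed + offset,
                      weight_p = weight_p)$p
  }
  panel_p <- run(draw_sets(panel, 1L), 101L)
  universe_p <- run(draw_sets(universe, 2L), 102L)
  list(panel_p = panel_p, universe_p = universe_p,
       frac_panel = mean(panel_p < 0.05),
       frac_universe = mean(universe_p < 0.05))
}
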