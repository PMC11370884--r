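# Subsampling null distribution for branch statistics ---------------------

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  expr
}

#' Draw subsampling null replicates of branch statistics
#'
#' Builds the empirical null distribution used to judge branch statistics of
#' a target family class: each replicate samples `|target|` families from
#' the null class without replacement (replicates are independent draws, so
#' subsamples may repeat across replicates), reconstructs them under Dollo
#' parsimony, and records per-node gains, per-branch losses and per-leaf
#' presence.
#'
#' The per-family reconstruction is computed once and replicates only
#' re-aggregate it, so large replicate counts are cheap.
#'
#' @param x a `profile_matrix` (copy counts are reduced to presence
#'   internally).
#' @param tree a labelled rooted `phylo`.
#' @param target_class class whose observed statistics will be judged
#'   (default `"disease"`); sets the subsample size.
#' @param null_class class supplying the null pool (default
#'   `"non_disease"`); must contain at least as many families as the target.
#' @param n_reps number of replicates (>= 2; default 1000).
#' @param seed mandatory RNG seed, recorded in the output.
#' @return an object of class `"null_replicates"`: a list with matrices
#'   `gains` (replicates x nodes), `losses` (replicates x branches) and
#'   `presence` (replicates x leaves), plus `n_reps`, `seed`, `target_size`.
#' @export
draw_null_replicates <- function(x, tree, target_class = "disease",
                                 null_class = "non_disease",
                                 n_reps = 1000L, seed) {
  stopifnot(inherits(x, "profile_matrix"))
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  if (n_reps < 2L) stop("`n_reps` must be >= 2 (variance is undefined at 1)")
  idx <- tree_index(tree)
  n_target <- sum(x$class == target_class)
  null_rows <- which(x$class == null_class)
  if (n_target == 0L) stop("no families of target class '", target_class, "'")
  if (length(null_rows) < n_target)
    stop("null pool (", length(null_rows), ") smaller than target size (",
         n_target, ")")
  pres <- x$counts[null_rows, tree$tip.label, drop = FALSE] >= 1L
  rec <- dollo_core(pres, idx)
  gain_ind <- matrix(0L, length(null_rows), idx$nv)
  gain_ind[cbind(seq_along(null_rows), rec$gain)] <- 1L
  loss_ind <- rec$loss * 1L
  internal <- idx$preorder[idx$preorder > idx$ntip]
  branches <- setdiff(c(internal, seq_len(idx$ntip)), idx$root)
  # gains can also occur at leaves (families private to one species); keep
  # those columns only when the pool actually contains such families
  gain_nodes <- internal
  leaf_gains <- colSums(gain_ind[, seq_len(idx$ntip), drop = FALSE])
  if (any(leaf_gains > 0)) gain_nodes <- c(internal, seq_len(idx$ntip))
  gains <- matrix(0L, n_reps, length(gain_nodes),
                  dimnames = list(NULL, idx$labels[gain_nodes]))
  losses <- matrix(0L, n_reps, length(branches),
                   dimnames = list(NULL, idx$labels[branches]))
  presence <- matrix(0L, n_reps, idx$ntip,
                     dimnames = list(NULL, tree$tip.label))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      take <- sample.int(length(null_rows), n_target)
      gains[r, ] <- colSums(gain_ind[take, gain_nodes, drop = FALSE])
      losses[r, ] <- colSums(loss_ind[take, branches, drop = FALSE])
      presence[r, ] <- colSums(pres[take, , drop = FALSE])
    }
  })
  structure(list(gains = gains, losses = losses, presence = presence,
                 n_reps = n_reps, seed = seed, target_size = n_target),
            class = "null_replicates")
}

#' Summarise a subsampling null against observed branch statistics
#'
#' For every statistic (per-node gains, per-branch losses, per-leaf
#' presence) computes the null mean, standard deviation (denominator
#' `n - 1`), standard error of the mean `sd / sqrt(n_reps)`, the one-sided
#' 99% upper limit `mean + 2.326 * se`, and the z-score
#' `(observed - mean) / sd`. When `sd` is zero the z-score is 0 if the
#' observation equals the mean and a signed infinity (with a warning)
#' otherwise.
#'
#' @param replicates a `"null_replicates"` object from
#'   [draw_null_replicates()].
#' @param observed a `"dollo_events"` table ([branch_event_table()]) for the
#'   target class on the same tree.
#' @return a data frame of class `"null_summary"` with columns `statistic`,
#'   `label`, `observed`, `mean`, `sd`, `se`, `upper99`, `z`; attributes
#'   `n_reps` and `seed`.
#' @export
null_summary <- function(replicates, observed) {
  stopifnot(inherits(replicates, "null_replicates"),
            inherits(observed, "dollo_events"))
  pull <- function(mat, stat, obs_col) {
    labs <- colnames(mat)
    obs <- observed[[obs_col]][match(labs, observed$label)]
    data.frame(statistic = stat, label = labs, observed = obs,
               mean = colMeans(mat), sd = apply(mat, 2L, sd))
  }
  df <- rbind(pull(replicates$presence, "presence", "presence"),
              pull(replicates$gains, "gain", "gains"),
              pull(replicates$losses, "loss", "losses"))
  df <- df[!is.na(df$observed), ]
  stats <- null_moment_stats(df$observed, df$mean, df$sd, replicates$n_reps)
  df$se <- stats$se
  df$upper99 <- stats$upper99
  df$z <- stats$z
  rownames(df) <- NULL
  structure(df, class = c("null_summary", "data.frame"),
            n_reps = replicates$n_reps, seed = replicates$seed)
}

#' Derived null statistics from first and second moments
#'
#' The arithmetic layer of [null_summary()], exposed directly so that
#' summary columns can be recomputed from any table of observed values and
#' null moments: `se = sd / sqrt(n_reps)`, `upper99 = mean + 2.326 * se`
#' (one-sided normal 99% limit on the mean) and `z = (observed - mean) / sd`.
#'
#' @param observed,mean,sd numeric vectors of equal length.
#' @param n_reps number of null replicates behind `mean` and `sd`.
#' @return data frame with columns `se`, `upper99`, `z`.
#' @examples
#' null_moment_stats(1583, 1566.0, 4.82, 1000)   # z = 3.53, se = 0.15
#' @export
null_moment_stats <- function(observed, mean, sd, n_reps = 1000L) {
  if (any(sd < 0)) stop("`sd` must be non-negative")
  se <- sd / sqrt(n_reps)
  upper99 <- mean + 2.326 * se
  z <- numeric(length(observed))
  zero <- sd == 0
  z[!zero] <- (observed[!zero] - mean[!zero]) / sd[!zero]
  if (any(zero)) {
    off <- zero & observed != mean
    z[zero] <- 0
    if (any(off)) {
      z[off] <- sign(observed[off] - mean[off]) * Inf
      warning("zero null sd with observed != mean; z reported as +/-Inf")
    }
  }
  data.frame(se = se, upper99 = upper99, z = z)
}

#' One-call subsampling null analysis
#'
#' Convenience wrapper: reconstructs the observed branch events of the
#' target class, draws the subsampling null from the null class, and
#' returns the [null_summary()] table.
#'
#' @inheritParams draw_null_replicates
#' @return a `"null_summary"` data frame.
#' @export
subsample_null <- function(x, tree, target_class = "disease",
                           null_class = "non_disease", n_reps = 1000L, seed) {
  obs <- branch_event_table(binarize(x), tree, class = target_class)
  reps <- draw_null_replicates(x, tree, target_class, null_class,
                               n_reps = n_reps, seed = seed)
  null_summary(reps, obs)
}
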