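# Pure-loss phylogenetic model of pathway content --------------------------
#
# Content size at the root is Poisson(lambda); each ancestral element
# survives each branch b independently with probability s_b in (0, 1], and
# a node's count is the number of elements surviving the root path. There
# are no gains or duplications, so the model obeys Dollo irreversibility at
# the level of counts. Branches carry survival probabilities directly (no
# rate x time factorisation): the study trees carry no time calibration, so
# only the per-branch survival is identifiable.

pl_prep <- function(tree) {
  idx <- tree_index(tree)
  leaf_col <- rep(-1L, idx$nv)
  leaf_col[seq_len(idx$ntip)] <- seq_len(idx$ntip) - 1L
  branch_nodes <- setdiff(seq_len(idx$nv), idx$root)
  # stable branch order: internal first, then terminal, each in preorder
  ord <- c(idx$preorder[idx$preorder > idx$ntip],
           idx$preorder[idx$preorder <= idx$ntip])
  branch_nodes <- ord[ord %in% branch_nodes]
  list(idx = idx, leaf_col = leaf_col, branch_nodes = branch_nodes,
       branch_labels = idx$labels[branch_nodes])
}

as_count_matrix <- function(counts, tree) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  if (is.null(colnames(counts)) || !setequal(colnames(counts), tree$tip.label))
    stop("`counts` must have one named column per tree tip")
  m <- as.matrix(counts[, tree$tip.label, drop = FALSE])
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("leaf counts must be non-negative integers")
  storage.mode(m) <- "integer"
  m
}

default_nmax <- function(counts, lambda) {
  nmax <- max(counts, 0L) + as.integer(ceiling(6 * sqrt(max(lambda, 1))))
  while (ppois(nmax, lambda, lower.tail = FALSE) >= 1e-12)
    nmax <- nmax + as.integer(ceiling(sqrt(max(lambda, 1))))
  nmax
}

#' Construct a pure-loss model
#'
#' Assembles an (unfitted) pure-loss model from a tree, per-branch survival
#' probabilities and a Poisson root-size mean. Use [fit_pure_loss()] to
#' estimate the parameters from data.
#'
#' @param tree a labelled rooted `phylo`.
#' @param survival numeric vector of per-branch survival probabilities in
#'   (0, 1], named by the child node of each branch (every non-root node
#'   must appear), or a single value recycled to all branches.
#' @param lambda positive Poisson mean of the root content size.
#' @return an object of class `"pure_loss"`.
#' @examples
#' m <- pure_loss_model(suite2_tree(), survival = 0.9, lambda = 5)
#' profile_loglik(m, simulate(m, nsim = 3, seed = 1))
#' @export
pure_loss_model <- function(tree, survival, lambda) {
  prep <- pl_prep(tree)
  if (length(survival) == 1L && is.null(names(survival)))
    survival <- setNames(rep(survival, length(prep$branch_labels)),
                         prep$branch_labels)
  if (!all(prep$branch_labels %in% names(survival)))
    stop("`survival` must name every branch by its child node; missing: ",
         paste(setdiff(prep$branch_labels, names(survival)), collapse = ", "))
  survival <- survival[prep$branch_labels]
  if (any(survival <= 0) || any(survival > 1))
    stop("survival probabilities must lie in (0, 1]")
  if (length(lambda) != 1L || lambda <= 0) stop("`lambda` must be > 0")
  structure(list(tree = tree, survival = survival, lambda = lambda,
                 prep = prep),
            class = "pure_loss")
}

pl_surv_by_node <- function(model) {
  prep <- model$prep
  sv <- rep(NA_real_, prep$idx$nv)
  sv[prep$branch_nodes] <- model$survival
  sv
}

#' Log-likelihood of leaf-count profiles under a pure-loss model
#'
#' Exact likelihood by postorder dynamic programming: the child-count
#' transition given a parent count `m` is `Binomial(m, s_b)`, and the
#' Poisson root prior is truncated at `n_max` (chosen so the discarded tail
#' mass is below 1e-12).
#'
#' @param model a `"pure_loss"` object (fitted or constructed).
#' @param counts leaf counts: a named vector over the tree's tips, or a
#'   matrix with one named column per tip and one row per profile.
#' @param n_max optional truncation bound; defaults to
#'   `max(counts) + ceiling(6 * sqrt(lambda))`, raised until the Poisson
#'   tail mass is below 1e-12. Counts above `n_max` are an error.
#' @return numeric vector of per-profile log-likelihoods.
#' @export
profile_loglik <- function(model, counts, n_max = NULL) {
  stopifnot(inherits(model, "pure_loss"))
  m <- as_count_matrix(counts, model$tree)
  if (is.null(n_max)) n_max <- default_nmax(m, model$lambda)
  if (max(m) > n_max)
    stop("leaf count ", max(m), " exceeds n_max = ", n_max,
         "; raise `n_max`")
  prep <- model$prep
  pl_loglik_cpp(m, prep$idx$postorder, prep$idx$parent,
                lengths(prep$idx$children), pl_surv_by_node(model),
                prep$leaf_col, model$lambda, as.integer(n_max))
}

#' Fit the pure-loss model by maximum likelihood
#'
#' Maximises the summed profile log-likelihood over all per-branch survival
#' probabilities and the root Poisson mean, using bounded quasi-Newton
#' (`L-BFGS-B` on logit-transformed survivals and log-transformed lambda)
#' with multi-start from jittered moment-based initial values.
#'
#' @param counts matrix of leaf counts, one row per pathway (profile), one
#'   named column per tree tip.
#' @param tree a labelled rooted `phylo`.
#' @param n_starts number of optimisation restarts (default 5); the first
#'   start uses the moment initialisation, the rest jitter it.
#' @param seed RNG seed for the jitter (default 1).
#' @param control passed to [stats::optim()] (defaults add
#'   `maxit = 300`).
#' @return an object of classes `"pure_loss_fit"`, `"pure_loss"` with the
#'   fitted `survival`, `lambda`, the `logLik`, the truncation `n_max` and
#'   a convergence report (`$fit_report`). Fewer than 10 profiles triggers
#'   a warning; the fit is still returned.
#' @seealso [ancestral_posterior()], [branch_loss_tally()], [rate_tree()]
#' @export
fit_pure_loss <- function(counts, tree, n_starts = 5L, seed = 1L,
                          control = list()) {
  m <- as_count_matrix(counts, tree)
  if (nrow(m) < 10L)
    warning("only ", nrow(m),
            " profile(s); estimates will be unstable (>= 10 recommended)")
  prep <- pl_prep(tree)
  nb <- length(prep$branch_nodes)
  nchild <- lengths(prep$idx$children)
  surv_node <- rep(NA_real_, prep$idx$nv)

  # moment initialisation: root mean from the best-preserved tip, branch
  # survivals from per-tip retention spread along the root path
  tip_means <- colMeans(m)
  lambda0 <- max(max(tip_means) * 1.05, 0.5)
  depth <- prep$idx$depth
  s0 <- numeric(nb)
  for (i in seq_len(nb)) {
    v <- prep$branch_nodes[i]
    tips <- which(prep$idx$clade[v, ])
    ratio <- pmin(pmax(tip_means[tips] / lambda0, 1e-3), 1)
    s0[i] <- mean(ratio^(1 / pmax(depth[tips], 1)))
  }
  s0 <- pmin(pmax(s0, 0.05), 0.98)

  control <- modifyList(list(maxit = 300L), control)
  lower <- c(rep(-9.2, nb), log(1e-3))
  upper <- c(rep(9.2, nb), log(1e5))
  nmax <- default_nmax(m, lambda0)

  negll <- function(par) {
    sv <- surv_node
    sv[prep$branch_nodes] <- plogis(par[seq_len(nb)])
    ll <- pl_loglik_cpp(m, prep$idx$postorder, prep$idx$parent, nchild,
                        sv, prep$leaf_col, exp(par[nb + 1L]),
                        as.integer(nmax))
    v <- -sum(ll)
    if (!is.finite(v)) 1e12 else v
  }

  starts <- with_seed(seed, {
    base <- c(qlogis(s0), log(lambda0))
    lapply(seq_len(n_starts), function(k) {
      if (k == 1L) base else base + rnorm(nb + 1L, sd = 0.7)
    })
  })

  best <- NULL
  report <- data.frame(start = seq_len(n_starts), value = NA_real_,
                       convergence = NA_integer_)
  for (k in seq_len(n_starts)) {
    fit <- tryCatch(
      optim(pmin(pmax(starts[[k]], lower + 0.1), upper - 0.1), negll,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = control),
      error = function(e) NULL)
    if (is.null(fit)) next
    report$value[k] <- fit$value
    report$convergence[k] <- fit$convergence
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("pure-loss optimisation failed in every start")
  if (all(report$convergence != 0, na.rm = TRUE))
    warning("no start reported clean convergence; returning best value found")

  lambda_hat <- exp(best$par[nb + 1L])
  # re-check the truncation at the fitted lambda
  nmax2 <- default_nmax(m, lambda_hat)
  if (nmax2 > nmax) {
    nmax <- nmax2
    best_refit <- tryCatch(
      optim(best$par, negll, method = "L-BFGS-B", lower = lower,
            upper = upper, control = control),
      error = function(e) NULL)
    if (!is.null(best_refit) && best_refit$value < best$value + 1e-6) {
      best <- best_refit
      lambda_hat <- exp(best$par[nb + 1L])
    }
  }

  model <- pure_loss_model(
    tree,
    survival = setNames(plogis(best$par[seq_len(nb)]), prep$branch_labels),
    lambda = lambda_hat)
  model$logLik <- -best$value
  model$n_max <- nmax
  model$n_profiles <- nrow(m)
  model$fit_report <- report
  model$counts <- m
  class(model) <- c("pure_loss_fit", "pure_loss")
  model
}

#' @export
print.pure_loss <- function(x, digits = 3, ...) {
  cat("Pure-loss content model on", length(x$tree$tip.label), "species\n")
  cat("  root size: Poisson(lambda =", format(x$lambda, digits = digits), ")\n")
  cat("  branch survival probabilities:\n")
  print(round(x$survival, digits))
  if (!is.null(x$logLik))
    cat("  log-likelihood:", format(x$logLik, digits = 8),
        "over", x$n_profiles, "profiles\n")
  invisible(x)
}

#' @export
coef.pure_loss <- function(object, ...) {
  c(setNames(object$survival,
             paste0("s_", names(object$survival))),
    lambda = object$lambda)
}

#' @export
logLik.pure_loss_fit <- function(object, ...) {
  structure(object$logLik,
            df = length(object$survival) + 1L,
            nobs = object$n_profiles, class = "logLik")
}

#' @export
summary.pure_loss_fit <- function(object, ...) {
  cat("Maximum-likelihood pure-loss fit\n")
  print(object)
  cat("  truncation n_max:", object$n_max, "\n")
  cat("  expected per-element loss intensity (-log s) totals",
      format(sum(-log(object$survival)), digits = 4), "\n")
  invisible(object)
}

#' Simulate leaf-count profiles from a pure-loss model
#'
#' Draws the root count from `Poisson(lambda)` and thins it down every
#' branch with the branch's survival probability.
#'
#' @param object a `"pure_loss"` model.
#' @param nsim number of profiles.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return integer matrix `nsim x ntips` of leaf counts, with the full
#'   node-count matrix in attribute `"node_counts"` (the simulation truth).
#' @export
simulate.pure_loss <- function(object, nsim = 1, seed = NULL, ...) {
  prep <- object$prep
  idx <- prep$idx
  sv <- pl_surv_by_node(object)
  with_seed(seed, {
    node_counts <- matrix(0L, nsim, idx$nv,
                          dimnames = list(NULL, idx$labels))
    node_counts[, idx$root] <- rpois(nsim, object$lambda)
    for (v in idx$preorder[-1])
      node_counts[, v] <- rbinom(nsim, node_counts[, idx$parent[v]], sv[v])
    out <- node_counts[, seq_len(idx$ntip), drop = FALSE]
    colnames(out) <- object$tree$tip.label
    attr(out, "node_counts") <- node_counts
    out
  })
}

#' Loss-rate tree of a pure-loss model
#'
#' Returns the model tree with branch lengths set to `-log(s_b)`, the
#' expected per-element loss intensity of each branch; a survival of 1 maps
#' to length 0. Emit with [ape::write.tree()] for newick output.
#'
#' @param model a `"pure_loss"` object.
#' @return a `phylo` with branch lengths.
#' @export
rate_tree <- function(model) {
  stopifnot(inherits(model, "pure_loss"))
  if (any(model$survival <= 0))
    stop("survival probability 0 implies infinite branch length")
  tree <- model$tree
  child <- tree$edge[, 2]
  labs <- model$prep$idx$labels[child]
  tree$edge.length <- unname(-log(model$survival[labs]))
  tree
}

# Upward (pruning) pass in plain R, returning per-node conditional
# likelihood vectors and the per-branch child-marginalisation vectors, both
# max-scaled. Shared by the posterior machinery.
pl_upward <- function(model, obs, n_max) {
  prep <- model$prep
  idx <- prep$idx
  K <- n_max + 1L
  sv <- pl_surv_by_node(model)
  B <- vector("list", idx$nv)
  for (v in seq_len(idx$nv)) {
    if (v == idx$root) next
    B[[v]] <- outer(0:n_max, 0:n_max,
                    function(m, k) dbinom(k, m, sv[v]))
  }
  L <- vector("list", idx$nv)
  M <- vector("list", idx$nv)   # M[[c]][m] = sum_k B_c[m,k] L_c[k]
  for (v in idx$postorder) {
    if (v <= idx$ntip) {
      L[[v]] <- numeric(K)
      L[[v]][obs[v] + 1L] <- 1
    } else {
      acc <- rep(1, K)
      for (c in idx$children[[v]]) {
        M[[c]] <- as.vector(B[[c]] %*% L[[c]])
        acc <- acc * M[[c]]
      }
      mx <- max(acc)
      if (mx <= 0) return(NULL)   # impossible data
      L[[v]] <- acc / mx
    }
    if (v != idx$root && is.null(M[[v]]) && v <= idx$ntip) {
      M[[v]] <- as.vector(B[[v]] %*% L[[v]])
    }
  }
  list(L = L, M = M, B = B)
}

#' Ancestral count posteriors under a pure-loss model
#'
#' Runs an inside-outside (upward-downward) pass per profile, yielding the
#' exact conditional distribution of the content count at every tree node
#' given all leaf counts, together with the joint parent-child branch event
#' probabilities needed by [branch_loss_tally()]: for each branch, the
#' probability that the pathway was lost on it (parent count >= 1, child
#' count 0) and that it contracted (parent >= 2, child exactly 1).
#'
#' @param model a `"pure_loss"` object (fitted or constructed).
#' @param counts leaf counts as in [profile_loglik()].
#' @param n_max optional truncation bound (see [profile_loglik()]).
#' @return an object of class `"ancestral_posterior"`: a list with
#'   `posterior` (list over profiles of `nodes x (0..n_max)` matrices, rows
#'   summing to 1), `events` (list over profiles of `branches x 2` matrices
#'   `[, c("lost", "contracted")]`), `tree`, `n_max`.
#' @export
ancestral_posterior <- function(model, counts, n_max = NULL) {
  stopifnot(inherits(model, "pure_loss"))
  m <- as_count_matrix(counts, model$tree)
  if (is.null(n_max)) n_max <- default_nmax(m, model$lambda)
  if (max(m) > n_max)
    stop("leaf count exceeds n_max = ", n_max, "; raise `n_max`")
  prep <- model$prep
  idx <- prep$idx
  K <- n_max + 1L
  prior <- dpois(0:n_max, model$lambda)
  branch_labels <- prep$branch_labels
  posterior <- vector("list", nrow(m))
  events <- vector("list", nrow(m))

  for (p in seq_len(nrow(m))) {
    obs <- integer(idx$nv)
    obs[seq_len(idx$ntip)] <- m[p, ]
    up <- pl_upward(model, obs, n_max)
    if (is.null(up)) stop("profile ", p, " has zero likelihood")
    G <- vector("list", idx$nv)
    G[[idx$root]] <- prior
    post <- matrix(0, idx$nv, K, dimnames = list(idx$labels, 0:n_max))
    ev <- matrix(0, length(branch_labels), 2L,
                 dimnames = list(branch_labels, c("lost", "contracted")))
    for (v in idx$preorder) {
      pv <- G[[v]] * up$L[[v]]
      post[v, ] <- pv / sum(pv)
      kids <- idx$children[[v]]
      for (c in kids) {
        prodsib <- rep(1, K)
        for (c2 in setdiff(kids, c)) prodsib <- prodsib * up$M[[c2]]
        Gmsg <- G[[v]] * prodsib
        G[[c]] <- as.vector(t(up$B[[c]]) %*% Gmsg)
        mx <- max(G[[c]])
        if (mx > 0) G[[c]] <- G[[c]] / mx
        # joint parent-child table for branch events
        J <- (Gmsg * up$B[[c]]) * rep(up$L[[c]], each = K)
        tot <- sum(J)
        if (tot > 0) {
          J <- J / tot
          lab <- idx$labels[c]
          ev[lab, "lost"] <- sum(J[2:K, 1L])
          if (K >= 3L) ev[lab, "contracted"] <- sum(J[3:K, 2L])
        }
      }
    }
    posterior[[p]] <- post
    events[[p]] <- ev
  }
  structure(list(posterior = posterior, events = events, tree = model$tree,
                 n_max = n_max, branch_labels = branch_labels),
            class = "ancestral_posterior")
}

#' Expected pathway losses and contractions per branch
#'
#' Sums, over all pathways, the posterior probability that the pathway was
#' lost on each branch (parent content >= 1, child content 0) and that it
#' contracted to a single element (parent >= 2, child exactly 1), and
#' expresses both as percentages of the pathway set. Per-lineage cumulative
#' loss percentages (root-to-leaf sums) are attached as attribute
#' `"lineage"`.
#'
#' @param posteriors an `"ancestral_posterior"` object covering all
#'   pathways (or a list of such objects on the same tree, concatenated).
#' @return data frame with columns `branch`, `expected_lost`,
#'   `expected_contracted`, `pct_lost`, `pct_contracted`.
#' @export
branch_loss_tally <- function(posteriors) {
  if (inherits(posteriors, "ancestral_posterior"))
    posteriors <- list(posteriors)
  trees <- lapply(posteriors, function(x) x$tree)
  for (t2 in trees[-1])
    if (!identical(ape::write.tree(t2), ape::write.tree(trees[[1]])))
      stop("posteriors computed on different trees cannot be combined")
  ev_list <- do.call(c, lapply(posteriors, `[[`, "events"))
  n_path <- length(ev_list)
  total <- Reduce(`+`, ev_list)
  out <- data.frame(branch = rownames(total),
                    expected_lost = total[, "lost"],
                    expected_contracted = total[, "contracted"],
                    pct_lost = 100 * total[, "lost"] / n_path,
                    pct_contracted = 100 * total[, "contracted"] / n_path)
  rownames(out) <- NULL
  idx <- tree_index(trees[[1]])
  lineage <- data.frame(
    leaf = trees[[1]]$tip.label,
    pct_lost = vapply(seq_along(trees[[1]]$tip.label), function(t) {
      path <- setdiff(root_path(idx, t), idx$root)
      sum(out$pct_lost[match(idx$labels[path], out$branch)])
    }, numeric(1)))
  attr(out, "lineage") <- lineage
  attr(out, "n_pathways") <- n_path
  out
}
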