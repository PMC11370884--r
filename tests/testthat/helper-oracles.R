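# Independent oracles used across the suite.

# --- Dollo: exhaustive minimum-loss search ---------------------------------
#
# Enumerates every 0/1 assignment to the internal nodes, keeps those with a
# single gain (one 0->1 transition, counting a presence at the root as the
# gain), and minimises the loss count. Returns per-profile gain node, loss
# incidence over nodes, and whether the minimum was attained by a unique
# assignment. `pres` is a profiles x tips logical/0-1 matrix in tree tip
# order.
dollo_oracle_tree <- function(tree, pres) {
  idx <- orthotrace:::tree_index(tree)
  ntip <- idx$ntip
  internal <- setdiff(seq_len(idx$nv), seq_len(ntip))
  nI <- length(internal)
  nA <- 2^nI
  A <- matrix(0L, nA, nI)
  for (j in seq_len(nI)) A[, j] <- (seq_len(nA) - 1L) %/% 2^(j - 1L) %% 2L
  nP <- nrow(pres)
  st <- matrix(0L, nA * nP, idx$nv)
  st[, seq_len(ntip)] <- (pres * 1L)[rep(seq_len(nP), each = nA), , drop = FALSE]
  st[, internal] <- A[rep(seq_len(nA), times = nP), , drop = FALSE]
  nonroot <- setdiff(seq_len(idx$nv), idx$root)
  P <- st[, idx$parent[nonroot], drop = FALSE]
  C <- st[, nonroot, drop = FALSE]
  gains <- st[, idx$root] + rowSums(P == 0L & C == 1L)
  losses <- rowSums(P == 1L & C == 0L)
  grp <- rep(seq_len(nP), each = nA)
  losses[gains != 1L] <- NA_integer_
  best <- tapply(losses, grp, min, na.rm = TRUE)
  is_best <- !is.na(losses) & losses == best[grp]
  n_best <- tapply(is_best, grp, sum)
  pick <- vapply(seq_len(nP), function(p)
    which(is_best & grp == p)[1], integer(1))
  gain_node <- vapply(pick, function(r) {
    if (st[r, idx$root] == 1L) return(idx$root)
    nonroot[which(P[r, ] == 0L & C[r, ] == 1L)]
  }, integer(1))
  loss_mat <- matrix(FALSE, nP, idx$nv)
  for (p in seq_len(nP))
    loss_mat[p, nonroot[P[pick[p], ] == 1L & C[pick[p], ] == 0L]] <- TRUE
  list(gain = gain_node, loss = loss_mat, min_losses = as.integer(best),
       unique = n_best == 1L, labels = idx$labels)
}

dollo_oracle <- function(tree, profile) {
  pres <- matrix(as.logical(profile[tree$tip.label]), nrow = 1)
  res <- dollo_oracle_tree(tree, pres)
  list(gain = res$labels[res$gain],
       losses = sort(res$labels[which(res$loss[1, ])]),
       unique = res$unique[1])
}

# label every node of an unlabelled topology so tree_index() accepts it
label_tree <- function(tree) {
  tree$node.label <- paste0("I", seq_len(tree$Nnode))
  tree
}

all_profiles <- function(ntip) {
  m <- as.matrix(expand.grid(rep(list(0:1), ntip)))[-1, , drop = FALSE]
  storage.mode(m) <- "logical"
  m
}

# --- Pure loss: enumeration over root sizes and element fates --------------
#
# Enumerates each ancestral element's branch-survival outcomes (2^branches
# patterns), convolves N i.i.d. elements over capped per-node count states,
# and sums over root sizes N = 0..Nmax weighted by the Poisson prior. This
# shares no code path with the pruning algorithm: it never forms binomial
# transition matrices. Entries of per-node posteriors are exact for counts
# below `cap` (the top bin lumps >= cap).
#
# obs_list: list of named leaf-count vectors. Returns, per observation,
# the likelihood, the root-size posterior (0..Nmax), per-non-root-node
# posteriors (rows = nodes in `labels` order, cols = 0..cap), and expected
# branch loss/contraction probabilities.
oracle_pureloss <- function(tree, survival, lambda, obs_list,
                            Nmax = 30L, cap = NULL) {
  idx <- orthotrace:::tree_index(tree)
  nonroot <- setdiff(seq_len(idx$nv), idx$root)
  nb <- length(nonroot)
  sv <- setNames(rep(NA_real_, idx$nv), idx$labels)
  sv[names(survival)] <- survival
  stopifnot(!anyNA(sv[nonroot]))
  # element fate patterns over branches -> alive indicator per node
  pats <- as.matrix(expand.grid(rep(list(0:1), nb)))
  alive <- matrix(0L, nrow(pats), idx$nv)
  alive[, idx$root] <- 1L
  for (v in idx$preorder[-1]) {
    j <- match(v, nonroot)
    alive[, v] <- alive[, idx$parent[v]] * pats[, j]
  }
  pprob <- apply(pats, 1, function(r)
    prod(ifelse(r == 1, sv[nonroot], 1 - sv[nonroot])))
  key <- apply(alive[, nonroot, drop = FALSE], 1, paste, collapse = ",")
  agg <- rowsum(pprob, key)
  upat <- do.call(rbind, lapply(strsplit(rownames(agg), ","), as.integer))
  pp <- agg[, 1]

  if (is.null(cap)) cap <- max(unlist(obs_list)) + 6L
  mult <- cumprod(c(1, rep(cap + 1L, nb - 1L)))
  S <- (cap + 1L)^nb
  state_mat <- as.matrix(expand.grid(rep(list(0:cap), nb)))
  maps <- lapply(seq_len(nrow(upat)), function(i) {
    ns <- sweep(state_mat, 2L, upat[i, ], `+`)
    ns[ns > cap] <- cap
    as.integer(ns %*% mult) + 1L
  })
  leaf_pos <- match(seq_len(idx$ntip), nonroot)
  match_rows <- lapply(obs_list, function(obs) {
    ov <- obs[tree$tip.label]
    which(rowSums(sweep(state_mat[, leaf_pos, drop = FALSE], 2L, ov,
                        `!=`) != 0) == 0)
  })

  out <- lapply(obs_list, function(o) list(
    lik = 0, root_post = numeric(Nmax + 1L),
    node_post = matrix(0, nb, cap + 1L,
                       dimnames = list(idx$labels[nonroot], 0:cap)),
    events = matrix(0, nb, 2L,
                    dimnames = list(idx$labels[nonroot],
                                    c("lost", "contracted")))))

  dist <- numeric(S)
  dist[1L] <- 1
  for (N in 0:Nmax) {
    wN <- dpois(N, lambda)
    for (oi in seq_along(obs_list)) {
      mr <- match_rows[[oi]]
      w <- wN * dist[mr]
      tw <- sum(w)
      if (tw == 0) next
      out[[oi]]$lik <- out[[oi]]$lik + tw
      out[[oi]]$root_post[N + 1L] <- out[[oi]]$root_post[N + 1L] + tw
      sm <- state_mat[mr, , drop = FALSE]
      for (j in seq_len(nb)) {
        tab <- rowsum(w, sm[, j])
        cnt <- as.integer(rownames(tab)) + 1L
        out[[oi]]$node_post[j, cnt] <- out[[oi]]$node_post[j, cnt] + tab[, 1]
        v <- nonroot[j]
        p <- idx$parent[v]
        pc <- if (p == idx$root) rep(N, length(mr)) else sm[, match(p, nonroot)]
        out[[oi]]$events[j, 1L] <- out[[oi]]$events[j, 1L] +
          sum(w[pc >= 1 & sm[, j] == 0])
        out[[oi]]$events[j, 2L] <- out[[oi]]$events[j, 2L] +
          sum(w[pc >= 2 & sm[, j] == 1])
      }
    }
    if (N < Nmax) {
      nd <- numeric(S)
      for (i in seq_along(pp)) {
        rs <- rowsum(pp[i] * dist, maps[[i]])
        pos <- as.integer(rownames(rs))
        nd[pos] <- nd[pos] + rs[, 1]
      }
      dist <- nd
    }
  }
  for (oi in seq_along(out)) {
    L <- out[[oi]]$lik
    if (L > 0) {
      out[[oi]]$root_post <- out[[oi]]$root_post / L
      out[[oi]]$node_post <- out[[oi]]$node_post / L
      out[[oi]]$events <- out[[oi]]$events / L
    }
  }
  out
}

# --- small fixtures --------------------------------------------------------

toy_profiles <- function(counts, class = "unlabeled", species = NULL) {
  if (is.null(species)) species <- colnames(counts)
  profile_matrix(counts, class, anchor = NULL)
}

suite1_species <- function() suite1_tree()$tip.label
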