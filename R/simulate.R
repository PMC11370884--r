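# Synthetic data generator -------------------------------------------------
#
# Generates every pipeline input with the statistical structure the
# analysis assumes: single-origin (Dollo) family profiles with
# branch-specific loss and post-gain duplication, disease labels enriched
# at deep origins, pathways whose reactions are more conserved than their
# genes (a reaction survives if any member gene survives), and gene sets
# with a controlled conservation bias. Default magnitudes are anchored to
# the bundled reference tables: 10,441 families split 1597 / 7446 / 1398
# over disease / non-disease / mixed, origin distributions taken from the
# reference per-node gain counts, per-branch loss probabilities
# back-computed from the reference per-branch loss tallies relative to the
# families at risk, and pathway sizes log-normal with mean 29 genes and 11
# reactions. `scale` shrinks the family/pathway counts (not the sizes) for
# desk-scale work.

suite1_loss_probs <- function() c(
  Vertebrata = 0, Tetrapoda = 0, Mammalia = 0, Homo_sapiens = 0,
  Mus_musculus = 0.009, Xenopus_tropicalis = 0.04, Fish = 0.008,
  Danio_rerio = 0.016, Fundulus_heteroclitus = 0.023,
  Ecdysozoa = 0.02, Arthropoda = 0.018, Hexapoda = 0.13, Diptera = 0.065,
  Drosophila_melanogaster = 0.087, Anopheles_gambiae = 0.11,
  Nasonia_vitripennis = 0.084, Crustacea = 0.026, Cladocera = 0.057,
  Daphnia_magna = 0.103, Daphnia_pulex = 0.058, Hyalella_azteca = 0.108,
  Caenorhabditis_elegans = 0.36)

suite2_loss_probs <- function() c(
  Vertebrata = 0, Tetrapoda = 0, Amniota = 0, Mammalia = 0,
  Homo_sapiens = 0, Rodentia = 0.08, Mus_musculus = 0.12,
  Rattus_norvegicus = 0.14, Gallus_gallus = 0.30,
  Xenopus_tropicalis = 0.32, Danio_rerio = 0.38, Ecdysozoa = 0.35,
  Drosophila_melanogaster = 0.45, Caenorhabditis_elegans = 0.57)

#' Configuration of the synthetic-data generator
#'
#' Collects every knob of the generator with study-anchored defaults; the
#' defaults are the generating conditions, `scale` only shrinks the family
#' and pathway counts for desk-scale runs.
#'
#' @param preset `"suite1"` (12-species gene-family study) or `"suite2"`
#'   (8-species pathway study); chooses the tree, the class split, the
#'   origin distributions and the branch loss probabilities.
#' @param scale multiplier (0, 1] on family/pathway/set counts.
#' @param seed mandatory RNG seed.
#' @param ... named overrides of any config field.
#' @return a list of class `"generator_config"`.
#' @export
generator_config <- function(preset = c("suite1", "suite2"), scale = 1,
                             seed, ...) {
  preset <- match.arg(preset)
  if (missing(seed) || is.null(seed)) stop("`seed` is required")
  if (scale <= 0 || scale > 1) stop("`scale` must be in (0, 1]")
  origin <- if (preset == "suite1") {
    list(
      disease = c(Bilateria = 1133, Vertebrata = 372, Tetrapoda = 33,
                  Mammalia = 59) / 1597,
      non_disease = c(Bilateria = 940.7, Vertebrata = 401.9,
                      Tetrapoda = 71.5, Mammalia = 182.9) / 1597,
      mixed = c(Bilateria = 0.82, Vertebrata = 0.12, Tetrapoda = 0.02,
                Mammalia = 0.04))
  } else {
    list(
      disease = c(Bilateria = 0.71, Vertebrata = 0.23, Tetrapoda = 0.02,
                  Mammalia = 0.04),
      non_disease = c(Bilateria = 0.59, Vertebrata = 0.25, Tetrapoda = 0.045,
                      Mammalia = 0.115),
      mixed = c(Bilateria = 0.82, Vertebrata = 0.12, Tetrapoda = 0.02,
                Mammalia = 0.04))
  }
  cfg <- list(
    preset = preset,
    tree = if (preset == "suite1") suite1_tree() else suite2_tree(),
    anchor = "Homo_sapiens",
    scale = scale,
    seed = seed,
    n_families = round(10441 * scale),
    class_fractions = c(disease = 1597, non_disease = 7446,
                        mixed = 1398) / 10441,
    origin_probs = origin,
    loss_prob = if (preset == "suite1") suite1_loss_probs()
                else suite2_loss_probs(),
    dup_prob = 0.08,
    dup_mean = 2,
    genes_per_family_rate = 0.8,
    n_pathways = round(1508 * scale),
    disease_pathway_frac = 351 / 1508,
    pathway_size_meanlog = log(29) - 0.8^2 / 2,
    pathway_size_sdlog = 0.8,
    reactions_meanlog = log(11) - 0.6^2 / 2,
    reactions_sdlog = 0.6,
    genes_per_reaction = c(1L, 4L),
    n_sets = c(conserved = 10L, recent = 5L, neutral = 35L),
    set_size_range = c(19L, 132L))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  for (pr in cfg$origin_probs)
    if (any(pr < 0) || abs(sum(pr) - 1) > 1e-6)
      stop("origin probabilities must be non-negative and sum to 1")
  if (any(cfg$loss_prob < 0) || any(cfg$loss_prob > 1))
    stop("loss probabilities must lie in [0, 1]")
  structure(cfg, class = "generator_config")
}

#' Simulate gene-family profiles with known evolutionary events
#'
#' Each family gains once at a node drawn from its class's origin
#' distribution along the root-to-anchor path, is inherited down the tree,
#' lost on each branch with the branch's loss probability, and duplicated
#' (geometric extra copies) with the branch duplication probability.
#' Families that lose the anchor species are redrawn, enforcing the
#' human-anchored study design. Human genes and a morbid-gene list are
#' emitted so that [classify_families()] reproduces the class labels.
#'
#' @param config a [generator_config()].
#' @return list with `profiles` (a [profile_matrix()]), `truth` (data
#'   frame: `family_id`, `class`, `gain`, `losses` as a comma-joined
#'   string, `n_genes`), `family_genes` (named list), `morbid_genes`,
#'   `gene_to_family` (named character vector).
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  tree <- config$tree
  idx <- tree_index(tree)
  anchor_tip <- match(config$anchor, idx$labels)
  if (is.na(anchor_tip)) stop("anchor species missing from tree")
  path <- root_path(idx, anchor_tip)
  miss <- setdiff(names(config$loss_prob), idx$labels)
  if (length(miss)) stop("loss_prob names not on tree: ",
                         paste(miss, collapse = ", "))
  lp <- setNames(rep(0, idx$nv), idx$labels)
  lp[names(config$loss_prob)] <- config$loss_prob
  if (any(lp[setdiff(path, idx$root)] >= 1))
    stop("infeasible config: loss probability 1 on the anchor path")

  n <- config$n_families
  with_seed(config$seed, {
    cls <- sample(names(config$class_fractions), n, replace = TRUE,
                  prob = config$class_fractions)
    gain <- integer(n)
    for (cl in unique(cls)) {
      pr <- config$origin_probs[[cl]]
      nodes <- match(names(pr), idx$labels)
      if (anyNA(nodes)) stop("origin node missing from tree: ",
                             paste(names(pr)[is.na(nodes)], collapse = ", "))
      if (!all(nodes %in% path))
        stop("origin nodes must lie on the root-to-anchor path")
      rows <- which(cls == cl)
      gain[rows] <- nodes[sample.int(length(nodes), length(rows),
                                     replace = TRUE, prob = pr)]
    }

    sim_block <- function(gain_block) {
      nf <- length(gain_block)
      alive <- matrix(FALSE, nf, idx$nv)
      cnt <- matrix(0L, nf, idx$nv)
      alive[cbind(seq_len(nf), gain_block)] <- TRUE
      cnt[cbind(seq_len(nf), gain_block)] <- 1L
      gain_anc <- idx$anc[gain_block, , drop = FALSE]
      for (v in idx$preorder[-1]) {
        below <- gain_anc[, v] & gain_block != v
        surv <- runif(nf) >= lp[v]
        av <- alive[, idx$parent[v]] & surv & below
        alive[below, v] <- av[below]
        dup <- (runif(nf) < config$dup_prob) & av
        extra <- integer(nf)
        if (config$dup_mean > 1)
          extra[dup] <- 1L + rgeom(sum(dup), 1 / config$dup_mean)
        else extra[dup] <- 1L
        cv <- ifelse(av, cnt[, idx$parent[v]] + extra, 0L)
        cnt[below, v] <- cv[below]
      }
      list(alive = alive, cnt = cnt)
    }

    blk <- sim_block(gain)
    tries <- 0L
    repeat {
      bad <- which(!blk$alive[, anchor_tip])
      if (length(bad) == 0L) break
      tries <- tries + 1L
      if (tries > 1000L)
        stop("infeasible config: anchor constraint keeps failing")
      redo <- sim_block(gain[bad])
      blk$alive[bad, ] <- redo$alive
      blk$cnt[bad, ] <- redo$cnt
    }

    fam_ids <- sprintf("F%05d", seq_len(n))
    counts <- blk$cnt[, seq_len(idx$ntip), drop = FALSE]
    dimnames(counts) <- list(fam_ids, tree$tip.label)
    profiles <- profile_matrix(counts, cls, anchor = config$anchor)

    # true loss branches: alive parent, dead child, inside the gain clade
    losses <- character(n)
    for (f in seq_len(n)) {
      inside <- setdiff(which(idx$anc[gain[f], ]), gain[f])
      lost <- inside[!blk$alive[f, inside] &
                       blk$alive[f, idx$parent[inside]]]
      losses[f] <- paste(idx$labels[lost], collapse = ",")
    }

    n_genes <- ifelse(cls == "mixed",
                      2L + rpois(n, config$genes_per_family_rate),
                      1L + rpois(n, config$genes_per_family_rate))
    family_genes <- lapply(seq_len(n), function(f)
      paste0(fam_ids[f], "_g", seq_len(n_genes[f])))
    names(family_genes) <- fam_ids
    morbid <- character(0)
    for (f in which(cls == "disease")) morbid <- c(morbid, family_genes[[f]])
    for (f in which(cls == "mixed"))
      morbid <- c(morbid,
                  family_genes[[f]][seq_len(sample.int(n_genes[f] - 1L, 1))])
    gene_to_family <- setNames(rep(fam_ids, n_genes), unlist(family_genes))

    list(profiles = profiles,
         truth = data.frame(family_id = fam_ids, class = cls,
                            gain = idx$labels[gain], losses = losses,
                            n_genes = n_genes),
         family_genes = family_genes,
         morbid_genes = morbid,
         gene_to_family = gene_to_family)
  })
}

#' Simulate pathway conservation records
#'
#' Pathway genes are families drawn from a simulated profile matrix; a gene
#' is conserved in a species iff its family is present there, and a
#' reaction is conserved iff at least one of its member genes is. The
#' reaction rule is what makes reactions systematically more conserved
#' than the genes that implement them.
#'
#' @param config a [generator_config()] (normally `preset = "suite2"`).
#' @param sim output of [simulate_profiles()]; simulated afresh from
#'   `config` when `NULL`.
#' @return list with `records` (pathway data frame as in
#'   [read_pathway_table()]), `truth` (list: `members` family vectors and
#'   `reactions` member-index lists per pathway), and `sim` (the profile
#'   simulation used).
#' @export
simulate_pathways <- function(config, sim = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(sim)) sim <- simulate_profiles(config)
  pres <- sim$profiles$counts >= 1L
  fam_ids <- rownames(pres)
  species <- setdiff(colnames(pres), config$anchor)
  n <- config$n_pathways
  with_seed(config$seed + 1L, {
    sizes <- pmin(pmax(3L, round(rlnorm(n, config$pathway_size_meanlog,
                                        config$pathway_size_sdlog))),
                  length(fam_ids))
    if (any(sizes > length(fam_ids)))
      stop("pathway larger than the family universe")
    n_react <- pmax(1L, round(rlnorm(n, config$reactions_meanlog,
                                     config$reactions_sdlog)))
    disease <- runif(n) < config$disease_pathway_frac
    members <- vector("list", n)
    reactions <- vector("list", n)
    gcols <- matrix(0L, n, length(species),
                    dimnames = list(NULL, species))
    rcols <- matrix(0L, n, length(species),
                    dimnames = list(NULL, species))
    for (i in seq_len(n)) {
      fams <- sample(fam_ids, sizes[i])
      members[[i]] <- fams
      rx <- lapply(seq_len(n_react[i]), function(r)
        sample.int(sizes[i],
                   min(sizes[i],
                       sample(seq(config$genes_per_reaction[1],
                                  config$genes_per_reaction[2]), 1))))
      reactions[[i]] <- rx
      pmat <- pres[fams, species, drop = FALSE]
      gcols[i, ] <- colSums(pmat)
      for (s in seq_along(species))
        rcols[i, s] <- sum(vapply(rx, function(r) any(pmat[r, s]),
                                  logical(1)))
    }
    records <- data.frame(pathway_id = sprintf("PW%04d", seq_len(n)),
                          name = sprintf("synthetic pathway %d", seq_len(n)),
                          disease = disease,
                          n_genes = sizes,
                          n_reactions = n_react,
                          is_terminal = TRUE,
                          check.names = FALSE)
    for (s in species) {
      records[[species_col(s, "genes")]] <- gcols[, s]
      records[[species_col(s, "reactions")]] <- rcols[, s]
    }
    validate_pathway_table(records)
    list(records = records,
         truth = list(members = members, reactions = reactions),
         sim = sim)
  })
}

#' Simulate gene sets with controlled conservation bias
#'
#' Builds gene sets whose families are drawn from the top Shannon-index
#' quartile ("conserved"-biased), the bottom quartile ("recent"-biased) or
#' uniformly ("neutral"), returning the truth labels for calibration and
#' power studies of the enrichment machinery.
#'
#' @param config a [generator_config()]; `config$n_sets` gives the number
#'   of sets per bias type and `config$set_size_range` the size range.
#' @param sim output of [simulate_profiles()].
#' @return list with `genesets` (named list of gene-id sets), `truth`
#'   (data frame: `set`, `bias`, `size`), `gene_to_family`.
#' @export
simulate_gene_sets <- function(config, sim) {
  stopifnot(inherits(config, "generator_config"))
  H <- shannon_index(sim$profiles$counts)
  qs <- quantile(H, c(0.25, 0.75))
  pools <- list(conserved = names(H)[H >= qs[2]],
                recent = names(H)[H <= qs[1]],
                neutral = names(H))
  if (any(lengths(pools) == 0L)) stop("empty Shannon quartile pool")
  if (any(config$set_size_range < 1L)) stop("set sizes must be >= 1")
  n_sets <- config$n_sets
  with_seed(config$seed + 2L, {
    genesets <- list()
    truth <- NULL
    counter <- 0L
    for (bias in names(n_sets)) {
      for (i in seq_len(n_sets[[bias]])) {
        counter <- counter + 1L
        size <- sample(seq(config$set_size_range[1],
                           config$set_size_range[2]), 1L)
        size <- min(size, length(pools[[bias]]))
        fams <- sample(pools[[bias]], size)
        genes <- vapply(fams, function(f) sample(sim$family_genes[[f]], 1L),
                        character(1))
        # occasionally add a second paralog to exercise unique-mapping
        extra <- fams[runif(length(fams)) < 0.1]
        genes <- c(genes, vapply(extra, function(f)
          sample(sim$family_genes[[f]], 1L), character(1)))
        nm <- sprintf("%s_%03d", toupper(bias), i)
        genesets[[nm]] <- unique(unname(genes))
        truth <- rbind(truth, data.frame(set = nm, bias = bias,
                                         size = length(fams)))
      }
    }
    list(genesets = genesets, truth = truth,
         gene_to_family = sim$gene_to_family)
  })
}
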