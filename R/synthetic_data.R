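#' Default synthetic-study configuration
#'
#' Reads the versioned generator configuration shipped with the package
#' (`extdata/sim_config.json`). These values define the default study
#' conditions of the synthetic pipeline: a 100-species ultrametric phylogeny;
#' a 2000-reaction universe with a 700-reaction unlosable core; gain/loss
#' rates with stationary presence probability 0.35 for accessory reactions and
#' a total switching rate of 0.3 per time unit (roughly 1.4 expected
#' state-change scale over the height of a 100-leaf Yule tree with unit birth
#' rate); one ortholog family per reaction plus 1000 independently evolving
#' non-metabolic families; 32 substrate traits, each requiring 3 reactions,
#' with 30% label-flip noise and 1% missing entries.
#'
#' @return Named list of generator parameters.
#' @export
default_sim_config <- function() {
  path <- system.file("extdata", "sim_config.json", package = "panreactome",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Simulate an ultrametric species tree (Yule process)
#'
#' Pure-birth tree conditioned on the number of leaves, so all leaves are at
#' the same depth (ultrametric). Leaves are labelled `s001`, `s002`, ...
#'
#' @param n_leaves Number of species (>= 2).
#' @param birth_rate Speciation rate per lineage per time unit.
#' @param seed Integer seed.
#' @return List with `tree` (a `phylo`) and `newick` (character).
#' @export
simulate_tree <- function(n_leaves, birth_rate = 1, seed) {
  if (n_leaves < 2L) stop("n_leaves must be >= 2", call. = FALSE)
  if (birth_rate <= 0) stop("birth_rate must be positive", call. = FALSE)
  set.seed(seed)
  tr <- ape::rphylo(n_leaves, birth = birth_rate, death = 0)
  tr$tip.label <- sprintf("s%03d", seq_len(n_leaves))
  list(tree = tr, newick = ape::write.tree(tr))
}

# Two-state (absent/present) continuous-time Markov chain simulated down the
# tree for n_items independent characters. Over a branch of length t:
#   P(0 -> 1) = pi * (1 - exp(-(lg + ll) t))
#   P(1 -> 1) = pi + (1 - pi) * exp(-(lg + ll) t),   pi = lg / (lg + ll).
# Consumes the RNG stream; caller seeds.
sim_gain_loss <- function(tree, n_items, gain_rate, loss_rate, root_state) {
  nu <- gain_rate + loss_rate
  pi1 <- if (nu > 0) gain_rate / nu else 0
  n <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  E <- po$edge
  L <- po$edge.length
  states <- matrix(0L, n + po$Nnode, n_items)
  states[n + 1L, ] <- root_state
  for (e in rev(seq_len(nrow(E)))) {       # parents before children
    s <- states[E[e, 1L], ]
    if (nu == 0) {
      states[E[e, 2L], ] <- s              # frozen evolution
    } else {
      decay <- exp(-nu * L[e])
      p1 <- pi1 * (1 - decay) + s * decay  # = s*P11 + (1-s)*P01
      states[E[e, 2L], ] <- as.integer(stats::runif(n_items) < p1)
    }
  }
  out <- states[seq_len(n), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate reaction presence/absence along a phylogeny
#'
#' Each non-core reaction evolves independently down the tree as a two-state
#' gain/loss Markov chain with gain rate `gain_rate` and loss rate
#' `loss_rate`; root presence for non-core reactions is Bernoulli with
#' probability `root_presence_prob`. Core reactions are fixed present in every
#' species, emulating the conserved backbone of central metabolism.
#'
#' @param tree A `phylo` species tree with branch lengths.
#' @param params List with `universe_size`, `core_size`, `gain_rate`,
#'   `loss_rate`, `root_presence_prob` (see [default_sim_config()]).
#' @param seed Integer seed.
#' @return Binary species x reaction occurrence matrix; core reaction IDs in
#'   the `"core_ids"` attribute.
#' @export
simulate_occurrence <- function(tree, params, seed) {
  validate_tree(tree)
  us <- as.integer(params$universe_size)
  cs <- as.integer(params$core_size)
  lg <- params$gain_rate
  ll <- params$loss_rate
  rp <- params$root_presence_prob
  if (cs > us) stop("core_size must not exceed universe_size", call. = FALSE)
  if (lg < 0 || ll < 0) stop("rates must be non-negative", call. = FALSE)
  if (rp < 0 || rp > 1) stop("root_presence_prob must lie in [0,1]", call. = FALSE)
  set.seed(seed)
  n <- length(tree$tip.label)
  ids <- sprintf("MNX:R%04d", seq_len(us))
  occ <- matrix(1L, n, us, dimnames = list(tree$tip.label, ids))
  n_acc <- us - cs
  if (n_acc > 0L) {
    root <- as.integer(stats::runif(n_acc) < rp)
    occ[, (cs + 1L):us] <- sim_gain_loss(tree, n_acc, lg, ll, root)
  }
  attr(occ, "core_ids") <- if (cs > 0L) ids[seq_len(cs)] else character(0)
  occ
}

#' Simulate ortholog-family occurrence coupled to the reaction layer
#'
#' Every reaction gets `families_per_reaction` supporting ortholog families,
#' present exactly where the reaction is, so genotype similarity correlates
#' with model similarity by construction. `n_nonmetabolic` additional families
#' evolve independently down the tree by the same gain/loss process (rooted at
#' the stationary presence probability), diluting that coupling the way
#' non-metabolic genes do in real genomes.
#'
#' @param occ Reaction occurrence matrix (species x reactions).
#' @param families_per_reaction Integer >= 1.
#' @param n_nonmetabolic Number of independent families (>= 0).
#' @param tree Species tree (required when `n_nonmetabolic > 0`).
#' @param gain_rate,loss_rate Gain/loss rates for the independent families.
#' @param seed Integer seed.
#' @return List with `occurrence` (species x family binary matrix) and
#'   `family_map` (data frame `reaction_id`, `family_id`; `NA` reaction for
#'   non-metabolic families).
#' @export
simulate_orthologs <- function(occ, families_per_reaction = 1L,
                               n_nonmetabolic = 0L, tree = NULL,
                               gain_rate = 0.105, loss_rate = 0.195, seed) {
  if (!is.matrix(occ) || ncol(occ) == 0L) {
    stop("occurrence matrix has no reactions", call. = FALSE)
  }
  validate_occurrence(occ)
  if (families_per_reaction < 1L) {
    stop("families_per_reaction must be >= 1", call. = FALSE)
  }
  set.seed(seed)
  met <- occ[, rep(seq_len(ncol(occ)), each = families_per_reaction),
             drop = FALSE]
  fam_ids <- sprintf("OG%05d", seq_len(ncol(met)))
  colnames(met) <- fam_ids
  map <- data.frame(
    reaction_id = rep(colnames(occ), each = families_per_reaction),
    family_id = fam_ids, stringsAsFactors = FALSE)
  if (n_nonmetabolic > 0L) {
    if (is.null(tree)) stop("`tree` required for non-metabolic families",
                            call. = FALSE)
    validate_tree(tree)
    nu <- gain_rate + loss_rate
    pi1 <- if (nu > 0) gain_rate / nu else 0
    root <- as.integer(stats::runif(n_nonmetabolic) < pi1)
    extra <- sim_gain_loss(tree, n_nonmetabolic, gain_rate, loss_rate, root)
    extra <- extra[rownames(occ), , drop = FALSE]
    ex_ids <- sprintf("OGX%05d", seq_len(n_nonmetabolic))
    colnames(extra) <- ex_ids
    met <- cbind(met, extra)
    map <- rbind(map, data.frame(reaction_id = NA_character_,
                                 family_id = ex_ids, stringsAsFactors = FALSE))
  }
  list(occurrence = met, family_map = map)
}

#' Sample substrate-trait definitions
#'
#' Each substrate trait requires a fixed subset of reactions (pathway
#' completeness, AND-logic): the species grows on the substrate only when all
#' required reactions are present.
#'
#' @param reaction_ids Candidate reaction IDs (the occurrence-matrix columns).
#' @param n_substrates Number of substrates.
#' @param set_size Required reactions per substrate.
#' @param seed Integer seed.
#' @return Named list of reaction-ID vectors, one per substrate.
#' @export
sample_trait_definitions <- function(reaction_ids, n_substrates = 32L,
                                     set_size = 3L, seed) {
  if (length(reaction_ids) < set_size) {
    stop("not enough reactions to sample a required set", call. = FALSE)
  }
  set.seed(seed)
  defs <- lapply(seq_len(n_substrates), function(i) {
    sample(reaction_ids, set_size)
  })
  names(defs) <- sprintf("substrate%02d", seq_len(n_substrates))
  defs
}

#' Simulate substrate-usage traits from reaction presence
#'
#' Growth on a substrate requires every reaction in its definition
#' (AND-logic); the resulting label is flipped with probability `flip_noise`
#' (environment-like mislabelling that decouples traits from the metabolic
#' network) and then set missing with probability `missing_prob`.
#'
#' @param occ Reaction occurrence matrix.
#' @param required Named list of required-reaction vectors per substrate (see
#'   [sample_trait_definitions()]).
#' @param flip_noise,missing_prob Probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return Species x substrate matrix with values `1`, `0`, `NA`.
#' @export
simulate_traits <- function(occ, required, flip_noise = 0, missing_prob = 0,
                            seed) {
  validate_occurrence(occ)
  if (flip_noise < 0 || flip_noise > 1 || missing_prob < 0 || missing_prob > 1) {
    stop("flip_noise and missing_prob must lie in [0,1]", call. = FALSE)
  }
  if (any(lengths(required) == 0L)) {
    stop("required reaction sets must be non-empty", call. = FALSE)
  }
  unknown <- setdiff(unlist(required), colnames(occ))
  if (length(unknown)) {
    stop("unknown required reaction(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(occ)
  tr <- matrix(NA_real_, n, length(required),
               dimnames = list(rownames(occ), names(required)))
  for (j in seq_along(required)) {
    req <- required[[j]]
    tr[, j] <- as.numeric(rowSums(occ[, req, drop = FALSE]) == length(req))
  }
  if (flip_noise > 0) {
    flip <- matrix(stats::runif(length(tr)) < flip_noise, n)
    tr[flip] <- 1 - tr[flip]
  }
  if (missing_prob > 0) {
    tr[matrix(stats::runif(length(tr)) < missing_prob, n)] <- NA_real_
  }
  tr
}

#' Heaps'-law-shaped pan counts for fit testing
#'
#' Generates pan counts `n(N) = k * N^gamma * exp(eta)` with
#' `eta ~ Normal(0, noise_sd^2)` i.i.d. per `(N, permutation)` point;
#' `noise_sd = 0` gives the exact power law.
#'
#' @param k Positive amplitude.
#' @param gamma Exponent.
#' @param sizes Sample sizes `N`.
#' @param noise_sd Lognormal noise standard deviation (on the log scale).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param n_perm Number of replicate curves.
#' @return Data frame with columns `N`, `perm`, `pan`.
#' @export
generate_heaps_counts <- function(k, gamma, sizes, noise_sd = 0, seed = NULL,
                                  n_perm = 1L) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (length(sizes) == 0L) stop("sizes must be non-empty", call. = FALSE)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("`seed` required when noise_sd > 0", call. = FALSE)
    set.seed(seed)
  }
  out <- expand.grid(N = as.numeric(sizes), perm = seq_len(n_perm),
                     KEEP.OUT.ATTRS = FALSE)
  eta <- if (noise_sd > 0) stats::rnorm(nrow(out), 0, noise_sd) else 0
  out$pan <- k * out$N^gamma * exp(eta)
  out
}

#' Assign species to clades by cutting the tree
#'
#' Clusters the cophenetic distance matrix (UPGMA linkage) and cuts it into
#' `n_clades` groups, yielding a deterministic clade labelling that respects
#' the tree's major splits.
#'
#' @param tree A `phylo` species tree.
#' @param n_clades Number of clades.
#' @return Named character vector species -> clade label.
#' @export
assign_clades <- function(tree, n_clades = 8L) {
  validate_tree(tree)
  D <- cophenetic_distances(tree)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ct <- stats::cutree(hc, k = min(n_clades, length(tree$tip.label)))
  stats::setNames(sprintf("clade%02d", ct), names(ct))
}

#' Simulate a complete synthetic study
#'
#' Generates, from one master seed, every input the pipeline consumes: an
#' ultrametric species tree, a reaction occurrence matrix with a conserved
#' core, a coupled ortholog layer, noisy substrate traits, and a clade
#' assignment. Sub-seeds for the individual generators are drawn from the
#' master seed, so the whole bundle is reproducible.
#'
#' @param n_species Number of species.
#' @param config Generator parameters (see [default_sim_config()]).
#' @param seed Master integer seed.
#' @return List with `tree`, `newick`, `occurrence`, `orthologs`,
#'   `family_map`, `traits`, `trait_defs`, `clades`, `config`, `seed`.
#' @export
simulate_panreactome_data <- function(n_species = 100L,
                                      config = default_sim_config(),
                                      seed = 1L) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max, 4L)
  tr <- simulate_tree(n_species, birth_rate = config$birth_rate, seed = sub[1])
  occ <- simulate_occurrence(tr$tree, config, seed = sub[2])
  orth <- simulate_orthologs(occ,
                             families_per_reaction = config$families_per_reaction,
                             n_nonmetabolic = config$n_nonmetabolic,
                             tree = tr$tree,
                             gain_rate = config$gain_rate,
                             loss_rate = config$loss_rate,
                             seed = sub[3])
  defs <- sample_trait_definitions(colnames(occ),
                                   n_substrates = config$n_substrates,
                                   set_size = config$reactions_per_trait,
                                   seed = sub[4])
  traits <- simulate_traits(occ, defs,
                            flip_noise = config$flip_noise,
                            missing_prob = config$missing_prob,
                            seed = sub[4])
  clades <- assign_clades(tr$tree, n_clades = config$n_clades)
  list(tree = tr$tree, newick = tr$newick, occurrence = occ,
       orthologs = orth$occurrence, family_map = orth$family_map,
       traits = traits, trait_defs = defs, clades = clades,
       config = config, seed = seed)
}
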