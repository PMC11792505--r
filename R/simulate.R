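#' Simulate a pure-birth (Yule) phylogeny
#'
#' Ultrametric tree with exactly `n_taxa` tips labeled `T1..Tn`.
#'
#' @param n_taxa number of tips (>= 3).
#' @param birth_rate speciation rate.
#' @param seed integer seed; the same seed gives the identical newick
#'   string.
#' @return an [ape::phylo] object.
#' @export
simulate_tree <- function(n_taxa, birth_rate = 1, seed = 1L) {
  stopifnot(n_taxa >= 3, birth_rate > 0)
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = birth_rate, death = 0))
  tr$tip.label <- paste0("T", seq_len(n_taxa))
  tr
}

#' Simulate Brownian-motion trait values on a tree
#'
#' Root value 0; the trait accrues Gaussian increments with variance
#' `sigma^2 * branch length` along every branch, so close relatives have
#' similar traits — the phylogenetic niche conservatism the signal gate
#' tests.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param sigma Brownian rate (>= 0; 0 gives all-zero traits).
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_traits <- function(tree, sigma = 1, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0)
    return(stats::setNames(rep(0, length(tree$tip.label)), tree$tip.label))
  with_seed(seed, ape::rTraitCont(tree, model = "BM", sigma = sigma,
                                  root.value = 0))
}

#' Scenario description for the community simulator
#'
#' Bundles the study conditions under which a known assembly regime is
#' simulated. Defaults (80 taxa, 12 sites, 2000 individuals per site,
#' Brownian sigma 1) are the shipped validation conditions; see the methods
#' vignette for the rationale behind each value.
#'
#' @param regime one of [assembly_processes()].
#' @param n_taxa,n_sites community dimensions.
#' @param site_total individuals drawn per site (multinomial total, so the
#'   Raup-Crick fixed-total null is exactly satisfiable).
#' @param birth_rate Yule speciation rate for the simulated tree.
#' @param sigma Brownian trait rate (trait units per sqrt branch-length
#'   unit).
#' @param env per-site environmental optima (trait units) for the selection
#'   regimes; default spans the simulated trait range (heterogeneous) or is
#'   constant at the trait mean (homogeneous).
#' @param niche_width Gaussian niche filter width (trait units); default
#'   0.3 * sd(traits).
#' @param dispersal_scale exponential dispersal kernel scale on the unit
#'   transect (dispersal limitation regime).
#' @param mix_rate,mix_steps mass-effect mixing fraction and iterations
#'   (homogenizing dispersal regime).
#' @param divergent_taxon `TRUE` to implant one phylogenetically isolated
#'   taxon whose trait is moved to the top of the gradient (heterogeneous
#'   selection regime only): the known causal taxon for attribution tests.
#'   May also be a tip label.
#' @param divergence trait offset added beyond the gradient maximum for the
#'   divergent taxon, in units of `sd(traits)`.
#' @param seed integer seed (mandatory).
#' @return object of class `assembly_scenario`.
#' @export
assembly_scenario <- function(regime = assembly_processes(),
                              n_taxa = 80, n_sites = 12, site_total = 2000,
                              birth_rate = 1, sigma = 1,
                              env = NULL, niche_width = NULL,
                              dispersal_scale = 0.08,
                              mix_rate = 0.8, mix_steps = 2,
                              divergent_taxon = FALSE, divergence = 1,
                              seed) {
  regime <- match.arg(regime)
  if (missing(seed)) stop("assembly_scenario: a seed is required")
  stopifnot(n_taxa >= 3, n_sites >= 2, site_total >= n_sites,
            sigma >= 0, dispersal_scale > 0,
            mix_rate >= 0, mix_rate <= 1, mix_steps >= 1)
  structure(list(regime = regime, n_taxa = n_taxa, n_sites = n_sites,
                 site_total = site_total, birth_rate = birth_rate,
                 sigma = sigma, env = env, niche_width = niche_width,
                 dispersal_scale = dispersal_scale, mix_rate = mix_rate,
                 mix_steps = mix_steps, divergent_taxon = divergent_taxon,
                 divergence = divergence, seed = as.integer(seed)),
            class = "assembly_scenario")
}

# Multinomial site filling from a weight matrix (sites x taxa).
fill_sites <- function(weights, site_total, site_ids, taxon_ids) {
  weights <- pmax(weights, 1e-12)  # guard against an all-zero filter row
  counts <- t(apply(weights, 1, function(w)
    stats::rmultinom(1, site_total, prob = w)[, 1]))
  dimnames(counts) <- list(site_ids, taxon_ids)
  counts
}

#' Simulate a community table under a known assembly regime
#'
#' Given a tree and traits, draws a sites-by-taxa count table whose pairwise
#' turnover carries the signature of the scenario's regime:
#' * heterogeneous selection — Gaussian niche filter
#'   `exp(-(trait - env_k)^2 / (2 w^2))` times lognormal carrying
#'   capacities, with site optima spread across the trait range;
#' * homogeneous selection — the same filter with all sites sharing one
#'   optimum;
#' * drift — multinomial draws from one shared metacommunity distribution
#'   (exactly the situation the Raup-Crick null emulates);
#' * dispersal limitation — each taxon has a home position on a unit
#'   transect and each site samples taxa with exponentially decaying access
#'   `exp(-|x_site - x_taxon| / scale)`;
#' * homogenizing dispersal — site compositions are repeatedly mixed toward
#'   the regional mean (mass effects), making sites more similar than
#'   independent draws from the shared pool.
#'
#' @param scenario an [assembly_scenario()].
#' @param tree tree from [simulate_tree()] (simulated from the scenario when
#'   absent).
#' @param traits traits from [simulate_traits()] (idem).
#' @return list with `community` (counts, sites `S1..Sn` x taxa), `tree`,
#'   `traits`, `metadata` (site env value, transect position, gradient
#'   band), and `scenario`.
#' @export
simulate_regime <- function(scenario, tree = NULL, traits = NULL) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  sc <- scenario
  if (is.null(tree)) tree <- simulate_tree(sc$n_taxa, sc$birth_rate,
                                           seed = derive_seed(sc$seed, 1))
  if (is.null(traits)) traits <- simulate_traits(tree, sc$sigma,
                                                 seed = derive_seed(sc$seed, 2))
  taxa <- tree$tip.label
  traits <- traits[taxa]
  site_ids <- paste0("S", seq_len(sc$n_sites))

  divergent <- NULL
  if (!isFALSE(sc$divergent_taxon)) {
    if (sc$regime != "heterogeneous_selection")
      stop("divergent_taxon applies to the heterogeneous_selection regime only")
    divergent <- if (isTRUE(sc$divergent_taxon)) {
      # most phylogenetically isolated lineage: largest mean patristic distance
      D <- stats::cophenetic(tree)
      taxa[which.max(rowMeans(D))]
    } else as.character(sc$divergent_taxon)
    stopifnot(divergent %in% taxa)
    # push its trait beyond its relatives'; the default gradient below then
    # matches the top site to it, so the top of the gradient is dominated by
    # this single phylogenetically isolated taxon
    others <- traits[setdiff(taxa, divergent)]
    traits[divergent] <- max(others) + sc$divergence * stats::sd(others)
  }

  env <- sc$env
  if (is.null(env)) {
    env <- switch(sc$regime,
                  heterogeneous_selection = seq(min(traits), max(traits),
                                                length.out = sc$n_sites),
                  homogeneous_selection = rep(mean(traits), sc$n_sites),
                  rep(NA_real_, sc$n_sites))
  }
  if (sc$regime %in% c("heterogeneous_selection", "homogeneous_selection") &&
      anyNA(env))
    stop("selection regimes require environmental optima for every site")

  comm <- with_seed(derive_seed(sc$seed, 3), {
    K <- stats::rlnorm(sc$n_taxa, meanlog = 0, sdlog = 1)
    switch(sc$regime,
      heterogeneous_selection = ,
      homogeneous_selection = {
        w <- sc$niche_width %||% (0.3 * stats::sd(traits))
        filt <- outer(env, traits, function(e, tr) exp(-(tr - e)^2 / (2 * w^2)))
        fill_sites(sweep(filt, 2, K, "*"), sc$site_total, site_ids, taxa)
      },
      drift = {
        p <- matrix(K, sc$n_sites, sc$n_taxa, byrow = TRUE)
        fill_sites(p, sc$site_total, site_ids, taxa)
      },
      dispersal_limitation = {
        x_site <- seq(0, 1, length.out = sc$n_sites)
        x_taxon <- stats::runif(sc$n_taxa)
        access <- outer(x_site, x_taxon,
                        function(s, u) exp(-abs(s - u) / sc$dispersal_scale))
        fill_sites(sweep(access, 2, K, "*"), sc$site_total, site_ids, taxa)
      },
      homogenizing_dispersal = {
        p <- matrix(K, sc$n_sites, sc$n_taxa, byrow = TRUE)
        counts <- fill_sites(p, sc$site_total, site_ids, taxa)
        for (s in seq_len(sc$mix_steps)) {
          mixed <- (1 - sc$mix_rate) * counts +
            sc$mix_rate * matrix(colMeans(counts), nrow = sc$n_sites,
                                 ncol = sc$n_taxa, byrow = TRUE)
          counts <- round(mixed)
        }
        counts
      })
  })

  band <- cut(seq_len(sc$n_sites), breaks = 3,
              labels = c("low", "medium", "high"))
  metadata <- data.frame(env = env,
                         position = seq(0, 1, length.out = sc$n_sites),
                         band = as.character(band),
                         row.names = site_ids, stringsAsFactors = FALSE)
  # taxa never drawn anywhere are dropped silently; the tree is pruned to the
  # table at alignment time
  comm <- suppressWarnings(as_community_matrix(comm))
  list(community = comm, tree = tree, traits = traits,
       metadata = metadata, scenario = sc, divergent_taxon = divergent)
}

#' One-call simulation of tree, traits and community
#'
#' @inheritParams assembly_scenario
#' @param ... passed to [assembly_scenario()].
#' @return see [simulate_regime()].
#' @export
simulate_assembly <- function(regime, seed, ...) {
  simulate_regime(assembly_scenario(regime = regime, seed = seed, ...))
}
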