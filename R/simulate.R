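#' Specify a synthetic community simulation
#'
#' Bundles and validates the parameters shared by the four community
#' generators. Each generator consumes the fields relevant to its regime and
#' derives all randomness from `seed` through [derive_seed()], so identical
#' specs give bit-identical tables.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param n_samples number of samples (>= 3).
#' @param reads_per_sample library size N (>= 1).
#' @param regime one of `"neutral"`, `"niche"`, `"dispersal"`,
#'   `"block_network"`.
#' @param m metacommunity migration rate in (0, 1]; neutral regime only.
#' @param n_modules number of co-occurrence modules (block_network only, >= 2).
#' @param gradient_groups data.frame with columns `label`, `mean_salinity`,
#'   `sd_salinity` (psu); niche regime only. The default reproduces the three
#'   salinity regions of an estuary-to-shelf transect: estuary 13.15 +/- 0.93,
#'   nearshore 17.28 +/- 0.56, offshore 29.17 +/- 0.24 psu.
#' @param niche_width Gaussian niche breadth in psu (niche regime); larger
#'   values flatten the salinity response.
#' @param module_loading latent-factor loading for block_network; 2 gives
#'   strongly correlated within-module taxa.
#' @param gem_concentration stick-breaking (GEM) concentration for the
#'   metacommunity abundance distribution; 5 gives a long tail comparable to
#'   observed amplicon rank-abundance curves.
#' @param seed integer master seed.
#' @return A validated list of class `community_sim_spec`.
#' @export
community_sim_spec <- function(n_taxa, n_samples, reads_per_sample,
                               regime = c("neutral", "niche", "dispersal",
                                          "block_network"),
                               m = NULL, n_modules = NULL,
                               gradient_groups = default_gradient_groups(),
                               niche_width = 3,
                               module_loading = 2,
                               gem_concentration = 5,
                               seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(n_taxa >= 2, n_samples >= 3, reads_per_sample >= 1)
  if (regime == "neutral") {
    if (is.null(m)) stop("neutral regime requires migration rate 'm'")
    assert_scalar_in(m, "m", 0, 1, open_lo = TRUE)
  }
  if (regime == "block_network") {
    if (is.null(n_modules) || n_modules < 2) {
      stop("block_network regime requires 'n_modules' >= 2")
    }
    if (n_modules > n_taxa) stop("'n_modules' cannot exceed 'n_taxa'")
  }
  if (regime == "niche") {
    gg <- gradient_groups
    if (is.null(gg) || nrow(gg) == 0) stop("niche regime requires non-empty 'gradient_groups'")
    stopifnot(all(c("label", "mean_salinity", "sd_salinity") %in% names(gg)))
    if (any(gg$sd_salinity < 0)) stop("group salinity sds must be >= 0")
  }
  structure(list(n_taxa = as.integer(n_taxa),
                 n_samples = as.integer(n_samples),
                 reads_per_sample = as.integer(reads_per_sample),
                 regime = regime, m = m, n_modules = n_modules,
                 gradient_groups = gradient_groups,
                 niche_width = niche_width,
                 module_loading = module_loading,
                 gem_concentration = gem_concentration,
                 seed = as.integer(seed)),
            class = "community_sim_spec")
}

#' Default salinity gradient design
#'
#' Three regions with the salinity means and station-to-station standard
#' deviations observed along a river-estuary to continental-shelf transect.
#'
#' @return data.frame with columns `label`, `mean_salinity`, `sd_salinity`.
#' @export
default_gradient_groups <- function() {
  data.frame(label = c("estuary", "nearshore", "offshore"),
             mean_salinity = c(13.15, 17.28, 29.17),
             sd_salinity = c(0.93, 0.56, 0.24),
             stringsAsFactors = FALSE)
}

# Stick-breaking (GEM) metacommunity relative abundances, long-tailed,
# renormalised to sum exactly 1.
gem_abundances <- function(n_taxa, concentration) {
  v <- stats::rbeta(n_taxa, 1, concentration)
  p <- v * cumprod(c(1, 1 - v[-n_taxa]))
  p / sum(p)
}

taxon_ids <- function(n, prefix = "OTU") sprintf("%s%04d", prefix, seq_len(n))
sample_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Simulate a neutrally assembled community
#'
#' Generative twin of the Sloan neutral community model: each taxon has a
#' metacommunity relative abundance p drawn from a stick-breaking
#' distribution; the local relative abundance in every sample is drawn from
#' Beta(N m p, N m (1 - p)) with N the library size and m the migration rate,
#' and observed counts are Binomial(N, local abundance). Lower m concentrates
#' local abundances at 0 or 1 (stronger dispersal limitation).
#'
#' @param spec a [community_sim_spec()] with `regime = "neutral"`.
#' @return A list with elements `table` (an [otu_table]) and `ground_truth`
#'   (list with `metacommunity_abundances`, `true_m`).
#' @export
simulate_neutral <- function(spec) {
  stopifnot(inherits(spec, "community_sim_spec"), spec$regime == "neutral")
  with_seed(derive_seed(spec$seed, "simulate_neutral"), function() {
    N <- spec$reads_per_sample
    p <- gem_abundances(spec$n_taxa, spec$gem_concentration)
    # guard the Beta parameters against p exactly 0 or 1
    pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    a <- N * spec$m * pc
    b <- N * spec$m * (1 - pc)
    cnt <- matrix(0L, spec$n_taxa, spec$n_samples,
                  dimnames = list(taxon_ids(spec$n_taxa),
                                  sample_ids(spec$n_samples)))
    for (j in seq_len(spec$n_samples)) {
      loc <- stats::rbeta(spec$n_taxa, a, b)
      cnt[, j] <- stats::rbinom(spec$n_taxa, N, loc)
    }
    cnt <- ensure_nonempty_samples(cnt, N)
    list(table = otu_table(cnt),
         ground_truth = list(metacommunity_abundances = p, true_m = spec$m))
  })
}

# an all-zero sample is astronomically unlikely at realistic N but would
# violate the otu_table invariant; give such a sample one read of taxon 1
ensure_nonempty_samples <- function(cnt, N) {
  z <- colSums(cnt) == 0
  if (any(z)) cnt[1L, z] <- 1L
  cnt
}

#' Simulate a niche-structured community along a salinity gradient
#'
#' Samples are assigned to salinity groups (near-equal split in group order)
#' and given salinities Normal(group mean, group sd). Each taxon receives a
#' salinity optimum and a Gaussian response of width `niche_width`; expected
#' abundance is proportional to the response at the sample's salinity, and
#' counts are a multinomial draw of `reads_per_sample`. Optima are drawn
#' from 5 + 28 * Beta(1, 2) psu — a pool skewed toward fresh water, so that
#' high-salinity samples draw on fewer adapted taxa and observed richness
#' declines with salinity, the filtering signature seen in estuarine
#' transects. Metadata carries salinity, temperature (decreasing with
#' salinity plus noise) and region label.
#'
#' @param spec a [community_sim_spec()] with `regime = "niche"`.
#' @return A list with `table`, `ground_truth` (`metacommunity_abundances` =
#'   mean expected relative abundance across the drawn samples,
#'   `niche_optima`, `niche_width`) and `metadata` (data.frame with
#'   `sample_id`, `salinity`, `temperature`, `region`).
#' @export
simulate_niche_gradient <- function(spec) {
  stopifnot(inherits(spec, "community_sim_spec"), spec$regime == "niche")
  with_seed(derive_seed(spec$seed, "simulate_niche_gradient"), function() {
    gg <- spec$gradient_groups
    sizes <- diff(floor(seq(0, spec$n_samples, length.out = nrow(gg) + 1)))
    region <- rep(gg$label, sizes)
    sal <- stats::rnorm(spec$n_samples, rep(gg$mean_salinity, sizes),
                        rep(gg$sd_salinity, sizes))
    temp <- 12 - 0.35 * sal + stats::rnorm(spec$n_samples, 0, 0.5)
    opt <- 5 + 28 * stats::rbeta(spec$n_taxa, 1, 2)
    cnt <- matrix(0L, spec$n_taxa, spec$n_samples,
                  dimnames = list(taxon_ids(spec$n_taxa),
                                  sample_ids(spec$n_samples)))
    relw <- matrix(0, spec$n_taxa, spec$n_samples)
    for (j in seq_len(spec$n_samples)) {
      w <- if (is.finite(spec$niche_width)) {
        exp(-(sal[j] - opt)^2 / (2 * spec$niche_width^2))
      } else rep(1, spec$n_taxa)
      if (sum(w) <= 0) w <- rep(1, spec$n_taxa)
      relw[, j] <- w / sum(w)
      cnt[, j] <- stats::rmultinom(1, spec$reads_per_sample, relw[, j])
    }
    cnt <- ensure_nonempty_samples(cnt, spec$reads_per_sample)
    list(table = otu_table(cnt),
         ground_truth = list(metacommunity_abundances = rowMeans(relw),
                             niche_optima = opt,
                             niche_width = spec$niche_width),
         metadata = data.frame(sample_id = colnames(cnt), salinity = sal,
                               temperature = temp, region = region,
                               stringsAsFactors = FALSE))
  })
}

#' Simulate a dispersal-structured community
#'
#' Community structure is carried entirely by per-taxon occupancy: each taxon
#' draws an occupancy probability Uniform(0.05, 0.95); presence at each site
#' is an independent Bernoulli draw at that probability with no site effect,
#' and abundance conditional on presence is i.i.d. lognormal noise around the
#' taxon's baseline weight (Poisson counts). Sites are therefore exchangeable
#' by construction — the signature of dispersal assembly.
#'
#' @param spec a [community_sim_spec()] with `regime = "dispersal"`.
#' @return A list with `table` and `ground_truth`
#'   (`metacommunity_abundances`, `occupancy_probabilities`).
#' @export
simulate_dispersal_structured <- function(spec) {
  stopifnot(inherits(spec, "community_sim_spec"), spec$regime == "dispersal")
  with_seed(derive_seed(spec$seed, "simulate_dispersal"), function() {
    base <- gem_abundances(spec$n_taxa, spec$gem_concentration)
    occ <- stats::runif(spec$n_taxa, 0.05, 0.95)
    pres <- matrix(stats::rbinom(spec$n_taxa * spec$n_samples, 1,
                                 rep(occ, spec$n_samples)),
                   spec$n_taxa, spec$n_samples)
    lam <- spec$reads_per_sample * base *
      matrix(stats::rlnorm(spec$n_taxa * spec$n_samples, 0, 0.5),
             spec$n_taxa, spec$n_samples)
    cnt <- matrix(stats::rpois(length(lam), lam * pres),
                  spec$n_taxa, spec$n_samples,
                  dimnames = list(taxon_ids(spec$n_taxa),
                                  sample_ids(spec$n_samples)))
    # a present taxon should be detected: guarantee at least one read
    cnt[pres == 1 & cnt == 0] <- 1L
    cnt <- ensure_nonempty_samples(cnt, spec$reads_per_sample)
    list(table = otu_table(cnt),
         ground_truth = list(metacommunity_abundances = base,
                             occupancy_probabilities = occ))
  })
}

#' Simulate a community with block-structured co-occurrence
#'
#' Taxa are partitioned into `n_modules` modules of near-equal size. Taxa in
#' the same module share a per-sample latent log-normal factor scaled by
#' `module_loading`, which induces high positive rank correlation within
#' modules; counts are Poisson around the scaled latent abundances. The
#' ground-truth edge set is every within-module taxon pair.
#'
#' With the defaults the module factors are independent and the resulting
#' co-occurrence graph is a set of disjoint cliques. Two optional knobs
#' produce the connected modular topology of real co-occurrence networks:
#' `factor_correlation` rho > 0 gives all module factors a shared component
#' (common environmental driver), and `n_bridge_taxa` adds taxa that load
#' equally on two adjacent module factors — synthetic "gatekeepers" joining
#' consecutive modules into a chain. A bridge taxon can only cross the edge
#' threshold when rho > 0 (its correlation with a member of either module is
#' bounded by sqrt((1 + rho)/2)). Bridge taxa carry module id 0 and
#' contribute no ground-truth edges.
#'
#' @param spec a [community_sim_spec()] with `regime = "block_network"`.
#' @param factor_correlation correlation rho between module factors
#'   (default 0).
#' @param n_bridge_taxa number of extra bridge taxa, at most
#'   `n_modules - 1`; bridge i joins modules i and i+1 (default 0).
#' @return A list with `table` and `ground_truth` (`module_assignment` —
#'   0 for bridge taxa, `true_edges` — a two-column character matrix of
#'   unordered within-module taxon pairs, and `metacommunity_abundances`).
#' @export
simulate_block_network <- function(spec, factor_correlation = 0,
                                   n_bridge_taxa = 0) {
  stopifnot(inherits(spec, "community_sim_spec"),
            spec$regime == "block_network")
  assert_scalar_in(factor_correlation, "factor_correlation", 0, 1,
                   open_hi = TRUE)
  if (n_bridge_taxa > spec$n_modules - 1) {
    stop("'n_bridge_taxa' cannot exceed n_modules - 1")
  }
  with_seed(derive_seed(spec$seed, "simulate_block_network"), function() {
    n_all <- spec$n_taxa + n_bridge_taxa
    ids <- taxon_ids(n_all)
    mod <- c(sort(rep(seq_len(spec$n_modules), length.out = spec$n_taxa)),
             integer(n_bridge_taxa))
    base <- exp(stats::rnorm(n_all, 0, 0.5))
    base <- base / sum(base)
    lo <- spec$module_loading
    eps <- 0.3
    rho <- factor_correlation
    g <- stats::rnorm(spec$n_samples)
    fac <- sqrt(1 - rho) *
      matrix(stats::rnorm(spec$n_modules * spec$n_samples),
             spec$n_modules, spec$n_samples) +
      sqrt(rho) * matrix(g, spec$n_modules, spec$n_samples, byrow = TRUE)
    sig <- fac[pmax(mod, 1L), , drop = FALSE]  # placeholder rows for bridges
    if (n_bridge_taxa > 0) {
      for (b in seq_len(n_bridge_taxa)) {
        sig[spec$n_taxa + b, ] <-
          (fac[b, ] + fac[b + 1, ]) / sqrt(2 * (1 + rho))
      }
    }
    z <- matrix(stats::rnorm(n_all * spec$n_samples, 0, eps),
                n_all, spec$n_samples)
    lam <- spec$reads_per_sample * base *
      exp(lo * sig + z - (lo^2 + eps^2) / 2)
    cnt <- matrix(stats::rpois(length(lam), lam), n_all, spec$n_samples,
                  dimnames = list(ids, sample_ids(spec$n_samples)))
    cnt <- ensure_nonempty_samples(cnt, spec$reads_per_sample)
    member <- mod > 0
    edges <- do.call(rbind, lapply(split(ids[member], mod[member]),
                                   function(gr) {
      if (length(gr) < 2) return(NULL)
      t(utils::combn(gr, 2))
    }))
    rownames(edges) <- NULL
    list(table = otu_table(cnt),
         ground_truth = list(metacommunity_abundances = base,
                             module_assignment = stats::setNames(mod, ids),
                             true_edges = edges))
  })
}

#' Write simulation ground truth as JSON
#'
#' @param ground_truth the `ground_truth` element returned by a simulator.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  if (!is.null(gt$true_edges)) {
    gt$true_edges <- apply(gt$true_edges, 1, paste, collapse = "--")
  }
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
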