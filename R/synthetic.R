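#' Synthetic single-peak chronoamperometry pulse
#'
#' Builds a smooth one-peak current trace with an exactly placed peak and a
#' prescribed total charge. The pulse is Gaussian in log-time,
#' I(t) = A exp(-(log(t / t_peak))^2 / (2 sigma^2)), which peaks exactly at
#' `peak_time` with height `peak_current`; the width `sigma` is solved
#' numerically so that the trapezoidal integral of the emitted samples
#' equals `total_charge`. Only (peak height, peak time, total charge) are
#' treated as meaningful; the shape itself is a modelling convenience.
#'
#' @param peak_current Peak current, amperes (non-zero; its sign must match
#'   the sign of `total_charge`).
#' @param peak_time Time of the peak, hours (inside `(0, duration)`).
#' @param total_charge Target integrated charge, coulombs.
#' @param duration Trace length, hours.
#' @param n Number of samples (default 601).
#' @param noise_sd Additive Gaussian noise, as a fraction of the peak
#'   height (default 0).
#' @param seed Seed used when `noise_sd > 0`.
#' @return Trace tibble (`time_h`, `current_A`) whose [integrate_current()]
#'   matches `total_charge` (exactly to solver tolerance when noise-free).
#' @examples
#' tr <- make_current_pulse(6.43e-6, 31.5, 1.06, 150)
#' integrate_current(tr)
#' @export
make_current_pulse <- function(peak_current, peak_time, total_charge,
                               duration = 150, n = 601, noise_sd = 0,
                               seed = 1) {
  if (peak_current == 0) abort("peak current must be non-zero")
  if (peak_time <= 0 || peak_time >= duration) {
    abort("peak time must lie strictly inside (0, duration)")
  }
  if (sign(peak_current) != sign(total_charge)) {
    abort("peak current and total charge must have the same sign")
  }
  a <- abs(peak_current)
  q <- abs(total_charge)
  if (q >= a * duration * 3600) {
    abort(paste0("infeasible targets: total charge ", q,
                 " C exceeds the bound peak * duration = ",
                 signif(a * duration * 3600, 4), " C"))
  }
  t <- sort(unique(c(seq(0, duration, length.out = n), peak_time)))
  shape <- function(sigma) {
    g <- exp(-(log(t / peak_time))^2 / (2 * sigma^2))
    g[t == 0] <- 0
    g
  }
  charge_of <- function(sigma) a * pracma::trapz(t * 3600, shape(sigma))
  sigma <- uniroot(function(s) charge_of(s) - q,
                   lower = 1e-4, upper = 60, tol = 1e-12)$root
  cur <- sign(peak_current) * a * shape(sigma)
  if (noise_sd > 0) {
    withr_seed(seed)
    cur <- cur + rnorm(length(cur), sd = noise_sd * a)
  }
  tibble::tibble(time_h = t, current_A = cur)
}

#' Generate one synthetic reactor batch
#'
#' Builds a reactor spec, a metabolite panel exactly consistent with the
#' configured consumption and yields, and (when charge targets are given) a
#' single-peak current trace whose integral matches the target charge.
#' When `unaccounted_carbon` is configured, the biomass concentration is
#' back-computed so the carbon balance closes to exactly that unaccounted
#' fraction.
#'
#' @param config Named list. Reactor fields: `reactor_id`,
#'   `applied_potential` (NA for a control), `volume_l` (default 0.1),
#'   `initial_substrate` (g L^-1, default 4), `duration_h` (default 150).
#'   Targets: `consumed_fraction` in \[0, 1\]; `yield_ethanol`,
#'   `yield_acetate` (mol mol^-1 consumed); `h2_umol`; optional `c_i`
#'   (coulombs), `peak_current` (A), `peak_time` (h) — all three needed for
#'   a trace; optional `unaccounted_carbon` fraction in \[0, 1\];
#'   optional `noise_sd` (trace noise fraction, default 0).
#' @param seed Integer seed (used only for trace noise).
#' @return One-row tibble in the batch-table layout accepted by
#'   [balance_all()], with a `trace` list-column (`NULL` when no charge
#'   targets were configured).
#' @examples
#' b <- make_reactor_batch(list(reactor_id = "demo", applied_potential = 0.842,
#'                              consumed_fraction = 0.115,
#'                              yield_ethanol = 0.652, yield_acetate = 0.6,
#'                              h2_umol = 0.11, c_i = 1.06,
#'                              peak_current = 6.43e-6, peak_time = 31.5))
#' glance(balance_all(b)$report[[1]])
#' @export
make_reactor_batch <- function(config, seed = 1) {
  cfg <- config
  cfg$volume_l <- cfg$volume_l %||% 0.1
  cfg$initial_substrate <- cfg$initial_substrate %||% 4
  cfg$duration_h <- cfg$duration_h %||% 150
  cfg$substrate_molar_mass <- cfg$substrate_molar_mass %||% xylose_molar_mass()
  cfg$yield_ethanol <- cfg$yield_ethanol %||% 0
  cfg$yield_acetate <- cfg$yield_acetate %||% 0
  cfg$h2_umol <- cfg$h2_umol %||% 0
  if (is.null(cfg$consumed_fraction) || cfg$consumed_fraction < 0 ||
      cfg$consumed_fraction > 1) {
    abort("consumed_fraction must be given, in [0, 1]")
  }
  if (cfg$yield_ethanol < 0 || cfg$yield_acetate < 0 || cfg$h2_umol < 0) {
    abort("yields and H2 amount must be >= 0")
  }

  consumed <- consumed_molar_conc(cfg$initial_substrate, cfg$consumed_fraction,
                                  cfg$substrate_molar_mass)
  ethanol <- cfg$yield_ethanol * consumed
  acetate <- cfg$yield_acetate * consumed

  biomass <- NA_real_
  if (!is.null(cfg$unaccounted_carbon)) {
    if (cfg$unaccounted_carbon < 0 || cfg$unaccounted_carbon > 1) {
      abort("unaccounted_carbon must lie in [0, 1]")
    }
    # close the carbon balance: 2 eth + 2 ace + 5 bio = (1 - u) * 5 consumed
    biomass <- ((1 - cfg$unaccounted_carbon) * 5 * consumed -
                  2 * ethanol - 2 * acetate) / 5
    if (biomass < -1e-9) {
      abort(paste0("infeasible targets: configured yields assign ",
                   signif((2 * ethanol + 2 * acetate) / (5 * consumed) * 100, 4),
                   " % of consumed carbon, exceeding the ",
                   signif((1 - cfg$unaccounted_carbon) * 100, 4),
                   " % available"))
    }
    biomass <- max(biomass, 0)
  } else if (consumed > 0 &&
             2 * ethanol + 2 * acetate > 5 * consumed * (1 + 1e-9)) {
    abort("infeasible targets: product carbon exceeds consumed carbon")
  }

  trace <- NULL
  if (!is.null(cfg$c_i) && !is.null(cfg$peak_current) &&
      !is.null(cfg$peak_time)) {
    trace <- make_current_pulse(cfg$peak_current, cfg$peak_time, cfg$c_i,
                                duration = cfg$duration_h,
                                noise_sd = cfg$noise_sd %||% 0, seed = seed)
  }

  tibble::tibble(
    reactor_id = cfg$reactor_id %||% "synthetic",
    applied_potential = cfg$applied_potential %||% NA_real_,
    volume_l = cfg$volume_l,
    initial_substrate = cfg$initial_substrate,
    substrate_molar_mass = cfg$substrate_molar_mass,
    duration_h = cfg$duration_h,
    consumed_fraction = cfg$consumed_fraction,
    ethanol = ethanol,
    acetate = acetate,
    hydrogen = cfg$h2_umol,
    biomass = biomass,
    c_i = cfg$c_i %||% NA_real_,
    peak_current = cfg$peak_current %||% NA_real_,
    peak_time = cfg$peak_time %||% NA_real_,
    trace = list(trace)
  )
}

#' The five-reactor benchmark fixture
#'
#' Reactor batch table for the five xylose electro-fermentation reactors of
#' the study this package models: a no-potential control and applied
#' potentials of -0.058, +0.242, +0.542 and +0.842 V vs SHE, populated
#' with the published endpoint measurements (consumption rate, ethanol and
#' acetate concentrations, hydrogen amount) and published integrated
#' charges. All reactors: 0.1 L working volume, 4 g L^-1 xylose, 150 h.
#' Peak currents/times are carried where published. This fixture drives the
#' package's acceptance checks.
#'
#' @return A five-row batch table in the layout accepted by
#'   [balance_all()]; the `trace` list-column is `NULL` throughout (the
#'   charges are carried directly in `c_i`).
#' @examples
#' balance_all(make_benchmark_fixture())
#' @export
make_benchmark_fixture <- function() {
  tibble::tibble(
    reactor_id = c("control", "-0.058 V", "+0.242 V", "+0.542 V", "+0.842 V"),
    applied_potential = c(NA, -0.058, 0.242, 0.542, 0.842),
    volume_l = 0.1,
    initial_substrate = 4,
    substrate_molar_mass = xylose_molar_mass(),
    duration_h = 150,
    consumed_fraction = c(0.0275, 0.293, 0.184, 0.955, 0.115),
    ethanol = c(148, 567, 2093, 764, 2000),     # umol/L
    acetate = c(805, 1380, 1594, 632, 1874),    # umol/L
    hydrogen = c(0, 0.20, 0.12, 0.36, 0.11),    # umol, absolute
    biomass = NA_real_,
    c_i = c(NA, -0.58, 0.17, 0.63, 1.06),       # C
    peak_current = c(NA, NA, 0.96e-6, 3.36e-6, 6.43e-6),
    peak_time = c(NA, NA, 65, 110, 31.5),
    trace = list(NULL)
  )
}

rdirichlet <- function(n, alpha) {
  # standard gamma construction
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Generate a synthetic microbial community experiment
#'
#' Emulates the community structure of a potential-application experiment:
#' pre-treatment samples are Dirichlet-multinomial draws around a diffuse
#' baseline; post-treatment samples concentrate a configurable set of
#' dominance families to a configured combined relative abundance
#' (mirroring the post-treatment takeover by two families observed in such
#' reactors). Also emits a random coalescent tree over the taxa with
#' exponential branch lengths, a taxon-to-family taxonomy, and sample
#' metadata. Fully reproducible under `seed`.
#'
#' @param config Named list: `n_samples` per group (default 3), `n_taxa`
#'   (default 50), `n_families` (default 12), `depth` reads per sample
#'   (default 2000), `concentration` Dirichlet precision around the
#'   baseline (default 200; larger = samples closer to the baseline),
#'   `dominance_families` number of families boosted post-treatment
#'   (default 2), `dominance_abundance` their combined post-treatment
#'   relative abundance in (0, 1\] (default 0.9).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return List with `table` (wide OTU tibble, pre then post samples),
#'   `tree` (`phylo`), `taxonomy` (tibble `taxon`, `family`), `metadata`
#'   (tibble `sample_id`, `group`), `baseline` and `post_baseline`
#'   (expected taxon proportions per group), `dominant_families`.
#' @examples
#' com <- make_community(list(n_samples = 3), seed = 42)
#' alpha_diversity(com$table, com$tree)
#' @export
make_community <- function(config = list(), seed) {
  if (missing(seed)) abort("seed is mandatory")
  cfg <- config
  n_samples <- cfg$n_samples %||% 3
  n_taxa <- cfg$n_taxa %||% 50
  n_families <- cfg$n_families %||% 12
  depth <- cfg$depth %||% 2000
  concentration <- cfg$concentration %||% 200
  n_dom <- cfg$dominance_families %||% 2
  q <- cfg$dominance_abundance %||% 0.9
  if (q > 1 || q <= 0) abort("dominance abundance must lie in (0, 1]")
  if (n_samples < 2) abort("need at least 2 samples per group")

  withr_seed(seed)
  taxa <- sprintf("otu%02d", seq_len(n_taxa))
  families <- sprintf("family_%02d", seq_len(n_families))
  taxonomy <- tibble::tibble(
    taxon = taxa,
    family = sample(rep_len(families, n_taxa))
  )
  dominant <- families[seq_len(n_dom)]

  baseline <- as.numeric(rdirichlet(1, rep(2, n_taxa)))
  names(baseline) <- taxa

  in_dom <- taxonomy$family %in% dominant
  if (!any(in_dom)) abort("no taxon belongs to a dominance family")
  post_baseline <- baseline
  post_baseline[in_dom] <- q * baseline[in_dom] / sum(baseline[in_dom])
  post_baseline[!in_dom] <- (1 - q) * baseline[!in_dom] / sum(baseline[!in_dom])

  draw_group <- function(base, prefix) {
    p <- rdirichlet(n_samples, concentration * base)
    counts <- t(apply(p, 1, function(pi) rmultinom(1, depth, pi)))
    rownames(counts) <- paste0(prefix, "_", seq_len(n_samples))
    colnames(counts) <- taxa
    counts
  }
  m <- rbind(draw_group(baseline, "pre"), draw_group(post_baseline, "post"))

  tree <- ape::rcoal(n_taxa, tip.label = sample(taxa))
  tree$edge.length <- rexp(nrow(tree$edge), rate = 1 / mean(tree$edge.length))

  list(
    table = otu_tibble(m),
    tree = tree,
    taxonomy = taxonomy,
    metadata = tibble::tibble(
      sample_id = rownames(m),
      group = rep(c("pre", "post"), each = n_samples)
    ),
    baseline = baseline,
    post_baseline = post_baseline,
    dominant_families = dominant
  )
}
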