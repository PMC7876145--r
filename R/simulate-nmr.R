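#' Configuration for a synthetic HSQC titration
#'
#' Defines the experimental design of a simulated lipid titration: the
#' protein and lipid concentrations, the true binding parameters
#' \eqn{(K_D, L)}, and the noise level on the intensity ratios. Binding can
#' differ between sequence regions through a per-region multiplicative
#' scaling of the bound fraction (e.g. 1 for an anchoring region, 0 for a
#' detached C-terminus).
#'
#' Defaults mirror the titration design used throughout: 50 uM protein and
#' total lipid from 0 to 14 mM.
#'
#' @param protein_conc total protein concentration (uM), > 0
#' @param lipid_concs strictly increasing non-negative lipid series (uM)
#' @param kd_true true dissociation constant (uM), > 0
#' @param l_true true lipids per protein, > 0
#' @param regions list of `list(region =, scaling =)` entries, scaling in
#'   \[0,1\], applied to the bound fraction of residues in the region;
#'   residues covered by no region get scaling 1
#' @param noise_sd Gaussian SD of the intensity-ratio noise, >= 0
#' @param n_residues number of residues simulated
#' @param seed integer RNG seed
#' @return object of class `nmr_sim_config`
#' @export
nmr_sim_config <- function(protein_conc = 50,
                           lipid_concs = c(0, 50, 100, 250, 500, 1000,
                                           2000, 4000, 7000, 10000, 14000),
                           kd_true = 5.2, l_true = 14.3,
                           regions = NULL,
                           noise_sd = 0.02, n_residues = 140, seed = 1L) {
  stopifnot(protein_conc > 0, kd_true > 0, l_true > 0,
            all(lipid_concs >= 0), !is.unsorted(lipid_concs, strictly = TRUE),
            noise_sd >= 0, n_residues >= 1)
  scaling <- rep(1, n_residues)
  if (!is.null(regions)) {
    for (rg in regions) {
      stopifnot(inherits(rg$region, "region_definition"),
                rg$scaling >= 0, rg$scaling <= 1)
      idx <- seq(rg$region$start, min(rg$region$end, n_residues))
      scaling[idx] <- rg$scaling
    }
  }
  structure(list(protein_conc = protein_conc, lipid_concs = lipid_concs,
                 kd_true = kd_true, l_true = l_true,
                 residue_scaling = scaling, noise_sd = noise_sd,
                 n_residues = as.integer(n_residues), seed = as.integer(seed)),
            class = "nmr_sim_config")
}

#' Simulate an HSQC titration with known ground truth
#'
#' For each residue r and lipid concentration c the noiseless ratio is
#' `1 - scaling_r * chi_B(c)` with `chi_B` the quadratic isotherm
#' ([eval_binding_model()]); Gaussian noise is added and the result clipped
#' to \[0, 1.05\] (intensity ratios can overshoot 1 slightly by noise).
#' Configurations whose expected fraction of clipped cells exceeds 10% are
#' rejected as having unusable noise levels.
#'
#' @param config an [nmr_sim_config()]
#' @return list with elements `dataset` (a [titration_dataset()]) and
#'   `truth` (kd_true, l_true, residue_scaling, noiseless ratio matrix)
#' @export
generate_titration <- function(config) {
  stopifnot(inherits(config, "nmr_sim_config"))
  chi <- eval_binding_model(config$protein_conc, config$lipid_concs,
                            config$kd_true, config$l_true)
  clean <- 1 - outer(config$residue_scaling, chi)   # residues x concs
  if (config$noise_sd > 0) {
    # a cell counts as affected by clipping when truncating the noise to
    # [0, 1.05] shifts its expected value by more than 0.05; ratios sitting
    # exactly at a boundary only incur the small one-sided truncation bias
    sd <- config$noise_sd
    a <- (0 - clean) / sd
    b <- (1.05 - clean) / sd
    e_clip <- clean * (stats::pnorm(b) - stats::pnorm(a)) +
      1.05 * (1 - stats::pnorm(b)) +
      sd * (stats::dnorm(a) - stats::dnorm(b))
    if (mean(abs(e_clip - clean) > 0.05) > 0.10)
      stop("noise_sd too large: expected clipping would affect >10% of values")
  }
  set.seed(config$seed)
  ratios <- clean + stats::rnorm(length(clean), sd = config$noise_sd)
  ratios <- pmin(pmax(ratios, 0), 1.05)
  dim(ratios) <- dim(clean)
  dataset <- titration_dataset(config$protein_conc,
                               seq_len(config$n_residues),
                               config$lipid_concs, ratios)
  truth <- list(kd_true = config$kd_true, l_true = config$l_true,
                residue_scaling = config$residue_scaling,
                chi_b = chi, clean_ratios = clean, seed = config$seed)
  list(dataset = dataset, truth = truth)
}

#' Configuration for synthetic CEST profiles
#'
#' Phenomenological model of a saturation-transfer profile: the bound state
#' is assumed to give a Lorentzian transfer efficiency
#' \eqn{T(\Omega) = w^2 / (w^2 + \Omega^2)} of half-width `transfer_width`,
#' and direct saturation of the free state near zero offset a Lorentzian
#' \eqn{D(\Omega)} of half-width `direct_sat_width`. This reproduces the
#' shapes the downstream estimators consume; it is not a Bloch-McConnell
#' simulation of the exchange physics.
#'
#' @param offsets saturation offsets (kHz), symmetric about 0; default the
#'   standard series -28 ... 28 kHz
#' @param bandwidth saturation field strength (Hz), metadata
#' @param per_residue_bound_fraction vector in \[0,1\], one entry per residue
#' @param transfer_width effective saturation half-width of the bound state
#'   (kHz); the bound-state resonances are tens of kHz broad, so transfer is
#'   nearly complete at small offsets
#' @param direct_sat_width near-zero-offset direct-saturation half-width
#'   (kHz); of the order of the saturation bandwidth
#' @param noise_sd Gaussian noise SD on the ratios
#' @param seed integer RNG seed
#' @return object of class `cest_sim_config`
#' @export
cest_sim_config <- function(offsets = c(-28, -21, -14, -9, -5, -3, -1.5, 0,
                                        1.5, 3, 5, 9, 14, 21, 28),
                            bandwidth = 350,
                            per_residue_bound_fraction = rep(0.5, 140),
                            transfer_width = 10, direct_sat_width = 0.35,
                            noise_sd = 0.02, seed = 1L) {
  stopifnot(all(per_residue_bound_fraction >= 0),
            all(per_residue_bound_fraction <= 1),
            transfer_width > 0, direct_sat_width > 0, noise_sd >= 0)
  for (x in offsets)
    if (!any(abs(offsets + x) < 1e-9))
      stop("offsets must contain symmetric +/- pairs")
  structure(list(offsets = as.numeric(offsets), bandwidth = bandwidth,
                 per_residue_bound_fraction = per_residue_bound_fraction,
                 transfer_width = transfer_width,
                 direct_sat_width = direct_sat_width,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cest_sim_config")
}

#' Simulate CEST profiles with known bound fractions
#'
#' Noiseless ratio: `(1 - p_b * T(offset)) * (1 - D(offset))`, an even
#' function of the offset; Gaussian noise added on top.
#'
#' @param config a [cest_sim_config()]
#' @return list with `profiles` (a [cest_profile_set()]) and `truth`
#'   (per-residue bound fractions, widths, noiseless matrix)
#' @export
generate_cest_profiles <- function(config) {
  stopifnot(inherits(config, "cest_sim_config"))
  pb <- config$per_residue_bound_fraction
  w2 <- config$transfer_width^2
  d2 <- config$direct_sat_width^2
  tr <- w2 / (w2 + config$offsets^2)
  ds <- d2 / (d2 + config$offsets^2)
  clean <- outer(pb, tr, function(p, t) 1 - p * t) *
    rep(1 - ds, each = length(pb))
  set.seed(config$seed)
  ratios <- clean + stats::rnorm(length(clean), sd = config$noise_sd)
  dim(ratios) <- dim(clean)
  profiles <- cest_profile_set(seq_along(pb), config$offsets, ratios,
                               bandwidth = config$bandwidth)
  truth <- list(per_residue_bound_fraction = pb,
                transfer_width = config$transfer_width,
                direct_sat_width = config$direct_sat_width,
                clean_ratios = clean, seed = config$seed)
  list(profiles = profiles, truth = truth)
}

#' Simulate single-exponential transverse relaxation decays
#'
#' Intensity at delay d is `exp(-d / t2_true)` plus Gaussian noise, per
#' residue; `t2_true` may be a vector (one T2 per residue).
#'
#' @param t2_true true T2 value(s) (ms), > 0; recycled to `n_residues`
#' @param delays relaxation delays (ms), non-negative
#' @param noise_sd Gaussian noise SD
#' @param seed integer RNG seed
#' @param n_residues number of residues (defaults to `length(t2_true)`)
#' @return list with `series` (a [relaxation_series()]) and `truth`
#' @export
generate_relaxation <- function(t2_true, delays, noise_sd = 0, seed = 1L,
                                n_residues = length(t2_true)) {
  stopifnot(all(t2_true > 0), all(delays >= 0), noise_sd >= 0)
  t2 <- rep_len(t2_true, n_residues)
  clean <- exp(-outer(t2, delays, function(a, b) b / a))
  set.seed(seed)
  intens <- clean + stats::rnorm(length(clean), sd = noise_sd)
  dim(intens) <- dim(clean)
  list(series = relaxation_series(delays, intens),
       truth = list(t2_true = t2, seed = seed))
}
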