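#' Titration dataset of per-residue HSQC intensity ratios
#'
#' Container for the raw material of a binding-curve analysis: the
#' intensity ratio I/I0 of each backbone amide peak at each total lipid
#' (SUV) concentration, relative to the lipid-free spectrum.
#'
#' @param protein_conc total protein concentration (uM)
#' @param residues integer vector of residue indices (1-based, unique)
#' @param lipid_concs strictly increasing vector of total lipid
#'   concentrations (uM), >= 0
#' @param ratios numeric matrix, residues x concentrations, of I/I0
#' @return object of class `titration_dataset`
#' @export
titration_dataset <- function(protein_conc, residues, lipid_concs, ratios) {
  residues <- as.integer(residues)
  ratios <- as.matrix(ratios)
  stopifnot(protein_conc > 0,
            !anyDuplicated(residues),
            all(lipid_concs >= 0), !is.unsorted(lipid_concs, strictly = TRUE),
            nrow(ratios) == length(residues),
            ncol(ratios) == length(lipid_concs),
            all(is.finite(ratios)))
  structure(list(protein_conc = protein_conc, residues = residues,
                 lipid_concs = as.numeric(lipid_concs), ratios = ratios),
            class = "titration_dataset")
}

#' CEST profile set
#'
#' Per-residue saturation-transfer profiles: intensity ratio I/I0 at each
#' saturation offset, relative to a far-off-resonance reference spectrum.
#'
#' @param residues integer residue indices
#' @param offsets saturation offsets (kHz); must contain symmetric +/- pairs
#'   (0 pairs with itself)
#' @param ratios numeric matrix, residues x offsets
#' @param bandwidth saturation field strength (Hz), metadata
#' @param reference_offset offset of the reference spectrum (kHz)
#' @return object of class `cest_profile_set`
#' @export
cest_profile_set <- function(residues, offsets, ratios, bandwidth = 350,
                             reference_offset = -100) {
  residues <- as.integer(residues)
  ratios <- as.matrix(ratios)
  stopifnot(nrow(ratios) == length(residues),
            ncol(ratios) == length(offsets),
            all(is.finite(ratios)))
  for (x in offsets)
    if (!any(abs(offsets + x) < 1e-9))
      stop(sprintf("offsets are not symmetric: %g kHz has no -%g kHz partner",
                   x, x))
  structure(list(residues = residues, offsets = as.numeric(offsets),
                 ratios = ratios, bandwidth = bandwidth,
                 reference_offset = reference_offset),
            class = "cest_profile_set")
}

#' Relaxation decay series
#'
#' Per-residue peak intensity as a function of relaxation delay, normalised
#' to the zero-delay intensity.
#'
#' @param delays relaxation delays (ms), non-negative
#' @param intensities numeric matrix, residues x delays
#' @param residues integer residue indices
#' @return object of class `relaxation_series`
#' @export
relaxation_series <- function(delays, intensities, residues = seq_len(nrow(intensities))) {
  intensities <- as.matrix(intensities)
  stopifnot(all(delays >= 0), ncol(intensities) == length(delays),
            all(is.finite(intensities)))
  structure(list(delays = as.numeric(delays), intensities = intensities,
                 residues = as.integer(residues)),
            class = "relaxation_series")
}
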