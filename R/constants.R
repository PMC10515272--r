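# Shared physico-chemical constants. Values are package-level documented
# choices: the field reports derived ranges (mw in kDa, pI in pH units) but no
# single canonical table, so the tables used here are stated explicitly.

# Kyte-Doolittle hydropathy (J Mol Biol 1982). Non-standard residues are
# treated as neutral (0) so they never create or destroy a hydrophobic core.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Average (isotope-averaged) residue masses in Da; protein mw = sum + one water.
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# Ambiguity/rare codes: counted for length, average mass for mw, excluded
# from pI charge balance.
RESIDUE_MASS_EXTRA <- c(
  X = mean(RESIDUE_MASS),
  B = mean(RESIDUE_MASS[c("N", "D")]),
  Z = mean(RESIDUE_MASS[c("E", "Q")]),
  U = 150.0388
)

# EMBOSS-style pKa values for the ionisable groups used in pI bisection.
PKA_TABLE <- list(
  n_term = 8.6, c_term = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

# Molar extinction coefficient of the MDA-TBA adduct at 532 nm (L/mol/cm).
MDA_EXTINCTION <- 1.55e5

#' Controlled vocabulary of known SSP families
#'
#' The 38 known plant SSP families used by [classify_families()] as the legal
#' label set, each with its SSP class (post-translationally modified peptide,
#' cysteine-rich peptide, non-Cys-rich/non-PTM peptide, or functional
#' precursor) and predicted mode of action. Shipped motif rules (see
#' [default_family_rules()]) cover the families with published motif
#' evidence; the remaining names exist so that externally produced
#' assignments can be imported and linted against one vocabulary.
#'
#' @return A tibble with columns `family`, `ssp_class` (one of `"PTM"`,
#'   `"CRP"`, `"NonCysNonPTM"`, `"FunctionalPrecursor"`), `mode_of_action`
#'   (one of `"Signal"`, `"Antimicrobial"`, `"PeptidaseInhibitor"`,
#'   `"Unknown"`) and `description`.
#' @export
#' @examples
#' ssp_family_vocabulary()
ssp_family_vocabulary <- function() {
  ptm <- tibble::tribble(
    ~family, ~mode_of_action, ~description,
    "CEP", "Signal", "C-terminally encoded peptide",
    "CLE", "Signal", "Clavata/Embryo Surrounding Region",
    "GLV/RGF/CLEL", "Signal", "Golven/Root Growth Factor",
    "IDA", "Signal", "Inflorescence Deficient in Abscission",
    "PIP", "Signal", "PAMP-induced Secreted Peptide",
    "PSK", "Signal", "Phytosulfokine",
    "PSY", "Signal", "Plant Peptide Containing Sulfated Tyrosine"
  )
  crp <- tibble::tribble(
    ~family, ~mode_of_action, ~description,
    "2SA", "Antimicrobial", "2S Albumin",
    "ECL", "Signal", "Egg Cell 1-Like",
    "EPFL", "Signal", "Epidermal Patterning Factor-Like",
    "GASA", "Signal", "Gibberellic Acid Stimulated in Arabidopsis",
    "HEVEIN", "Antimicrobial", "Hevein",
    "Kunitz", "PeptidaseInhibitor", "Kunitz-P trypsin inhibitor",
    "LAT52-POE", "Signal", "LAT52/Pollen Ole e 1 Allergen",
    "MEG", "Signal", "Maternally Expressed Gene",
    "N26", "Signal", "Nodulin26",
    "nsLTP", "Signal", "non-specific Lipid Transfer Protein",
    "PCY", "Signal", "Plantcyanin/Chemocyanin",
    "PDF", "Antimicrobial", "Plant Defensin",
    "RALF", "Signal", "Rapid Alkalinization Factor",
    "RC", "Signal", "Root Cap",
    "STIG-GRI", "Signal", "Stigma1/GRI",
    "T2SPI", "PeptidaseInhibitor", "Potato type II proteinase inhibitor",
    "THL", "Antimicrobial", "Thionin-like",
    "TPD", "Signal", "Tapetum Determinant 1",
    "Kaz", "PeptidaseInhibitor", "Kazal family inhibitors",
    "PDL", "Antimicrobial", "Plant Defensin-like",
    "LCR", "Unknown", "Low-molecular weight Cys-rich",
    "TAX", "Signal", "Taximin",
    "SCR/SP11", "Signal", "S-locus Cysteine Rich"
  )
  ncnp <- tibble::tribble(
    ~family, ~mode_of_action, ~description,
    "CTLA", "PeptidaseInhibitor", "Cytotoxic T-lymphocyte antigen-2 alpha",
    "GRP", "Unknown", "Glycine-rich Protein",
    "PhyCys", "PeptidaseInhibitor", "Phytocystatin",
    "PNP", "Signal", "Plant Natriuretic Peptide",
    "PRP669", "Unknown", "Pro-rich Protein Group 669",
    "Subln", "PeptidaseInhibitor", "Subtilisin inhibitor"
  )
  fp <- tibble::tribble(
    ~family, ~mode_of_action, ~description,
    "CAPE", "Signal", "CAP-derived Peptide",
    "MtSUBPEP", "Signal", "Subtilisin-embedded Plant Elicitor Peptide"
  )
  dplyr::bind_rows(
    dplyr::mutate(ptm, ssp_class = "PTM"),
    dplyr::mutate(crp, ssp_class = "CRP"),
    dplyr::mutate(ncnp, ssp_class = "NonCysNonPTM"),
    dplyr::mutate(fp, ssp_class = "FunctionalPrecursor")
  ) %>%
    dplyr::select("family", "ssp_class", "mode_of_action", "description")
}
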