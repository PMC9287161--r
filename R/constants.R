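# Shared constants: amino acid alphabet, hydropathy and charge tables,
# signal peptide classes and organism groups.

#' Standard amino acid alphabet (20 residues)
#' @keywords internal
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Non-standard residue codes mapped to the UNK token for encoding purposes.
AA_NONSTANDARD <- c("B", "Z", "X", "U", "O", "J")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values from the standard Kyte-Doolittle table,
#' frozen as a constant. Positive values are hydrophobic.
#' @format Named numeric vector over the 20 standard amino acids.
#' @export
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Residue net charge at pH 7: Lys/Arg +1, Asp/Glu -1, His configurable
# (default 0), everything else 0.
CHARGE_PH7 <- c(K = 1, R = 1, D = -1, E = -1)

#' Signal peptide classes
#'
#' The six global sequence classes: no signal peptide, plus the five SP
#' types defined by translocation pathway (Sec vs Tat) and cleaving
#' signal peptidase (SPase I, II, III).
#' @export
SP_CLASSES <- c("NO_SP", "SEC_SPI", "SEC_SPII", "SEC_SPIII",
                "TAT_SPI", "TAT_SPII")

#' Organism groups
#'
#' The four organism groups carried by training data, plus the UNKNOWN
#' token used for sequences of unknown origin at prediction time.
#' @export
ORGANISM_GROUPS <- c("ARCHAEA", "EUKARYA", "GRAM_POS", "GRAM_NEG")

ORGANISM_GROUPS_EXT <- c(ORGANISM_GROUPS, "UNKNOWN")

# Annotation characters of the 3-line training format, per class.
# Tat/SPII shares "L" with Sec/SPII; the header class field disambiguates.
SP_ANNOT_CHAR <- c(SEC_SPI = "S", SEC_SPII = "L", SEC_SPIII = "P",
                   TAT_SPI = "T", TAT_SPII = "L")

split_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_sp_class <- function(cls) cls %in% SP_CLASSES[-1]

check_class <- function(cls) {
  if (!is.character(cls) || length(cls) != 1L || !cls %in% SP_CLASSES)
    stop("unknown SP class: ", paste(cls, collapse = ","))
  cls
}

check_group <- function(group, allow_unknown = TRUE) {
  ok <- if (allow_unknown) ORGANISM_GROUPS_EXT else ORGANISM_GROUPS
  if (!is.character(group) || length(group) != 1L || !group %in% ok)
    stop("unknown organism group: ", paste(group, collapse = ","))
  group
}
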