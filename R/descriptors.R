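#' Built-in amino-acid side-chain descriptor table
#'
#' A synthetic stand-in descriptor table assembled from standard published
#' per-residue scales, one row per proteinogenic l-amino acid.  Columns:
#'
#' * `hydrophobicity` — Fauchere–Pliska side-chain partition parameter pi
#'   (octanol/water log P increment relative to glycine).
#' * `hydration` — Hopp–Woods hydrophilicity value (larger = more readily
#'   hydrated side chain).
#' * `polarity` — Grantham polarity index.
#' * `hydropathy` — Kyte–Doolittle hydropathy index.
#' * `charge` — formal side-chain charge at pH ~8 (Asp/Glu -1, Lys/Arg +1,
#'   His treated as neutral).
#' * `volume` — Zamyatnin residue volume, cubic Angstrom (glycine is the
#'   smallest).
#'
#' These are generic literature scales chosen to span the property classes
#' commonly used in classical QSAR (hydrophobicity, hydration, polarity,
#' hydropathy, charge, size); they are not transcribed from any specific
#' study's supplementary material.
#'
#' @return data.frame with columns `ligand_id` (three-letter code), `name`,
#'   and the six descriptors.
#' @examples
#' d <- builtin_descriptor_table()
#' d[which.min(d$volume), "ligand_id"]  # "Gly"
#' @export
builtin_descriptor_table <- function() {
  tab <- data.frame(
    ligand_id = c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                  "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                  "Thr", "Trp", "Tyr", "Val"),
    name = c("alanine", "arginine", "asparagine", "aspartate", "cysteine",
             "glutamine", "glutamate", "glycine", "histidine", "isoleucine",
             "leucine", "lysine", "methionine", "phenylalanine", "proline",
             "serine", "threonine", "tryptophan", "tyrosine", "valine"),
    hydrophobicity = c(0.31, -1.01, -0.60, -0.77, 1.54, -0.22, -0.64, 0.00,
                       0.13, 1.80, 1.70, -0.99, 1.23, 1.79, 0.72, -0.04,
                       0.26, 2.25, 0.96, 1.22),
    hydration = c(-0.5, 3.0, 0.2, 3.0, -1.0, 0.2, 3.0, 0.0, -0.5, -1.8,
                  -1.8, 3.0, -1.3, -2.5, 0.0, 0.3, -0.4, -3.4, -2.3, -1.5),
    polarity = c(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4, 5.2,
                 4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9),
    hydropathy = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
                   3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
    charge = c(0, 1, 0, -1, 0, 0, -1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    volume = c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1, 153.2,
               166.7, 166.7, 168.6, 162.9, 189.9, 112.7, 89.0, 116.1, 227.8,
               193.6, 140.0),
    stringsAsFactors = FALSE
  )
  tab
}
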