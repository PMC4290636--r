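#' Physical constants used throughout the pipeline
#'
#' @description
#' `PROTON_MASS` is the mass of a charging proton in daltons, used to convert
#' between m/z and neutral monoisotopic mass. `PHOSPHO_MASS` is the
#' monoisotopic mass of one phosphate group (HPO3) lost per dephosphorylation
#' event; alkaline-phosphatase treatment shifts a phosphopeptide's neutral
#' mass down by `n * PHOSPHO_MASS` for n phosphorylated residues.
#'
#' @format Numeric scalars (Da).
#' @name constants
NULL

#' @rdname constants
#' @export
PROTON_MASS <- 1.00728

#' @rdname constants
#' @export
PHOSPHO_MASS <- 79.966
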