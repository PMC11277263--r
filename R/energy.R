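#' Ensemble free energy of an RNA sequence
#'
#' Partition-function (ensemble) free energy at 37 degrees C under the
#' standard nearest-neighbor parameter set, computed with the ViennaRNA
#' `RNAfold` program (`-p`, default parameters). T is mapped to U before
#' folding. Deterministic.
#'
#' @param sequence nucleotide string (DNA or RNA alphabet).
#' @return ensemble free energy in kcal/mol (0 for sequences with no
#'   pairable structure).
#' @export
ensemble_free_energy <- function(sequence) {
  if (Sys.which("RNAfold") == "")
    stop("RNAfold (ViennaRNA) not found on PATH")
  rna <- toupper(gsub("T", "U", gsub("t", "u", sequence)))
  owd <- setwd(tempdir())
  on.exit(setwd(owd))
  out <- system2("RNAfold", c("-p", "--noPS", "--noDP"),
                 input = rna, stdout = TRUE, stderr = FALSE)
  m <- regmatches(out, regexpr("\\[\\s*(-?[0-9.]+)\\s*\\]", out))
  m <- m[lengths(regmatches(m, gregexpr("[0-9]", m))) > 0]
  if (!length(m)) stop("could not parse RNAfold ensemble energy output")
  as.numeric(gsub("[][ ]", "", m[[1]]))
}
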