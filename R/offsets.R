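#' Precursor-to-mature residue offsets for the six milk protein genes
#'
#' Milk protein variant nomenclature numbers amino acids in the mature
#' (secreted) protein, i.e. after cleavage of the N-terminal signal peptide,
#' while translation of a CDS yields precursor (pre-protein) numbering. The
#' offset is the number of residues subtracted from a precursor position to
#' obtain the mature position.
#'
#' Two configurations ship:
#' \describe{
#'   \item{`"table"`}{Offsets derived from the printed mature/precursor
#'     position pairs of the allele catalog (e.g. kappa-casein 66 (87) gives
#'     21). These reproduce the published numbering and are the default. Note
#'     that for CSN2 (50) and LALBA (48) they differ from the biological
#'     signal peptide lengths.}
#'   \item{`"canonical"`}{Biological signal peptide lengths (CSN2 15,
#'     LALBA 19), for users who prefer strict biochemistry over the published
#'     numbering.}
#' }
#'
#' @param set Which configuration, `"table"` (default) or `"canonical"`.
#' @return Named integer vector gene -> offset.
#' @examples
#' milk_offsets()[["CSN3"]]  # 21
#' @export
milk_offsets <- function(set = c("table", "canonical")) {
  set <- match.arg(set)
  switch(set,
    table = c(CSN1S1 = 15L, CSN2 = 50L, CSN1S2 = 15L,
              CSN3 = 21L, LALBA = 48L, LGB = 16L),
    canonical = c(CSN1S1 = 15L, CSN2 = 15L, CSN1S2 = 15L,
                  CSN3 = 21L, LALBA = 19L, LGB = 16L)
  )
}

#' Convert a precursor residue number to mature-protein numbering
#'
#' @param gene Gene symbol (must be present in `offsets`).
#' @param precursor_residue Positive integer residue position in the
#'   precursor (signal peptide included).
#' @param offsets Named offset vector, see [milk_offsets()].
#' @return The mature residue number (integer), or the character tag
#'   `"pre-mature region"` when the residue lies within the signal peptide.
#' @examples
#' precursor_to_mature("CSN3", 87)  # 66
#' precursor_to_mature("LGB", 134)  # 118
#' @export
precursor_to_mature <- function(gene, precursor_residue,
                                offsets = milk_offsets()) {
  if (!gene %in% names(offsets)) {
    stop("no precursor offset configured for gene '", gene, "'")
  }
  stopifnot(precursor_residue >= 1)
  m <- as.integer(precursor_residue) - offsets[[gene]]
  if (m <= 0L) "pre-mature region" else m
}
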