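#' The canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in the fixed order used for every
#' probability matrix in this package. Column `j` of a probability matrix
#' always refers to `aa_alphabet()[j]`.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# letter -> column index; NA for non-canonical letters
aa_index <- function(letters) {
  match(letters, aa_alphabet())
}

# split a sequence string into single residues
aa_split <- function(sequence_aa) {
  strsplit(sequence_aa, "", fixed = TRUE)[[1]]
}

is_canonical_aa <- function(sequence_aa) {
  nchar(sequence_aa) > 0L &
    !grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), sequence_aa)
}
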