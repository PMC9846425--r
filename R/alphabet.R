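## Residue alphabets and validation helpers.
##
## Canonical residues carry substitution/emission information; ambiguity
## codes are accepted everywhere and treated as scoring-neutral (they emit
## with probability 1 under both the model and the null, so they never move
## a bit-score).

GAP_CHARS <- c("-", ".")

ALPHABETS <- list(
  dna = list(
    canonical = c("A", "C", "G", "T"),
    ambiguity = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")
  ),
  rna = list(
    canonical = c("A", "C", "G", "U"),
    ambiguity = c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "T")
  ),
  protein = list(
    canonical = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
    ambiguity = c("X", "B", "Z", "J", "U", "O")
  )
)

#' Resolve an alphabet name
#'
#' @param alphabet One of `"dna"`, `"rna"`, `"protein"`.
#' @return A list with elements `name`, `canonical` and `ambiguity`.
#' @keywords internal
resolve_alphabet <- function(alphabet) {
  alphabet <- match.arg(tolower(alphabet), names(ALPHABETS))
  c(list(name = alphabet), ALPHABETS[[alphabet]])
}

#' Guess the alphabet of a set of residue strings
#'
#' Sequences dominated by A/C/G/T/U/N are called nucleotide (DNA unless U
#' outnumbers T), anything else protein. Used when the caller does not
#' declare an alphabet.
#'
#' @param x Character vector of (possibly gapped) sequences.
#' @return Alphabet name.
#' @keywords internal
guess_alphabet <- function(x) {
  chars <- toupper(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE))
  chars <- chars[!chars %in% GAP_CHARS]
  if (length(chars) == 0L) return("dna")
  nuc <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  if (nuc < 0.9) return("protein")
  if (sum(chars == "U") > sum(chars == "T")) "rna" else "dna"
}

## Error unless every non-gap character of `x` belongs to `alph`.
## `what` names the offending record in the message.
validate_residues <- function(x, alph, what = "sequence") {
  chars <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  chars <- setdiff(chars, GAP_CHARS)
  ok <- c(alph$canonical, alph$ambiguity)
  bad <- setdiff(chars, ok)
  if (length(bad) > 0L) {
    stop(sprintf("invalid %s alphabet character(s) %s in %s",
                 alph$name, paste(sQuote(bad), collapse = ", "), what),
         call. = FALSE)
  }
  invisible(TRUE)
}
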