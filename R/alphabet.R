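#' Monomer alphabets
#'
#' Construct the symbol alphabet over which sequences are designed. The two
#' shipped modes are `"dna"` (M = 4 channels, order A, C, G, T) and
#' `"protein"` (M = 20 canonical amino acids, alphabetical one-letter codes).
#' Arbitrary alphabets with M >= 2 unique symbols are accepted for toy
#' landscapes via a character vector.
#'
#' @param x `"dna"`, `"protein"`, or a character vector of unique
#'   single-character symbols (length >= 2).
#' @return An object of class `fsp_alphabet`: a character vector of symbols
#'   with a `mode` attribute.
#' @examples
#' alphabet("dna")
#' alphabet(c("0", "1"))
#' @export
alphabet <- function(x = "dna") {
  if (is.character(x) && length(x) == 1 && x %in% c("dna", "protein")) {
    symbols <- switch(x,
      dna = c("A", "C", "G", "T"),
      protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
    )
    mode <- x
  } else {
    symbols <- as.character(x)
    if (length(symbols) < 2) stop("an alphabet needs at least 2 symbols")
    if (anyDuplicated(symbols)) stop("alphabet symbols must be unique")
    if (any(nchar(symbols) != 1)) stop("alphabet symbols must be single characters")
    mode <- "custom"
  }
  structure(symbols, mode = mode, class = "fsp_alphabet")
}

#' @export
print.fsp_alphabet <- function(x, ...) {
  cat(sprintf("<alphabet: %s, M = %d> %s\n",
              attr(x, "mode"), length(x), paste(unclass(x), collapse = "")))
  invisible(x)
}

n_channels <- function(alph) length(alph)

#' Convert one-hot matrices to character strings
#'
#' @param x an N x M one-hot matrix, or a list of them.
#' @param alph an [alphabet()].
#' @return A character vector of sequences.
#' @export
onehot_to_string <- function(x, alph) {
  if (is.list(x)) return(vapply(x, onehot_to_string, character(1), alph = alph))
  stopifnot(is.matrix(x), ncol(x) == length(alph))
  paste(unclass(alph)[max.col(x, ties.method = "first")], collapse = "")
}

#' Convert character strings to one-hot matrices
#'
#' @param s a character vector of sequences over `alph`.
#' @param alph an [alphabet()].
#' @return A one-hot matrix for a single string, otherwise a list of matrices.
#' @export
string_to_onehot <- function(s, alph) {
  one <- function(si) {
    chars <- strsplit(si, "", fixed = TRUE)[[1]]
    idx <- match(chars, unclass(alph))
    if (anyNA(idx)) stop("sequence contains symbols outside the alphabet: ", si)
    m <- matrix(0, nrow = length(idx), ncol = length(alph))
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  if (length(s) == 1) one(s) else lapply(s, one)
}
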