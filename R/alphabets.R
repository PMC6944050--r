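#' Sequence alphabets
#'
#' Ordered symbol sets over which sequences and word sets are defined.
#' `dna_alphabet()`, `rna_alphabet()` and `protein_alphabet()` return the
#' standard presets; `alphabet_preset()` resolves one by name (as used in
#' config files).
#'
#' @return A character vector of distinct single-character symbols.
#' @examples
#' dna_alphabet()
#' alphabet_preset("protein")
#' @export
dna_alphabet <- function() c("A", "C", "G", "T")

#' @rdname dna_alphabet
#' @export
rna_alphabet <- function() c("A", "C", "G", "U")

#' @rdname dna_alphabet
#' @export
protein_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' @rdname dna_alphabet
#' @param name One of `"DNA"`, `"RNA"`, `"PROTEIN"` (case-insensitive).
#' @export
alphabet_preset <- function(name) {
  switch(toupper(name),
    DNA = dna_alphabet(),
    RNA = rna_alphabet(),
    PROTEIN = protein_alphabet(),
    stop("unknown alphabet preset: ", name)
  )
}

check_alphabet <- function(alphabet) {
  if (!is.character(alphabet) || length(alphabet) == 0L) {
    stop("alphabet must be a nonempty character vector")
  }
  if (any(nchar(alphabet) != 1L)) stop("alphabet symbols must be single characters")
  if (anyDuplicated(alphabet)) stop("alphabet symbols must be distinct")
  invisible(alphabet)
}

#' Word sets for feature extraction
#'
#' A word set is an ordered vector of p distinct nonempty strings over an
#' alphabet; the feature vector of a sequence counts the (overlapping)
#' occurrences of each word. `k_grams()` enumerates all words of length `k`
#' in lexicographic order of the alphabet; `one_grams()` is the default used
#' throughout (the single-symbol counts).
#'
#' @param alphabet Character vector of symbols, e.g. [dna_alphabet()].
#' @param k Word length, a positive integer.
#' @return Character vector of words.
#' @examples
#' one_grams(dna_alphabet())
#' k_grams(dna_alphabet(), 2)
#' @export
k_grams <- function(alphabet, k) {
  check_alphabet(alphabet)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  grids <- rev(rep(list(alphabet), k))
  g <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; reverse for lexicographic order
  apply(g[, rev(seq_len(k)), drop = FALSE], 1L, paste0, collapse = "")
}

#' @rdname k_grams
#' @export
one_grams <- function(alphabet = dna_alphabet()) {
  check_alphabet(alphabet)
  alphabet
}

check_word_set <- function(words) {
  if (!is.character(words) || length(words) == 0L) {
    stop("word set must contain at least one word")
  }
  if (any(nchar(words) == 0L)) stop("the empty string is not a valid word")
  if (anyDuplicated(words)) stop("words must be distinct")
  invisible(words)
}
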