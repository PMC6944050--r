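#' Count word occurrences in a sequence
#'
#' The feature vector of a sequence: the number of (overlapping)
#' occurrences of every word of the word set. A word longer than the
#' sequence simply counts 0.
#'
#' @param residues A single sequence (character scalar) over the word
#'   alphabet.
#' @param words Word set, e.g. [one_grams()] or [k_grams()].
#' @return Named integer-valued numeric vector of length `length(words)`.
#' @examples
#' count_words("ACGT", one_grams(dna_alphabet()))
#' count_words("AAA", "AA")  # overlapping: 2
#' @export
count_words <- function(residues, words) {
  stopifnot(is.character(residues), length(residues) == 1L)
  check_word_set(words)
  subj <- Biostrings::BString(residues)
  counts <- vapply(words, function(w) {
    Biostrings::countPattern(w, subj)
  }, integer(1L))
  names(counts) <- words
  as.numeric(counts)
}

#' Transformation functions between feature spaces
#'
#' A transformation maps the p-vector of word counts into another feature
#' space. `phi_identity()` is the linear map (counts unchanged);
#' `phi_power(q)` raises every component to the power `q`, with `q = 2`
#' the quadratic non-linear map used throughout; `phi_composite()` wraps
#' an arbitrary total function with a declared output dimension.
#'
#' @param q Positive real exponent. Non-integer `q` on a negative input
#'   is an error at application time (count inputs are non-negative, so
#'   the quadratic map is always safe).
#' @param fun Function taking a numeric vector of length `input_dim` (or
#'   any length if `input_dim` is `NULL`) and returning a finite numeric
#'   vector of length `output_dim`.
#' @param output_dim,input_dim Declared dimensions of the composite map.
#' @return An object of class `transform_spec`.
#' @examples
#' apply_transform(c(1, 2, 3, 4), phi_power(2))
#' @export
phi_identity <- function() {
  structure(list(kind = "identity"), class = "transform_spec")
}

#' @rdname phi_identity
#' @export
phi_power <- function(q = 2) {
  stopifnot(is.numeric(q), length(q) == 1L, q > 0)
  structure(list(kind = "power", q = q), class = "transform_spec")
}

#' @rdname phi_identity
#' @export
phi_composite <- function(fun, output_dim, input_dim = NULL) {
  stopifnot(is.function(fun), output_dim >= 1L)
  structure(list(kind = "composite", fun = fun,
                 output_dim = as.integer(output_dim),
                 input_dim = if (!is.null(input_dim)) as.integer(input_dim)),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("<transform_spec>", switch(x$kind,
    identity = "identity (linear)",
    power = paste0("elementwise power q=", x$q),
    composite = paste0("composite -> R^", x$output_dim)), "\n")
  invisible(x)
}

#' Apply a transformation function to a feature vector
#'
#' @param x Numeric feature vector.
#' @param phi A [transform_spec][phi_identity] (default identity).
#' @return Transformed numeric vector; the identity map returns `x`
#'   unchanged.
#' @export
apply_transform <- function(x, phi = phi_identity()) {
  stopifnot(is.numeric(x), inherits(phi, "transform_spec"))
  out <- switch(phi$kind,
    identity = x,
    power = {
      if (phi$q != round(phi$q) && any(x < 0)) {
        stop("non-integer power of a negative component")
      }
      x^phi$q
    },
    composite = {
      if (!is.null(phi$input_dim) && length(x) != phi$input_dim) {
        stop("input dimension mismatch: expected ", phi$input_dim,
             ", got ", length(x))
      }
      y <- phi$fun(x)
      if (length(y) != phi$output_dim) {
        stop("composite transform returned length ", length(y),
             ", declared ", phi$output_dim)
      }
      y
    },
    stop("unknown transform kind: ", phi$kind)
  )
  if (any(!is.finite(out))) stop("transform produced non-finite values")
  out
}

#' Embed a sequence-set in feature space
#'
#' Maps every sequence of the set to its (optionally transformed) word
#' count vector; row i is the feature vector of sequence i, in set order.
#'
#' @param x A [seq_set()].
#' @param words Word set (default DNA 1-grams).
#' @param phi Transformation function (default identity).
#' @param frequencies If `TRUE`, counts are divided by the retained
#'   sequence length before the transform. Raw counts are the default:
#'   the length-scaling behaviour of the simulator experiments depends on
#'   counts growing with sequence length.
#' @return Numeric matrix, one row per sequence (rownames = sequence
#'   ids), columns named by words for elementwise transforms.
#' @examples
#' s <- seq_set("demo", c(s1 = "ACGT", s2 = "AAAA"))
#' embed_seq_set(s)
#' embed_seq_set(s, phi = phi_power(2))
#' @export
embed_seq_set <- function(x, words = one_grams(dna_alphabet()),
                          phi = phi_identity(), frequencies = FALSE) {
  stopifnot(inherits(x, "seq_set"))
  rows <- lapply(x$sequences, function(s) {
    v <- count_words(s, words)
    if (frequencies) v <- v / nchar(s)
    apply_transform(v, phi)
  })
  dims <- vapply(rows, length, integer(1L))
  if (length(unique(dims)) != 1L) stop("transform produced inconsistent dimensions")
  F <- do.call(rbind, rows)
  rownames(F) <- names(x$sequences)
  if (ncol(F) == length(words) && phi$kind != "composite") colnames(F) <- words
  F
}
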