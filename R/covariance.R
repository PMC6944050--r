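#' Variance-covariance structure of a feature matrix
#'
#' Summarizes a sequence-set's cloud of feature vectors by its p' x p'
#' variance-covariance matrix, the set's representation in feature space.
#' Two estimators are available:
#'
#' * `centered = TRUE` (default): the sample covariance with mean
#'   subtraction and divisor n - 1 (zero matrix for n = 1). This reads
#'   "variance-covariance" literally and is always positive semidefinite.
#' * `centered = FALSE`: the uncentered second moment `crossprod(F)/n`,
#'   matching the model assumption that the transformed features have
#'   mean zero.
#'
#' The result is explicitly symmetrized as (M + M')/2. Rank-deficient
#' output is expected and fine: everything downstream is inverse-free.
#'
#' @param F Numeric matrix, one row per sequence (n >= 1 rows).
#' @param centered Use mean-subtracted sample covariance (default) or the
#'   uncentered second moment.
#' @param set_id Optional identifier carried into the result.
#' @return An object of class `cov_structure`: list with `matrix`
#'   (p' x p' symmetric), `mean` (column means), `n`, `centered`,
#'   `set_id`.
#' @examples
#' estimate_cov(rbind(c(0, 0), c(2, 2)))  # matrix of 2s
#' @export
estimate_cov <- function(F, centered = TRUE, set_id = NULL) {
  if (!is.matrix(F)) F <- matrix(F, nrow = 1L)
  stopifnot(is.numeric(F), nrow(F) >= 1L)
  if (any(!is.finite(F))) stop("feature matrix contains non-finite values")
  n <- nrow(F)
  mu <- colMeans(F)
  M <- if (centered) {
    if (n >= 2L) stats::cov(F) else matrix(0, ncol(F), ncol(F))
  } else {
    crossprod(F) / n
  }
  M <- unname((M + t(M)) / 2)
  structure(list(matrix = M, mean = unname(mu), n = n,
                 centered = isTRUE(centered), set_id = set_id),
            class = "cov_structure")
}

#' @export
print.cov_structure <- function(x, ...) {
  cat("<cov_structure>", if (!is.null(x$set_id)) x$set_id else "",
      sprintf("p'=%d, n=%d, %s\n", ncol(x$matrix), x$n,
              if (x$centered) "centered" else "uncentered"))
  invisible(x)
}

#' Covariance structure of a sequence-set
#'
#' Composition of [embed_seq_set()] and [estimate_cov()]: the one-call
#' route from a set of sequences to its feature-space representation.
#'
#' @inheritParams embed_seq_set
#' @inheritParams estimate_cov
#' @return A `cov_structure` whose `set_id` is the set's.
#' @examples
#' s <- seq_set("demo", c(a = "AAAA", b = "CCCC"))
#' cov_of_set(s)$matrix  # diagonal (8, 8, 0, 0), cov(A, C) = -8
#' @export
cov_of_set <- function(x, words = one_grams(dna_alphabet()),
                       phi = phi_identity(), centered = TRUE,
                       frequencies = FALSE) {
  stopifnot(inherits(x, "seq_set"))
  F <- embed_seq_set(x, words = words, phi = phi, frequencies = frequencies)
  estimate_cov(F, centered = centered, set_id = x$set_id)
}

as_cov_matrix <- function(psi) {
  if (inherits(psi, "cov_structure")) return(psi$matrix)
  if (is.matrix(psi) && is.numeric(psi)) return(psi)
  stop("expected a cov_structure or a numeric matrix")
}
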