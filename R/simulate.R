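#' Composition profile of a sequence-set
#'
#' The per-sequence multinomial model behind the simulator: for every
#' sequence its base probabilities (maximum-likelihood relative
#' frequencies, no pseudocount by default) and its original length.
#'
#' @param x A [seq_set()] with nonempty sequences.
#' @param alphabet Symbols over which the composition is taken.
#' @param pseudocount Added to every symbol count before normalizing
#'   (default 0; a small value keeps every base reachable in generated
#'   data).
#' @return An object of class `composition_profile`: list with
#'   `set_id`, `alphabet`, `probs` (n x |alphabet| matrix, rows sum to
#'   1, rownames = sequence ids), `lengths` (named integer vector).
#' @examples
#' estimate_composition(seq_set("s", c(a = "AACG")))$probs
#' @export
estimate_composition <- function(x, alphabet = dna_alphabet(), pseudocount = 0) {
  stopifnot(inherits(x, "seq_set"), pseudocount >= 0)
  check_alphabet(alphabet)
  counts <- t(vapply(x$sequences, function(s) {
    count_words(s, alphabet)
  }, numeric(length(alphabet))))
  counts <- counts + pseudocount
  probs <- counts / rowSums(counts)
  colnames(probs) <- alphabet
  rownames(probs) <- names(x$sequences)
  composition_profile(x$set_id, probs, nchar(x$sequences), alphabet)
}

#' @rdname estimate_composition
#' @param set_id Identifier for the profile.
#' @param probs n x |alphabet| matrix of base probabilities (rows sum to
#'   1).
#' @param lengths Per-sequence original lengths (positive integers).
#' @export
composition_profile <- function(set_id, probs, lengths,
                                alphabet = dna_alphabet()) {
  check_alphabet(alphabet)
  probs <- as.matrix(probs)
  if (ncol(probs) != length(alphabet)) stop("probs columns must match the alphabet")
  if (any(probs < 0)) stop("base probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-12)) stop("each row of probs must sum to 1")
  lengths <- as.integer(round(lengths))
  if (length(lengths) != nrow(probs)) stop("one length per sequence required")
  if (any(lengths < 1L)) stop("lengths must be >= 1")
  if (is.null(rownames(probs))) rownames(probs) <- paste0("seq", seq_len(nrow(probs)))
  names(lengths) <- rownames(probs)
  colnames(probs) <- alphabet
  structure(list(set_id = set_id, alphabet = alphabet,
                 probs = probs, lengths = lengths),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> '%s': %d sequence(s) over {%s}\n",
              x$set_id, nrow(x$probs), paste(x$alphabet, collapse = ",")))
  invisible(x)
}

#' Deterministic RNG substream seed
#'
#' Mixes a user seed with stream indices (replicate, sequence, ...) into
#' a single 31-bit seed, so every generated sequence has its own
#' reproducible, order-independent stream.
#'
#' @param seed Integer base seed.
#' @param ... Further non-negative integer indices.
#' @return An integer in \[0, 2^31 - 2\].
#' @export
substream_seed <- function(seed, ...) {
  ix <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  for (v in ix) h <- (h * 69069 + v + 1) %% 2147483647
  as.integer(h)
}

#' Generate one i.i.d. multinomial sequence
#'
#' Draws `length` symbols independently from `base_probs`. Consumes the
#' current R RNG stream; seed it (directly or via [substream_seed()])
#' for reproducibility.
#'
#' @param base_probs Probability vector over `alphabet` (sums to 1).
#' @param length Positive integer sequence length.
#' @param alphabet Symbols to draw from.
#' @return A single character string of the drawn residues.
#' @export
generate_sequence <- function(base_probs, length, alphabet = dna_alphabet()) {
  check_alphabet(alphabet)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be a positive integer")
  if (base::length(base_probs) != base::length(alphabet) ||
      any(base_probs < 0) || abs(sum(base_probs) - 1) > 1e-12) {
    stop("base_probs must be a probability vector over the alphabet")
  }
  paste(sample(alphabet, size = length, replace = TRUE, prob = base_probs),
        collapse = "")
}

#' Generate a heterogeneous sequence-set from a composition profile
#'
#' One sequence per profile row, drawn i.i.d. from that row's base
#' probabilities with length `round(factor * original_length)` (floor
#' 1). As `factor` grows, each generated sequence's empirical
#' composition converges to its prototype row — the sense in which the
#' simulated set approaches the prototype's limiting distribution. Each
#' sequence uses its own RNG substream keyed by
#' `(seed, replicate, sequence index)`, so output is reproducible and
#' independent of generation order.
#'
#' @param profile A [composition_profile()].
#' @param factor Length multiplier n' >= 1 (real).
#' @param seed Integer seed.
#' @param replicate Replicate index (>= 1), part of the RNG key and the
#'   default set id suffix.
#' @param set_id Optional id for the generated set (default
#'   `"<profile id>_r<replicate>"`).
#' @return A [seq_set()].
#' @export
generate_seq_set <- function(profile, factor = 1, seed, replicate = 1L,
                             set_id = NULL) {
  stopifnot(inherits(profile, "composition_profile"), factor >= 1)
  n <- nrow(profile$probs)
  lens <- pmax(1L, as.integer(round(factor * profile$lengths)))
  seqs <- vapply(seq_len(n), function(i) {
    set.seed(substream_seed(seed, replicate, i))
    generate_sequence(profile$probs[i, ], lens[i], profile$alphabet)
  }, character(1L))
  names(seqs) <- rownames(profile$probs)
  if (is.null(set_id)) set_id <- paste0(profile$set_id, "_r", replicate)
  seq_set(set_id, seqs)
}

#' Generate a collection of simulated sequence-sets
#'
#' `m` independent sets from the same composition profile (default
#' `m = 20`, a typical random-sample size for these experiments), ids
#' suffixed by replicate index.
#'
#' @inheritParams generate_seq_set
#' @param m Number of sets to generate.
#' @param label Collection label (default the profile's id).
#' @return A [seq_collection()].
#' @export
generate_collection <- function(profile, m = 20L, factor = 1, seed,
                                label = profile$set_id) {
  stopifnot(m >= 1L)
  sets <- lapply(seq_len(m), function(r) {
    generate_seq_set(profile, factor = factor, seed = seed, replicate = r)
  })
  seq_collection(label, sets)
}

#' Total-variation distance between composition vectors
#'
#' Half the L1 distance between two probability vectors; in \[0, 1\].
#'
#' @param p,q Probability vectors of equal length.
#' @return Non-negative real number.
#' @export
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  sum(abs(p - q)) / 2
}

#' Convergence diagnostic for the simulator
#'
#' Empirical content of the limiting-distribution condition: for each
#' length factor, generate `reps` sets and measure the per-sequence
#' total-variation distance between the generated and prototype base
#' frequencies. The median TV distance shrinks as the factor grows
#' (O(1/sqrt(length)) sampling noise).
#'
#' @param profile A [composition_profile()].
#' @param factors Numeric vector of length factors (all >= 1).
#' @param reps Replicates per factor (>= 3).
#' @param seed Integer seed.
#' @return An object of class `convergence_report`: list with `detail`
#'   (data.frame: factor, replicate, seq_id, tv) and `summary`
#'   (data.frame: factor, median_tv, mean_tv).
#' @export
convergence_diagnostic <- function(profile, factors = c(1, 10, 100),
                                   reps = 20L, seed) {
  stopifnot(inherits(profile, "composition_profile"),
            all(factors >= 1), reps >= 3L)
  rows <- list()
  for (fi in seq_along(factors)) {
    for (r in seq_len(reps)) {
      g <- generate_seq_set(profile, factor = factors[fi],
                            seed = substream_seed(seed, fi), replicate = r)
      gp <- estimate_composition(g, alphabet = profile$alphabet)
      tv <- vapply(seq_len(nrow(profile$probs)), function(i) {
        tv_distance(gp$probs[i, ], profile$probs[i, ])
      }, numeric(1L))
      rows[[length(rows) + 1L]] <- data.frame(
        factor = factors[fi], replicate = r,
        seq_id = rownames(profile$probs), tv = tv,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  detail <- do.call(rbind, rows)
  med <- vapply(factors, function(f) stats::median(detail$tv[detail$factor == f]),
                numeric(1L))
  mn <- vapply(factors, function(f) mean(detail$tv[detail$factor == f]),
               numeric(1L))
  structure(list(detail = detail,
                 summary = data.frame(factor = factors, median_tv = med,
                                      mean_tv = mn)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report>\n")
  print(x$summary)
  invisible(x)
}

#' Sliding-window composition of a sequence
#'
#' Local base frequencies along a sequence: windows start at offsets
#' 0, step, 2*step, ... with `start + window <= length`. Real sequences
#' are rarely compositionally homogeneous along their length; this table
#' makes that visible.
#'
#' @param residues Single sequence string.
#' @param window Window width (<= sequence length).
#' @param step Offset between windows (default `window`,
#'   non-overlapping).
#' @param alphabet Symbols whose frequencies are reported.
#' @return data.frame with `start`, `end` (1-based, inclusive) and one
#'   frequency column per symbol.
#' @examples
#' sliding_window_composition("AAAACCCC", window = 4)
#' @export
sliding_window_composition <- function(residues, window, step = window,
                                       alphabet = dna_alphabet()) {
  stopifnot(is.character(residues), length(residues) == 1L)
  check_alphabet(alphabet)
  len <- nchar(residues)
  window <- as.integer(window)
  step <- as.integer(step)
  if (is.na(window) || window < 1L) stop("window must be a positive integer")
  if (is.na(step) || step < 1L) stop("step must be a positive integer")
  if (window > len) stop("window (", window, ") exceeds sequence length (", len, ")")
  starts <- seq.int(1L, len - window + 1L, by = step)
  freqs <- t(vapply(starts, function(s) {
    w <- substring(residues, s, s + window - 1L)
    count_words(w, alphabet) / window
  }, numeric(length(alphabet))))
  colnames(freqs) <- alphabet
  cbind(data.frame(start = starts, end = starts + window - 1L), as.data.frame(freqs))
}

#' Synthetic heterogeneous composition profile
#'
#' Builds a composition profile around a class-level base composition
#' with a deterministic per-sequence tilt, emulating a heterogeneous
#' set whose sequences (like the segments of a viral genome) are
#' distinct relative enrichments of a shared composition. Sequence `i`
#' gets probabilities proportional to
#' `base_probs * (1 + tilt * d_i)`, where `d_i` is a fixed quasi-random
#' contrast pattern in \[-1, 1\]. The tilt is multiplicative in the base
#' composition, so both the mean and the *spread* of the per-sequence
#' compositions carry the class signature — the spread is what the
#' centered covariance structure sees.
#'
#' @param base_probs Class composition, a probability vector over
#'   `alphabet` with all entries > 0.
#' @param n_seq Number of sequences in the profile.
#' @param base_length Prototype length of every sequence.
#' @param tilt Relative enrichment amplitude in \[0, 1)
#'   (0 = all sequences share `base_probs`).
#' @param set_id Profile identifier.
#' @param alphabet Symbols.
#' @return A [composition_profile()].
#' @examples
#' synthetic_profile(c(0.4, 0.3, 0.2, 0.1), n_seq = 4, base_length = 100)
#' @export
synthetic_profile <- function(base_probs, n_seq = 8L, base_length = 1000L,
                              tilt = 0.3, set_id = "synthetic",
                              alphabet = dna_alphabet()) {
  check_alphabet(alphabet)
  stopifnot(length(base_probs) == length(alphabet),
            all(base_probs > 0), abs(sum(base_probs) - 1) < 1e-12,
            n_seq >= 1L, base_length >= 1L, tilt >= 0, tilt < 1)
  p <- length(alphabet)
  golden <- (sqrt(5) - 1) / 2
  probs <- t(vapply(seq_len(n_seq), function(i) {
    d <- 2 * ((seq_len(p) * i * golden) %% 1) - 1   # fixed contrast pattern
    w <- base_probs * (1 + tilt * d)
    w / sum(w)
  }, numeric(p)))
  composition_profile(set_id, probs, rep(base_length, n_seq), alphabet)
}
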