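#' Run configuration
#'
#' Plain-text `key=value` configuration shared by the command-line
#' subcommands. Recognized keys and defaults:
#' `alphabet=DNA` (`DNA|RNA|PROTEIN`), `words=1-grams`
#' (`1-grams|2-grams|3-grams` or a comma-separated explicit list),
#' `transform=identity` (`identity` or `power:q`), `centered=true`,
#' `features=counts` (`counts|frequencies`), `rule=mean`,
#' `linkage=average`, `k=2`, `seed=1`.
#'
#' @param path Optional path to a config file; missing keys take the
#'   defaults above.
#' @param overrides Named list overriding file values (used for
#'   command-line flags).
#' @return An object of class `run_config`: a validated list with
#'   elements `alphabet` (symbol vector), `words`, `phi`, `centered`,
#'   `frequencies`, `rule`, `linkage`, `k`, `seed`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(parts) < 2L) stop("bad config line: ", ln)
      kv[[trimws(parts[1L])]] <- trimws(paste(parts[-1L], collapse = "="))
    }
  }
  for (nm in names(overrides)) {
    if (!is.null(overrides[[nm]])) kv[[nm]] <- overrides[[nm]]
  }
  get <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default

  alphabet <- alphabet_preset(get("alphabet", "DNA"))
  words_spec <- get("words", "1-grams")
  words <- if (grepl("^[0-9]+-grams$", words_spec)) {
    k_grams(alphabet, as.integer(sub("-grams$", "", words_spec)))
  } else {
    check_word_set(trimws(strsplit(words_spec, ",")[[1L]]))
  }
  tr <- get("transform", "identity")
  phi <- if (tr == "identity") {
    phi_identity()
  } else if (grepl("^power:", tr)) {
    phi_power(as.numeric(sub("^power:", "", tr)))
  } else {
    stop("unknown transform: ", tr)
  }
  centered <- tolower(get("centered", "true"))
  if (!centered %in% c("true", "false")) stop("centered must be true or false")
  feats <- get("features", "counts")
  if (!feats %in% c("counts", "frequencies")) {
    stop("features must be counts or frequencies")
  }
  rule <- match.arg(get("rule", "mean"), c("mean", "min", "median"))
  linkage <- match.arg(get("linkage", "average"),
                       c("average", "complete", "single"))
  k <- as.integer(get("k", "2"))
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  seed <- as.integer(get("seed", "1"))
  if (is.na(seed)) stop("seed must be an integer")

  structure(list(alphabet = alphabet, words = words, phi = phi,
                 centered = centered == "true",
                 frequencies = feats == "frequencies",
                 rule = rule, linkage = linkage, k = k, seed = seed),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> alphabet={%s} words=%d transform=%s centered=%s features=%s rule=%s linkage=%s k=%d seed=%d\n",
    paste(x$alphabet, collapse = ","), length(x$words), x$phi$kind,
    x$centered, if (x$frequencies) "frequencies" else "counts",
    x$rule, x$linkage, x$k, x$seed))
  invisible(x)
}
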