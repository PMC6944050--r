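#' Construct a sequence-set
#'
#' A sequence-set is one composite data point: an identifier plus one or
#' more sequences over a common alphabet. Sequences are stored as a named
#' character vector (names are the per-record ids, unique within the set).
#'
#' @param set_id Nonempty identifier string.
#' @param sequences Named character vector of residues, all nonempty.
#' @return An object of class `seq_set`.
#' @examples
#' seq_set("demo", c(s1 = "ACGT", s2 = "GGCC"))
#' @export
seq_set <- function(set_id, sequences) {
  if (!is.character(set_id) || length(set_id) != 1L || !nzchar(set_id)) {
    stop("set_id must be a nonempty string")
  }
  if (!is.character(sequences) || length(sequences) == 0L) {
    stop("a sequence-set needs at least one sequence")
  }
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) stop("every sequence needs a nonempty id")
  if (anyDuplicated(ids)) stop("sequence ids must be unique within a set")
  if (any(nchar(sequences) == 0L)) {
    stop("empty sequence in set '", set_id, "': ", ids[nchar(sequences) == 0L][1L])
  }
  structure(list(set_id = set_id, sequences = sequences), class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat("<seq_set> ", x$set_id, ": ", length(x$sequences),
      " sequence(s), lengths ", paste(nchar(x$sequences), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read a sequence-set from a FASTA file
#'
#' One FASTA file is one composite data point; each record is one sequence
#' of the set. Residues are uppercased and symbols outside the alphabet
#' (IUPAC ambiguity codes, `N`, gaps) are removed; the number of removed
#' symbols per record is attached as attribute `"filtered"`.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param alphabet Character vector of retained symbols (default DNA).
#' @return A [seq_set()] whose `set_id` is the file stem, with an integer
#'   attribute `filtered` (named per record) counting removed symbols.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "acgtn", ">s2", "GG-CC"), fa)
#' s <- read_seq_set(fa)
#' attr(s, "filtered")
#' @export
read_seq_set <- function(path, alphabet = dna_alphabet()) {
  check_alphabet(alphabet)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no records in '", path, "'")
  raw <- toupper(as.character(recs))
  ids <- vapply(strsplit(names(recs), "[[:space:]]+"), `[`, character(1L), 1L)
  keep <- paste0("[^", paste(alphabet, collapse = ""), "]")
  res <- gsub(keep, "", raw)
  filtered <- nchar(raw) - nchar(res)
  names(filtered) <- ids
  if (any(nchar(res) == 0L)) {
    stop("record '", ids[nchar(res) == 0L][1L], "' in '", path,
         "' is empty after alphabet filtering")
  }
  names(res) <- ids
  out <- seq_set(sub("\\.[^.]*$", "", basename(path)), res)
  attr(out, "filtered") <- filtered
  out
}

#' Write a sequence-set as FASTA
#'
#' Deterministic plain-text output: records in set order, sequences wrapped
#' at `width` columns, so identical inputs yield byte-identical files.
#'
#' @param x A [seq_set()].
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_seq_set <- function(x, path, width = 70L) {
  stopifnot(inherits(x, "seq_set"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(x$sequences)) {
    s <- x$sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", names(x$sequences)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read a labeled collection of sequence-sets
#'
#' One directory is one class: every FASTA file inside (extensions
#' `.fasta`, `.fa`, `.fna`) becomes one sequence-set, ordered
#' lexicographically by filename. Other files are skipped with a warning.
#'
#' @param dir Directory containing at least one FASTA file.
#' @param alphabet Passed to [read_seq_set()].
#' @return An object of class `seq_collection`: a list with `label` (the
#'   directory name) and `sets` (list of `seq_set`).
#' @export
read_collection <- function(dir, alphabet = dna_alphabet()) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- sort(list.files(dir, full.names = FALSE))
  is_fasta <- grepl("\\.(fasta|fa|fna)$", files, ignore.case = TRUE)
  if (any(!is_fasta)) {
    warning("skipping non-FASTA file(s) in ", dir, ": ",
            paste(files[!is_fasta], collapse = ", "))
  }
  files <- files[is_fasta]
  if (length(files) == 0L) stop("no FASTA files in directory: ", dir)
  sets <- lapply(file.path(dir, files), read_seq_set, alphabet = alphabet)
  seq_collection(basename(normalizePath(dir)), sets)
}

#' Construct a labeled collection
#'
#' @param label Nonempty class label.
#' @param sets List of [seq_set()] objects with unique `set_id`s.
#' @return An object of class `seq_collection`.
#' @export
seq_collection <- function(label, sets) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("label must be a nonempty string")
  }
  if (!is.list(sets) || length(sets) == 0L) stop("a collection needs at least one set")
  if (!all(vapply(sets, inherits, logical(1L), "seq_set"))) {
    stop("all elements must be seq_set objects")
  }
  ids <- vapply(sets, `[[`, character(1L), "set_id")
  if (anyDuplicated(ids)) stop("set_ids must be unique within a collection")
  structure(list(label = label, sets = sets), class = "seq_collection")
}

#' @export
print.seq_collection <- function(x, ...) {
  cat("<seq_collection> '", x$label, "': ", length(x$sets), " set(s)\n", sep = "")
  invisible(x)
}

#' Write and read distance matrices as TSV
#'
#' The matrix is written with a header row and a first column of set ids,
#' values at 15 significant digits, so that `read_distance_matrix()`
#' reproduces it to well below 1e-9. Asymmetric input is rejected.
#'
#' @param D Square symmetric numeric matrix with dimnames (set ids).
#' @param path Output TSV path.
#' @return `path` invisibly; for the reader, the labeled matrix.
#' @export
write_distance_matrix <- function(D, path) {
  check_distance_matrix(D)
  labs <- rownames(D)
  lines <- c(paste(c("set_id", labs), collapse = "\t"),
             vapply(seq_len(nrow(D)), function(i) {
               paste(c(labs[i], sprintf("%.15g", D[i, ])), collapse = "\t")
             }, character(1L)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- as.character(tab[[1L]])
  D <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(D) <- list(labs, colnames(tab)[-1L])
  storage.mode(D) <- "double"
  check_distance_matrix(D)
  D
}

check_distance_matrix <- function(D) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D)) {
    stop("distance matrix must be a square numeric matrix")
  }
  if (is.null(rownames(D)) || is.null(colnames(D))) {
    stop("distance matrix must carry set_id dimnames")
  }
  if (!identical(rownames(D), colnames(D))) stop("row and column labels differ")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12, check.attributes = FALSE))) {
    stop("distance matrix must be symmetric")
  }
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
  if (any(D < 0)) stop("distances must be non-negative")
  invisible(D)
}
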