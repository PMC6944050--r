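# shared fixture builders; everything is generated in code, nothing stored

random_psd <- function(p, rank = p) {
  A <- matrix(rnorm(p * rank), p, rank)
  tcrossprod(A)
}

# brute-force overlapping substring count, independent of count_words()
count_oracle <- function(seq, word) {
  lw <- nchar(word)
  ls <- nchar(seq)
  if (lw > ls) return(0L)
  sum(vapply(seq_len(ls - lw + 1L), function(i) {
    substring(seq, i, i + lw - 1L) == word
  }, logical(1L)))
}

write_fasta_file <- function(records, path, wrap = NULL) {
  lines <- unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  }))
  writeLines(lines, path)
  path
}

make_class_dir <- function(dir, sets) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sets)) {
    write_fasta_file(sets[[nm]], file.path(dir, paste0(nm, ".fasta")))
  }
  dir
}

random_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}
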