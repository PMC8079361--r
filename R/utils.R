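# Small shared helpers: sequence manipulation, Phred conversion, FASTA/FASTQ
# round-trips on plain character vectors.

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (ACGTN, either case).
#' @return Character vector of reverse complements, uppercase.
#' @export
revcomp <- function(x) {
  up <- toupper(x)
  comp <- chartr("ACGTN", "TGCAN", up)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

phred_to_char <- function(q) {
  intToUtf8(pmin(pmax(q, 0), 93) + 33L, multiple = FALSE)
}

char_to_phred <- function(s) {
  utf8ToInt(s) - 33L
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a FASTQ file (Phred+33)
#'
#' @param ids Read ids (full header line after `@`).
#' @param seqs Sequences.
#' @param quals Quality strings (same lengths as `seqs`).
#' @param path Output path.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals),
            all(nchar(seqs) == nchar(quals)))
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(ids)) {
    out <- paste0("@", ids, "\n", seqs, "\n+\n", quals)
    writeLines(out, con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path FASTQ path.
#' @return data.frame with columns id (full header), seq, qual.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  i <- seq(1, length(lines), by = 4)
  data.frame(id = sub("^@", "", lines[i]), seq = lines[i + 1],
             qual = lines[i + 3], stringsAsFactors = FALSE)
}

# deterministic weighted sample of indices summing probabilities to 1
sample_index <- function(n, prob) {
  sample.int(length(prob), n, replace = TRUE, prob = prob)
}
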