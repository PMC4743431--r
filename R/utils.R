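#' @importFrom stats rbinom rgamma runif p.adjust cor aggregate
#' @importFrom utils write.table read.table
NULL

DNA_BASES <- c("A", "C", "G", "T")
TAG_ANCHOR <- "CATG"
TAG_LENGTH <- 21L

# substitution alternatives: row = current base, columns = the 3 other bases
.BASE_ALT <- matrix(c("C", "G", "T",
                      "A", "G", "T",
                      "A", "C", "T",
                      "A", "C", "G"),
                    nrow = 4, byrow = TRUE,
                    dimnames = list(DNA_BASES, NULL))

#' Reverse complement of DNA strings
#'
#' Thin wrapper over [Biostrings::reverseComplement()] returning plain
#' character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# deterministic child seed, kept inside 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483629 + 1)
}

pct_of <- function(a, b) if (b > 0) 100 * a / b else 0

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Write reference transcripts as FASTA
#'
#' @param reference named character vector (names = gene ids) or the
#'   data.frame returned by [generate_reference()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  seqs <- as_reference_vector(reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read reference transcripts from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# accept either a named vector or a data.frame(gene_id, sequence)
as_reference_vector <- function(reference) {
  if (is.data.frame(reference)) {
    out <- reference$sequence
    names(out) <- reference$gene_id
    return(out)
  }
  if (is.null(names(reference)) || anyNA(names(reference))) {
    stop("reference sequences must be named by gene_id")
  }
  reference
}

#' Write raw tag reads
#'
#' Plain text writes one read per line (empty reads allowed). FASTQ writes
#' 4-line records with uniform quality "I"; empty reads get an empty
#' sequence/quality line.
#'
#' @param reads character vector of reads.
#' @param path output path.
#' @param format `"text"` or `"fastq"`.
#' @return the path, invisibly.
#' @export
write_reads <- function(reads, path, format = c("text", "fastq")) {
  format <- match.arg(format)
  if (format == "text") {
    writeLines(reads, path)
  } else {
    ids <- sprintf("@read_%d", seq_along(reads))
    qual <- strrep("I", nchar(reads))
    writeLines(as.vector(rbind(ids, reads, "+", qual)), path)
  }
  invisible(path)
}

#' Read raw tag reads
#'
#' @param path input path; `.fastq`/`.fq` files are parsed as FASTQ via
#'   Biostrings, anything else as one read per line.
#' @return character vector of reads.
#' @export
read_reads <- function(path) {
  if (grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)) {
    as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  } else {
    readLines(path)
  }
}
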