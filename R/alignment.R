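#' DNA alignment container
#'
#' An alignment is stored as a character matrix (one row per taxon, one
#' column per site) over the alphabet A, C, G, T, N, `-`. Constructors
#' validate shape and alphabet; most package functions accept either this
#' class or a plain character matrix / named vector of sequence strings.
#'
#' @param x A character matrix of single characters with unique rownames,
#'   or a named character vector of equal-length sequence strings.
#' @return A `dna_alignment` (character matrix subclass).
#' @examples
#' aln <- dna_alignment(c(t1 = "ACGT", t2 = "ACGA"))
#' @export
dna_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x))) {
      stop_bad("sequences must have unique names")
    }
    if (length(unique(nchar(x))) != 1) {
      stop_bad("all sequences must have the same length")
    }
    nm <- names(x)
    x <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(x) <- nm
  }
  if (!is.matrix(x) || !is.character(x)) {
    stop_bad("alignment must be a character matrix or named character vector")
  }
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop_bad("alignment rows must have unique taxon names")
  }
  x[] <- toupper(x)
  bad <- setdiff(unique(as.vector(x)), c("A", "C", "G", "T", "N", "-", "?"))
  if (length(bad)) stop_bad("invalid characters in alignment: ",
                            paste(bad, collapse = " "))
  class(x) <- c("dna_alignment", class(matrix()))
  x
}

as_aln_matrix <- function(x) {
  if (inherits(x, "dna_alignment")) return(unclass(x))
  # plain character matrices with unique rownames pass through unvalidated
  # (hot path for simulated windows); anything else is validated/coerced
  if (is.matrix(x) && is.character(x) && !is.null(rownames(x)) &&
      !anyDuplicated(rownames(x))) {
    return(x)
  }
  unclass(dna_alignment(x))
}

#' Read / write FASTA alignments
#'
#' Thin wrappers over ape's FASTA machinery returning/accepting the
#' package's `dna_alignment` matrix.
#'
#' @param path File path.
#' @param aln A `dna_alignment` or coercible object.
#' @return `read_fasta()` a `dna_alignment`; `write_fasta()` the path,
#'   invisibly.
#' @export
read_fasta <- function(path) {
  d <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(d)))
  dna_alignment(m)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(aln, path) {
  m <- as_aln_matrix(aln)
  ape::write.FASTA(ape::as.DNAbin(m), path)
  invisible(path)
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("<dna_alignment> ", nrow(x), " taxa x ", ncol(x), " sites\n", sep = "")
  show <- pmin(ncol(x), 60)
  for (i in seq_len(min(nrow(x), 10))) {
    cat(format(rownames(x)[i], width = 12), " ",
        paste(x[i, seq_len(show)], collapse = ""),
        if (ncol(x) > show) "..." else "", "\n", sep = "")
  }
  invisible(x)
}
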