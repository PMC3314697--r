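#' Aligned haplotype set
#'
#' A `haplotype_set` holds one aligned DNA sequence per distinct haplotype,
#' all of identical length, over the alphabet A/C/G/T, IUPAC ambiguity codes
#' (treated like N in all comparisons) and the alignment gap `-`.
#'
#' @param sequences named character vector of aligned, equal-length DNA
#'   sequences (one per haplotype; names are haplotype IDs).
#' @return An object of class `haplotype_set`: a list with elements
#'   `sequences` (named uppercase character vector) and `length`
#'   (alignment length in sites).
#' @examples
#' hs <- haplotype_set(c(A = "ACGT", B = "ACGA"))
#' hs$length
#' @export
haplotype_set <- function(sequences) {
  if (length(sequences) < 1L)
    stop("haplotype_set needs at least one sequence", call. = FALSE)
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
    stop("all haplotypes must have non-empty IDs", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate haplotype IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- toupper(as.character(sequences))
  names(seqs) <- ids
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != stats::median(lens)]
    stop("alignment error: sequences differ in length (offending IDs: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  ok <- grepl("^[ACGTRYSWKMBDHVN-]*$", seqs)
  if (!all(ok))
    stop("format error: non-IUPAC characters in sequences of: ",
         paste(ids[!ok], collapse = ", "), call. = FALSE)
  structure(list(sequences = seqs, length = unname(lens[1L])),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set:", length(x$sequences), "haplotypes,",
      x$length, "aligned sites\n")
  cat("IDs:", paste(utils::head(names(x$sequences), 10L), collapse = " "),
      if (length(x$sequences) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
length.haplotype_set <- function(x) length(x$sequences)

#' Read an aligned haplotype FASTA file
#'
#' Reads one record per distinct haplotype. The haplotype ID is the first
#' whitespace-delimited token of the header; sequences are uppercased and
#' must be equal-length IUPAC DNA (gaps allowed).
#'
#' @param path path to a FASTA file.
#' @return A [haplotype_set()].
#' @export
read_haplotype_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(dna), "[ \t]+"), `[[`, character(1L), 1L)
  seqs <- vapply(as.character(dna), function(s) paste(s, collapse = ""),
                 character(1L))
  names(seqs) <- ids
  haplotype_set(seqs)
}

#' Write a haplotype set as FASTA
#'
#' @param haps a [haplotype_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(haps, path) {
  stopifnot(inherits(haps, "haplotype_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(haps$sequences))
    writeLines(c(paste0(">", id), haps$sequences[[id]]), con)
  invisible(path)
}
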