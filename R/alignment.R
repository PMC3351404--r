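# Aligned-sequence container and shared pairwise-difference machinery.

.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N", "-", "?")
.BASES <- c("A", "C", "G", "T")

.normalize_seq <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  gsub("?", "N", x, fixed = TRUE)
}

#' Construct an aligned set of DNA sequences
#'
#' An alignment holds equal-length, normalized (uppercase, U mapped to T)
#' DNA sequences with unique identifiers. Ambiguity codes (IUPAC) and
#' alignment gaps (\code{-}) are retained and treated as ambiguous by all
#' downstream distance machinery.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of aligned sequences, same length as
#'   \code{ids}.
#' @return An object of class \code{"refugeo_alignment"}: a list with
#'   elements \code{ids}, \code{seqs}, \code{n} (number of records) and
#'   \code{L} (alignment length in sites).
#' @examples
#' alignment(c("a", "b"), c("ACGT", "ACGA"))
#' @export
alignment <- function(ids, seqs) {
  if (length(ids) != length(seqs))
    stop("ids and seqs must have equal length", call. = FALSE)
  if (length(seqs) == 0L)
    stop("empty input: alignment needs at least one record", call. = FALSE)
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- .normalize_seq(as.character(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment length error: sequences have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")", call. = FALSE)
  L <- lens[[1L]]
  if (L == 0L)
    stop("alignment length error: zero-length sequences", call. = FALSE)
  bad <- setdiff(unique(unlist(strsplit(seqs, "", fixed = TRUE))), .IUPAC)
  if (length(bad))
    stop("symbol error: non-IUPAC symbol(s) in alignment: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(ids = ids, seqs = seqs, n = length(ids), L = L),
            class = "refugeo_alignment")
}

#' @export
print.refugeo_alignment <- function(x, ...) {
  cat("Alignment:", x$n, "sequences x", x$L, "sites\n")
  invisible(x)
}

# n x L character matrix view of an alignment
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = aln$n, byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

# columns where every sequence carries an unambiguous base (complete deletion)
complete_sites <- function(aln) {
  m <- aln_matrix(aln)
  which(colSums(matrix(m %in% .BASES, nrow = aln$n)) == aln$n)
}

#' Read an aligned FASTA file
#'
#' @param path path to a multi-record FASTA file (wrapped or unwrapped).
#' @return A \code{\link{alignment}} object, record order preserved.
#'   Sequences are uppercased and U is mapped to T.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e)
      stop("empty-input error: no FASTA records in ", path, call. = FALSE))
  if (length(recs) == 0L)
    stop("empty-input error: no FASTA records in ", path, call. = FALSE)
  alignment(names(recs), vapply(recs, function(r) as.character(r)[[1L]], ""))
}

#' Write an alignment to FASTA
#'
#' @param aln an \code{\link{alignment}}.
#' @param path output file path.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqinr::write.fasta(as.list(aln$seqs), names = aln$ids, file.out = path,
                      nbchar = 70)
  invisible(path)
}

#' Pairwise differences under pairwise deletion
#'
#' For every pair of sequences, counts the sites at which both carry an
#' unambiguous base (\code{valid}) and, among those, the sites at which they
#' differ (\code{diff}). Sites with a gap or ambiguity code in either member
#' of a pair are excluded for that pair only (pairwise deletion). A pair
#' with no comparable site is flagged incomparable: its \code{diff} entry is
#' \code{NA}.
#'
#' @param aln an \code{\link{alignment}}.
#' @return A list of class \code{"pairwise_diff"} with symmetric integer
#'   matrices \code{diff} and \code{valid} (diagonal of \code{diff} is zero).
#' @examples
#' pairwise_differences(alignment(c("a", "b"), c("AC-T", "ACGA")))
#' @export
pairwise_differences <- function(aln) {
  m <- aln_matrix(aln)
  ok <- matrix(m %in% .BASES, nrow = aln$n)
  n <- aln$n
  dm <- matrix(0L, n, n, dimnames = list(aln$ids, aln$ids))
  vm <- matrix(0L, n, n, dimnames = list(aln$ids, aln$ids))
  diag(vm) <- as.integer(rowSums(ok))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        v <- ok[i, ] & ok[j, ]
        nv <- sum(v)
        vm[i, j] <- vm[j, i] <- nv
        if (nv == 0L) {
          dm[i, j] <- dm[j, i] <- NA_integer_
        } else {
          nd <- sum(m[i, v] != m[j, v])
          dm[i, j] <- dm[j, i] <- as.integer(nd)
        }
      }
    }
  }
  structure(list(diff = dm, valid = vm), class = "pairwise_diff")
}

# pairwise difference counts on complete-deletion sites only; returns the
# integer matrix of counts (used by the neutrality statistics, whose
# simulation nulls are gap-free)
complete_deletion_diffs <- function(aln) {
  cs <- complete_sites(aln)
  m <- aln_matrix(aln)[, cs, drop = FALSE]
  n <- aln$n
  dm <- matrix(0L, n, n, dimnames = list(aln$ids, aln$ids))
  if (n > 1L && length(cs)) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dm[i, j] <- dm[j, i] <- sum(m[i, ] != m[j, ])
      }
    }
  }
  dm
}

.GENETIC_CODES <- c(standard = 1, vertebrate_mito = 2, yeast_mito = 3,
                    mold_mito = 4, invertebrate_mito = 5)

#' Translate a nucleotide sequence codon by codon
#'
#' Defaults to the invertebrate mitochondrial code, the code of the COI
#' fragments this package targets (e.g. AGA encodes serine, not arginine).
#' Codons containing a gap or ambiguous base translate to \code{"X"}; a
#' trailing incomplete codon is dropped.
#'
#' @param seq a single nucleotide sequence (character scalar).
#' @param code genetic code: a name among
#'   \code{names(refugeo:::.GENETIC_CODES)} or an NCBI code number.
#' @param frame reading frame offset, 0, 1 or 2.
#' @return Character scalar of amino acids, one per complete codon.
#' @examples
#' translate_codons("ATGTTT")  # "MF"
#' translate_codons("AGA")     # "S" under the invertebrate mito code
#' @export
translate_codons <- function(seq, code = "invertebrate_mito", frame = 0) {
  stopifnot(length(seq) == 1L, frame %in% 0:2)
  numcode <- if (is.numeric(code)) code else {
    if (!code %in% names(.GENETIC_CODES))
      stop("unknown genetic code: ", code, call. = FALSE)
    .GENETIC_CODES[[code]]
  }
  s <- .normalize_seq(seq)
  if (nchar(s) - frame < 3L)
    stop("sequence shorter than one codon in frame ", frame, call. = FALSE)
  aa <- seqinr::translate(seqinr::s2c(s), frame = frame, numcode = numcode,
                          NAstring = "X", ambiguous = FALSE)
  paste(aa, collapse = "")
}
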