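#' Encode a k-mer window as a 2-bit packed integer
#'
#' Nucleotides are encoded A=00, C=01, G=10, T=11 with the first base in the
#' most significant position, so `"TCA"` encodes to binary `110100` = 52.
#' Windows containing a non-ACGT base cannot be encoded and raise an error;
#' callers scanning a sequence should skip such windows.
#'
#' @param seq Nucleotide string.
#' @param start 0-based start of the window within `seq`.
#' @param k Window length; at most 26 so the result is exactly representable
#'   as an R double.
#' @return The encoded integer as a double.
#' @examples
#' encode_kmer("TCA")  # 52
#' @export
encode_kmer <- function(seq, start = 0, k = nchar(seq) - start) {
  stopifnot(is.character(seq), length(seq) == 1L)
  cpp_encode_kmer(seq, as.integer(start), as.integer(k))
}

#' Decode a 2-bit packed integer back to a nucleotide string
#'
#' @param code Integer produced by [encode_kmer()].
#' @param k k-mer length.
#' @return Uppercase nucleotide string.
#' @export
decode_kmer <- function(code, k) {
  cpp_decode_kmer(as.numeric(code), as.integer(k))
}

#' Reverse complement of nucleotide sequences
#'
#' Vectorised; understands the full IUPAC alphabet (N maps to N) and errors
#' on any other character.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

#' Canonical representative of a k-mer and its reverse complement
#'
#' Returns the numerically (equivalently, lexicographically) smaller of the
#' two encodings together with the strand that supplied it. Palindromes
#' report the forward strand.
#'
#' @param x_fwd,x_rc Integer encodings (see [encode_kmer()]) of a k-mer and
#'   of its reverse complement.
#' @return List with elements `code` and `strand` ("forward"/"reverse").
#' @export
canonical_kmer <- function(x_fwd, x_rc) {
  stopifnot(is.numeric(x_fwd), is.numeric(x_rc))
  if (x_rc < x_fwd) list(code = x_rc, strand = "reverse")
  else list(code = x_fwd, strand = "forward")
}

#' 64-bit mixing hash
#'
#' A fixed xorshift-multiply finalizer (splitmix64 constants), bijective over
#' the 64-bit space and identical across platforms and runs. Values are
#' passed and returned as 16-digit lowercase hex strings so that the full
#' 64 bits survive the R boundary; plain numerics below 2^53 are accepted
#' too.
#'
#' @param x Numeric scalar (< 2^53) or hex string.
#' @return 16-character hex string.
#' @seealso [unhash64()] for the inverse permutation.
#' @export
hash64 <- function(x) {
  cpp_hash64_hex(as_hash_hex(x))
}

#' Inverse of the 64-bit mixing hash
#'
#' Applies the exact inverse of each xorshift/multiply step of [hash64()],
#' so `unhash64(hash64(x)) == x` for every 64-bit value.
#'
#' @inheritParams hash64
#' @return 16-character hex string.
#' @export
unhash64 <- function(x) {
  cpp_unhash64_hex(as_hash_hex(x))
}

# numeric (< 2^53) or hex string -> canonical 16-digit hex
as_hash_hex <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L, grepl("^[0-9a-fA-F]{1,16}$", x))
    return(tolower(formatC(x, width = 16, flag = "0")))
  }
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x < 2^53, x == floor(x))
  q <- numeric(4)                       # four 16-bit limbs, MSB first
  for (i in 4:1) { q[i] <- x %% 65536; x <- x %/% 65536 }
  sprintf("%04x%04x%04x%04x", as.integer(q[1]), as.integer(q[2]),
          as.integer(q[3]), as.integer(q[4]))
}

# hex -> numeric; exact only below 2^53, used where that is guaranteed
hash_hex_to_num <- function(h) {
  vapply(strsplit(tolower(h), ""), function(d) {
    Reduce(function(a, b) a * 16 + b, match(d, c(0:9, letters[1:6])) - 1, 0)
  }, numeric(1))
}

#' Sample window minimizers of a sequence
#'
#' Classic (w, k) minimizers under a random ordering given by [hash64()]
#' over canonical k-mers: within every window of `w` consecutive k-mers the
#' position with the smallest hash is selected (leftmost on ties), and
#' consecutive windows selecting the same position are collapsed to one
#' entry. Windows overlapping non-ACGT bases are skipped.
#'
#' @param seq Nucleotide string.
#' @param k k-mer length.
#' @param w Window size in k-mers; the expected density on random sequence
#'   is 2/(w+1).
#' @return Data frame with columns `pos` (0-based k-mer start) and `hash`
#'   (canonical hash, hex).
#' @export
sample_minimizers <- function(seq, k = 20, w = 9) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1, w >= 1)
  cpp_minimizers(seq, as.integer(k), as.integer(w))
}

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] (multi-record, wrapped
#' lines, case-insensitive). Record descriptions are truncated at the first
#' whitespace, as aligners conventionally do.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
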