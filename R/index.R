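#' Build the randstrobe reference index
#'
#' Seeds every reference with [reference_seeds()], stores records in a flat
#' vector sorted by (hash, reference id, start) and builds a directory from
#' hash to (offset, occurrence count). Seeds whose second-strobe offset
#' exceeds 255 cannot be packed and are truncated to the single-syncmer
#' fallback (counted in `n_offset_truncated`). The abundance cutoff `A` is
#' the occurrence count of the distinct hash ranked at position
#' `ceiling(f * n_distinct)` in descending count order, floored at 2;
#' lookups of hashes occurring more than `A` times report `masked`.
#'
#' @param references Named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA file path.
#' @param profile A [seed_profile()]; defaults to
#'   `choose_profile(read_length)`.
#' @param f Masking fraction of distinct hashes (default 0.0002).
#' @param read_length Read length used to pick the default profile.
#' @return Object of class `strobe_index`.
#' @export
build_index <- function(references, profile = NULL, f = 0.0002,
                        read_length = 150) {
  if (is.character(references) && length(references) == 1L &&
      !grepl("^[ACGTNacgtn]+$", references) && file.exists(references))
    references <- read_fasta(references)
  if (inherits(references, "DNAStringSet"))
    references <- as.character(references)
  stopifnot(is.character(references), length(references) >= 1L)
  if (any(nchar(references) == 0L)) stop("empty reference sequence")
  if (is.null(names(references)))
    names(references) <- paste0("ref", seq_along(references))
  if (is.null(profile)) profile <- choose_profile(read_length)
  stopifnot(inherits(profile, "seed_profile"), f >= 0, f <= 1)
  built <- cpp_build_index(unname(toupper(references)), names(references),
                           profile$k, profile$s, profile$t, profile$w_min,
                           profile$w_max, profile$p, profile$max_seed_len, f)
  structure(list(ptr = built$ptr,
                 refs = toupper(references),
                 ref_names = names(references),
                 ref_lens = nchar(references),
                 profile = profile, f = f, A = built$A,
                 n_records = built$n_records,
                 n_distinct = built$n_distinct,
                 n_offset_truncated = built$n_offset_truncated),
            class = "strobe_index")
}

#' @export
print.strobe_index <- function(x, ...) {
  cat(sprintf("strobe_index: %d reference(s), %s bp total\n",
              length(x$ref_names),
              format(sum(x$ref_lens), big.mark = ",")))
  cat(sprintf("  seeds: %s records, %s distinct, abundance cutoff A=%d (f=%g)\n",
              format(x$n_records, big.mark = ","),
              format(x$n_distinct, big.mark = ","), x$A, x$f))
  print(x$profile)
  invisible(x)
}

#' Query the index for one seed hash
#'
#' @param index A [build_index()] result.
#' @param hash Seed hash (hex or numeric).
#' @return List with `status` ("ok", "masked" or "absent"), `count`, and for
#'   `status == "ok"` a data frame `records` with columns `r_id` (0-based
#'   reference index), `r_s`, `r_e`, `offset`.
#' @export
index_lookup <- function(index, hash) {
  stopifnot(inherits(index, "strobe_index"))
  cpp_lookup(index$ptr, as_hash_hex(hash))
}

# occurrence counts of all distinct hashes (order unspecified)
index_counts <- function(index) {
  stopifnot(inherits(index, "strobe_index"))
  cpp_index_counts(index$ptr)
}

#' Save an index to a versioned binary file
#'
#' The file stores seeding parameters, the abundance cutoff, reference names
#' and lengths, and the sorted record vector; writing is deterministic
#' byte-for-byte for identical inputs. Reference sequences themselves are
#' not stored: alignment after [load_index()] needs the FASTA again.
#'
#' @param index A `strobe_index`.
#' @param path Output path.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "strobe_index"))
  cpp_save_index(index$ptr, path)
  invisible(path)
}

#' Load an index written by [save_index()]
#'
#' @param path Index file path.
#' @param references Optional reference sequences (named character vector,
#'   `DNAStringSet` or FASTA path) to re-attach for alignment; names and
#'   lengths are checked against the stored metadata.
#' @return A `strobe_index`.
#' @export
load_index <- function(path, references = NULL) {
  loaded <- cpp_load_index(path)
  par <- cpp_index_params(loaded$ptr)
  profile <- seed_profile(k = par$k, s_delta = par$k - par$s, p = par$p,
                          l = par$wmin - par$k %/% (par$k - par$s + 1),
                          u = par$wmax - par$k %/% (par$k - par$s + 1),
                          max_seed_len = par$max_seed_len)
  refs <- NULL
  if (!is.null(references)) {
    if (is.character(references) && length(references) == 1L &&
        file.exists(references))
      references <- read_fasta(references)
    if (inherits(references, "DNAStringSet"))
      references <- as.character(references)
    refs <- toupper(references)
    if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
    if (!identical(unname(names(refs)), unname(par$ref_names)) ||
        !identical(unname(nchar(refs)), unname(as.integer(par$ref_lens))))
      stop("supplied references do not match the saved index metadata")
  }
  structure(list(ptr = loaded$ptr, refs = refs,
                 ref_names = par$ref_names,
                 ref_lens = as.numeric(par$ref_lens),
                 profile = profile, f = par$f, A = par$A,
                 n_records = par$n_records,
                 n_distinct = par$n_distinct,
                 n_offset_truncated = par$n_offset_truncated),
            class = "strobe_index")
}
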