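# Small shared helpers: alphabet handling, seed substreams, argument checks.

#' Reverse-complement a nucleotide string
#'
#' Works on plain character vectors in either DNA or RNA alphabet
#' (case-insensitive; IUPAC ambiguity codes supported via Biostrings).
#'
#' @param x character vector of nucleotide strings.
#' @param rna logical; if `TRUE` the result uses the RNA alphabet.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x, rna = FALSE) {
  if (length(x) == 0L) return(character(0))
  dna <- chartr("Uu", "Tt", x)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(dna)))
  if (rna) out <- chartr("Tt", "Uu", out)
  unname(out)
}

#' Convert between DNA and RNA alphabets
#'
#' @param x character vector.
#' @return character vector with T<->U swapped.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# Derive a reproducible child seed from a parent seed and a stream label.
# Keeps results independent per named generator while remaining a pure
# function of (seed, stream); always < 2^31.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 2654435761 + h * 97 + 12345) %% .Machine$integer.max)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG afterwards so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
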