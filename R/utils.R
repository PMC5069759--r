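# Internal helpers shared across modules.

#' @importFrom stats setNames
NULL

.sp_env <- new.env(parent = emptyenv())

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed; stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483629)
}

BASES <- c("A", "C", "G", "T")

genetic_code <- function() {
  if (is.null(.sp_env$gcode)) {
    .sp_env$gcode <- Biostrings::GENETIC_CODE
  }
  .sp_env$gcode
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

stop_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc == "*"]
}

is_stop <- function(codon) {
  unname(genetic_code()[codon] == "*")
}

# Translate an in-frame CDS (character scalar) to an amino-acid string.
# A trailing stop is dropped; internal stops are an error unless allow_stop.
translate_cds <- function(cds, allow_stop = FALSE) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  codons <- codon_split(cds)
  aa <- genetic_code()[codons]
  if (anyNA(aa)) stop("CDS contains non-ACGT codons")
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (!allow_stop && any(aa == "*")) stop("internal stop codon in CDS")
  paste(aa, collapse = "")
}

codon_split <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
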