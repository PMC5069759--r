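#' Read a FASTA file into a named character vector
#'
#' Sequences are normalised to upper case on ingest; `U` (RNA) is rejected,
#' the pipeline is DNA/protein only. Duplicate record ids are an error.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param type `"DNA"` or `"AA"`; controls alphabet validation.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  if (type == "DNA" && any(grepl("U", seqs, fixed = TRUE))) {
    stop("RNA (U) not supported; DNA input expected")
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) {
    stop("duplicate FASTA id: ", names(seqs)[duplicated(names(seqs))][1])
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Write a TSV with a leading comment line recording the producing stage and
# parameters, then a header row. Read back with read_stage_tsv().
write_stage_tsv <- function(df, path, stage, params = list()) {
  ptxt <- if (length(params)) {
    paste(vapply(names(params), function(k) paste0(k, "=", params[[k]]),
                 character(1)), collapse = " ")
  } else ""
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s %s", stage, ptxt), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Site metadata for the seven Chicago-area waterway sampling stations
#'
#' Returns the packaged site table (station id, region, latitude, longitude,
#' temperature and water-chemistry covariates) used as the default geography
#' for distance-decay demonstrations.
#'
#' @return A data.frame with one row per site.
#' @export
caws_sites <- function() {
  path <- system.file("extdata", "caws_sites.tsv", package = "strainpop",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
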