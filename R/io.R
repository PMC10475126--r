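#' Write reads to a FASTQ file
#'
#' @param path Output file.
#' @param ids Read identifiers.
#' @param seqs Read sequences.
#' @param quals Quality strings (Phred+33), same lengths as `seqs`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(path, ids, seqs, quals) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals),
            all(nchar(seqs) == nchar(quals)))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Read a FASTQ file into sequences and integer qualities
#'
#' @param path FASTQ file.
#' @return List: `ids`, `seqs` (character), `quals` (list of integer
#'   Phred vectors).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  quals <- as(Biostrings::PhredQuality(q), "IntegerList")
  list(ids = names(x),
       seqs = as.character(x),
       quals = as.list(quals))
}

#' Write a data frame as TSV
#'
#' @param df Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline run records its configuration, package version and
#' input digests so artifacts are reproducible from the manifest alone.
#'
#' @param path Output JSON file.
#' @param config Named list of run parameters (seed included).
#' @param inputs Character vector of input file paths (digested).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(0)) {
  digest_file <- function(f) {
    if (!file.exists(f)) return(NA_character_)
    # small content digest without extra dependencies
    sz <- file.info(f)$size
    con <- file(f, "rb")
    on.exit(close(con))
    head_bytes <- readBin(con, "raw", n = min(sz, 65536))
    sprintf("size:%d;sum:%d", sz, sum(as.integer(head_bytes)))
  }
  payload <- list(
    package = "beoff",
    version = as.character(utils::packageVersion("beoff")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    inputs = lapply(stats::setNames(as.list(inputs), inputs), digest_file)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
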