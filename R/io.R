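# Readers and writers for the standard formats the pipeline touches:
# 4-line FASTQ, FASTA, the tabular study-design file, TSV matrices and BED6.

#' Read a 4-line FASTQ file
#'
#' Reads an entire (optionally gzipped) FASTQ file into memory. Sequences are
#' uppercased; record order is preserved. A record whose sequence and quality
#' strings differ in length is a parse error naming the offending line.
#'
#' @param path path to a FASTQ file (plain or gzip).
#' @return data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  }
  idx <- seq(1, length(lines), by = 4)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[idx]))
  seqs <- toupper(lines[idx + 1])
  quals <- lines[idx + 3]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0) {
    stop("malformed FASTQ record at line ", idx[bad[1]],
         ": sequence and quality lengths differ")
  }
  plus <- substr(lines[idx + 2], 1, 1)
  if (any(plus != "+")) {
    stop("malformed FASTQ record at line ", idx[which(plus != "+")[1]] + 2,
         ": expected '+' separator")
  }
  data.frame(read_id = ids, sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' Write a 4-line FASTQ file
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param path output path; a ".gz" suffix triggers gzip compression.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    out <- rbind(paste0("@", reads$read_id), reads$sequence, "+", reads$quality)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Multi-line sequences are concatenated and uppercased; record order is
#' preserved. Duplicate identifiers are an error.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  stats::setNames(toupper(as.character(ss)), ids)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a matrix as TSV with a leading feature-id column
#'
#' @param m matrix with rownames.
#' @param path output path.
#' @param id_col name of the leading id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export hairpin candidates as BED6
#'
#' Coordinates are 0-based half-open per BED convention; the name field holds
#' the canonical hairpin identifier and the score the category rank (A = 8
#' down to H = 1).
#'
#' @param candidates data.frame with `contig`, `start`, `end` (1-based
#'   inclusive), `identifier`, `category`, `strand`.
#' @param path output path.
#' @export
write_bed6 <- function(candidates, path) {
  rank <- 9L - match(candidates$category, LETTERS[1:8])
  bed <- data.frame(candidates$contig,
                    candidates$start - 1L,
                    candidates$end,
                    candidates$identifier,
                    rank,
                    candidates$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
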