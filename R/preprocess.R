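# Pre-processing for small RNA reads: adapter trimming, length partitioning,
# unique-read collapsing and the filter cascade (low abundance, contaminant
# mapping, breakdown-product assembly filter).
#
# The unique-read table is a data.frame with a `sequence` column, one count
# column per library and a `total_count` column; filters return the same
# shape with a `removed` attribute holding the rows they dropped.

#' Trim the 3' adapter from reads
#'
#' A read is trimmed at the earliest position where its suffix matches a
#' prefix of the adapter over at least `min_overlap` exact bases; reads with
#' no such match are returned unchanged and flagged untrimmed (they form the
#' second partition used for breakdown-product assembly).
#'
#' @param reads character vector of read sequences.
#' @param adapter3 3' adapter sequence (length >= `min_overlap`).
#' @param min_overlap minimum exact overlap (nt) required to call an adapter.
#' @return data.frame with `sequence` (trimmed) and `trimmed` (logical).
#' @export
trim_adapter <- function(reads, adapter3, min_overlap = 8) {
  la <- nchar(adapter3)
  stopifnot(la >= min_overlap)
  n <- nchar(reads)
  pos <- rep(NA_integer_, length(reads))
  for (i in seq_len(max(n, 0))) {
    idx <- which(is.na(pos) & n - i + 1 >= min_overlap)
    if (length(idx) == 0) break
    ov <- pmin(n[idx] - i + 1L, la)
    hit <- substr(reads[idx], i, i + ov - 1L) == substr(adapter3, 1, ov)
    pos[idx[hit]] <- i
  }
  trimmed <- !is.na(pos)
  out <- reads
  out[trimmed] <- substr(reads[trimmed], 1, pos[trimmed] - 1L)
  data.frame(sequence = out, trimmed = trimmed, stringsAsFactors = FALSE)
}

#' Partition trimmed reads into the two working sets
#'
#' Set 1 holds adapter-trimmed reads of 19-26 nt (hairpin discovery input);
#' set 2 holds reads in which no adapter was found (assembly input). Trimmed
#' reads of 15-50 nt form the wider window used for conserved-miRNA
#' profiling. Reads containing N are dropped as low quality; reads still
#' carrying a 5' adapter prefix after trimming are dropped when `adapter5`
#' is given.
#'
#' @param trimmed data.frame from [trim_adapter()].
#' @param adapter5 optional 5' adapter sequence; trimmed reads whose first
#'   `min_overlap` bases equal its 3' end are discarded.
#' @param min_overlap overlap used for the 5' adapter check.
#' @return list of character vectors: `hairpin_set` (19-26 nt trimmed),
#'   `untrimmed_set`, `approach1_set` (15-50 nt trimmed), `dropped`.
#' @export
partition_reads <- function(trimmed, adapter5 = NULL, min_overlap = 8) {
  seqs <- trimmed$sequence
  keep <- !grepl("N", seqs, fixed = TRUE)
  dropped <- seqs[!keep]
  seqs <- seqs[keep]
  tflag <- trimmed$trimmed[keep]
  if (!is.null(adapter5)) {
    la5 <- nchar(adapter5)
    tail5 <- substr(adapter5, la5 - min_overlap + 1L, la5)
    carry <- tflag & nchar(seqs) >= min_overlap &
      substr(seqs, 1, min_overlap) == tail5
    dropped <- c(dropped, seqs[carry])
    tflag <- tflag[!carry]
    seqs <- seqs[!carry]
  }
  len <- nchar(seqs)
  list(hairpin_set = seqs[tflag & len >= 19 & len <= 26],
       untrimmed_set = seqs[!tflag],
       approach1_set = seqs[tflag & len >= 15 & len <= 50],
       dropped = dropped)
}

#' Collapse per-library reads into a unique-read count table
#'
#' @param lib_reads named list (by library_id) of character vectors of read
#'   sequences.
#' @param design study design; every list name must be a design library.
#' @return unique-read table: data.frame with `sequence`, one integer count
#'   column per design library, and `total_count`.
#' @export
collapse_unique <- function(lib_reads, design) {
  unknown <- setdiff(names(lib_reads), design$library_id)
  if (length(unknown) > 0) {
    stop("unknown library_id in read streams: ",
         paste(unknown, collapse = ", "))
  }
  all_seq <- unique(unlist(lib_reads, use.names = FALSE))
  counts <- matrix(0L, nrow = length(all_seq), ncol = nrow(design),
                   dimnames = list(NULL, design$library_id))
  for (lib in names(lib_reads)) {
    t <- table(match(lib_reads[[lib]], all_seq))
    counts[as.integer(names(t)), lib] <- as.integer(t)
  }
  tbl <- data.frame(sequence = all_seq, counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tbl$total_count <- as.integer(rowSums(counts))
  tbl
}

# Library count columns of a unique-read table, as a matrix.
urt_counts <- function(tbl) {
  as.matrix(tbl[, setdiff(colnames(tbl), c("sequence", "total_count")),
                drop = FALSE])
}

#' Remove low-abundance unique reads
#'
#' Drops rows whose summed count across all libraries is at most `max_total`
#' (the "<= 5 reads in all samples" rule).
#'
#' @param tbl unique-read table.
#' @param max_total inclusive removal threshold on the row total.
#' @return filtered table; removed rows in `attr(, "removed")`.
#' @export
filter_low_abundance <- function(tbl, max_total = 5) {
  drop <- tbl$total_count <= max_total
  out <- tbl[!drop, , drop = FALSE]
  attr(out, "removed") <- tbl[drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exhaustive ungapped mismatch-bounded mapping
#'
#' Finds every reference offset (on either strand) at which the full query
#' aligns with Hamming distance at most `max_mismatch`; no indels. Queries
#' longer than a reference simply have no hit there.
#'
#' @param queries character vector of query sequences.
#' @param refs named character vector of reference sequences.
#' @param max_mismatch maximum Hamming distance.
#' @param min_mismatch minimum Hamming distance (used by the imperfect
#'   alignment mode of hairpin discovery).
#' @param both_strands also scan the reverse complement of each query.
#' @return data.frame of hits: `query`, `ref`, `start`, `end` (0-based
#'   half-open on the reference forward strand), `strand`, `mismatches`.
#' @export
map_ungapped <- function(queries, refs, max_mismatch = 2, min_mismatch = 0,
                         both_strands = TRUE) {
  stopifnot(max_mismatch >= 0)
  subj <- lapply(refs, Biostrings::DNAString)
  rows <- vector("list", 256)
  nrows <- 0
  add_row <- function(df) {
    nrows <<- nrows + 1
    if (nrows > length(rows)) length(rows) <<- 2 * nrows
    rows[[nrows]] <<- df
  }
  uq <- unique(queries)
  for (q in uq) {
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      pat <- Biostrings::DNAString(if (st == "+") q else revcomp(q))
      for (ri in seq_along(subj)) {
        s <- subj[[ri]]
        if (length(pat) > length(s)) next
        m <- Biostrings::matchPattern(pat, s, max.mismatch = max_mismatch,
                                      with.indels = FALSE, fixed = TRUE)
        if (length(m) == 0) next
        ok <- BiocGenerics::start(m) >= 1 & BiocGenerics::end(m) <= length(s)
        if (!any(ok)) next
        m <- m[ok]
        mm <- lengths(Biostrings::mismatch(pat, m))
        keep <- mm >= min_mismatch
        if (!any(keep)) next
        add_row(data.frame(query = q, ref = names(refs)[ri],
                           start = BiocGenerics::start(m)[keep] - 1L,
                           end = BiocGenerics::end(m)[keep],
                           strand = st, mismatches = mm[keep],
                           stringsAsFactors = FALSE))
      }
    }
  }
  if (nrows == 0) {
    return(data.frame(query = character(0), ref = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows[seq_len(nrows)])
  rownames(out) <- NULL
  out
}

#' Remove unique reads matching contaminant references
#'
#' A row is removed when its sequence has any ungapped alignment with at most
#' `max_mismatch` mismatches (no indels, either strand) to any contaminant
#' reference. Contaminant classes are taken from the reference name prefix
#' (text before the last underscore); per-class removal tallies are attached
#' as `attr(, "removal_log")`.
#'
#' @param tbl unique-read table.
#' @param contaminants named character vector of contaminant references.
#' @param max_mismatch maximum Hamming distance for a contaminant hit.
#' @return filtered table with `removed` and `removal_log` attributes.
#' @export
filter_contaminants <- function(tbl, contaminants, max_mismatch = 2) {
  stopifnot(length(contaminants) > 0)
  if (nrow(tbl) == 0) {
    attr(tbl, "removal_log") <- table(character(0))
    return(tbl)
  }
  hits <- map_ungapped(tbl$sequence, contaminants,
                       max_mismatch = max_mismatch)
  drop <- tbl$sequence %in% hits$query
  cls <- sub("_[^_]*$", "", hits$ref)
  first_cls <- vapply(split(cls, hits$query), `[`, character(1), 1)
  out <- tbl[!drop, , drop = FALSE]
  attr(out, "removed") <- tbl[drop, , drop = FALSE]
  attr(out, "removal_log") <- table(first_cls[tbl$sequence[drop]])
  rownames(out) <- NULL
  out
}

#' Assemble contigs from reads with a minimal de Bruijn graph
#'
#' Builds the k-mer de Bruijn graph of the input sequences and emits maximal
#' unbranched paths as contigs (no bubble popping, no read tracking); this is
#' only a breakdown-product filter reference, not a general assembler.
#'
#' @param seqs character vector of sequences (those shorter than `k` are
#'   ignored).
#' @param k odd k-mer length.
#' @return character vector of contigs.
#' @export
assemble_contigs <- function(seqs, k = 17) {
  stopifnot(k %% 2 == 1)
  seqs <- unique(seqs[nchar(seqs) >= k])
  if (length(seqs) == 0) return(character(0))
  kmers <- unique(unlist(lapply(seqs, function(s) {
    substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  })))
  pref <- substr(kmers, 1, k - 1)
  suf <- substr(kmers, 2, k)
  nodes <- unique(c(pref, suf))
  out_edges <- split(kmers, factor(pref, levels = nodes))
  outdeg <- lengths(out_edges)
  indeg <- table(factor(suf, levels = nodes))
  simple <- function(node) indeg[[node]] == 1L && outdeg[[node]] == 1L
  used <- new.env(hash = TRUE, parent = emptyenv())
  contigs <- character(0)
  for (km in kmers) {
    if (!is.null(used[[km]])) next
    if (simple(substr(km, 1, k - 1))) next # interior edge of some path
    path <- km
    used[[km]] <- TRUE
    cur <- substr(km, 2, k)
    while (simple(cur)) {
      nxt <- out_edges[[cur]][1]
      if (!is.null(used[[nxt]])) break
      path <- c(path, nxt)
      used[[nxt]] <- TRUE
      cur <- substr(nxt, 2, k)
    }
    contigs <- c(contigs, paste0(path[1],
                                 paste(substr(path[-1], k, k), collapse = "")))
  }
  contigs
}

#' Filter breakdown products of longer transcripts
#'
#' De novo assembles the untrimmed reads together with the unique reads
#' (k-mer graph, unbranched paths) and removes table rows with an ungapped
#' <=2-mismatch hit to any assembled contig of at least `contig_min` bp.
#'
#' @param tbl unique-read table.
#' @param untrimmed_seqs character vector of adapter-free reads (set 2).
#' @param k k-mer length for assembly.
#' @param contig_min minimum contig length (bp) used for filtering.
#' @param max_mismatch maximum Hamming distance for a filtering hit.
#' @return filtered table; removed rows in `attr(, "removed")`, contigs in
#'   `attr(, "contigs")`.
#' @export
assemble_and_filter_breakdown <- function(tbl, untrimmed_seqs, k = 17,
                                          contig_min = 50, max_mismatch = 2) {
  contigs <- assemble_contigs(c(untrimmed_seqs, tbl$sequence), k = k)
  contigs <- contigs[nchar(contigs) >= contig_min]
  if (length(contigs) == 0 || nrow(tbl) == 0) {
    attr(tbl, "removed") <- tbl[0, , drop = FALSE]
    attr(tbl, "contigs") <- contigs
    return(tbl)
  }
  names(contigs) <- sprintf("contig_%d", seq_along(contigs))
  hits <- map_ungapped(tbl$sequence, contigs, max_mismatch = max_mismatch)
  drop <- tbl$sequence %in% hits$query
  out <- tbl[!drop, , drop = FALSE]
  attr(out, "removed") <- tbl[drop, , drop = FALSE]
  attr(out, "contigs") <- contigs
  rownames(out) <- NULL
  out
}

#' Run the full pre-processing cascade on per-library FASTQ-style reads
#'
#' Trims adapters, partitions reads, collapses to unique reads, then applies
#' the filters in the printed order: low abundance, contaminant classes,
#' breakdown-product assembly filter. Each stage only removes rows, so the
#' cascade is monotone.
#'
#' @param lib_reads named list (library_id) of data.frames with a `sequence`
#'   column (e.g. from [read_fastq()]) or character vectors.
#' @param design study design.
#' @param contaminants named character vector of contaminant references.
#' @param adapter3 3' adapter.
#' @param params list overriding defaults: `min_overlap`, `low_abundance_max`,
#'   `contaminant_max_mismatch`, `assembly_k`, `contig_min_len`.
#' @return list with `hairpin_table` (19-26 nt unique reads after all
#'   filters), `approach1_table` (15-50 nt unique reads, unfiltered beyond
#'   trimming/N removal), `untrimmed` (set-2 sequences), `log` (data.frame of
#'   per-stage row counts).
#' @export
preprocess_libraries <- function(lib_reads, design, contaminants = NULL,
                                 adapter3 = "AGATCGGAAGAGCACACGTCT",
                                 params = list()) {
  p <- utils::modifyList(list(min_overlap = 8, low_abundance_max = 5,
                              contaminant_max_mismatch = 2, assembly_k = 17,
                              contig_min_len = 50), params)
  hairpin_sets <- list()
  approach1_sets <- list()
  untrimmed <- character(0)
  for (lib in names(lib_reads)) {
    seqs <- if (is.data.frame(lib_reads[[lib]])) lib_reads[[lib]]$sequence
            else lib_reads[[lib]]
    tr <- trim_adapter(seqs, adapter3, min_overlap = p$min_overlap)
    parts <- partition_reads(tr)
    hairpin_sets[[lib]] <- parts$hairpin_set
    approach1_sets[[lib]] <- parts$approach1_set
    untrimmed <- c(untrimmed, parts$untrimmed_set)
  }
  tbl <- collapse_unique(hairpin_sets, design)
  log <- data.frame(stage = "collapsed", rows = nrow(tbl),
                    stringsAsFactors = FALSE)
  tbl <- filter_low_abundance(tbl, max_total = p$low_abundance_max)
  log <- rbind(log, data.frame(stage = "low_abundance", rows = nrow(tbl)))
  if (!is.null(contaminants)) {
    tbl <- filter_contaminants(tbl, contaminants,
                               max_mismatch = p$contaminant_max_mismatch)
    log <- rbind(log, data.frame(stage = "contaminants", rows = nrow(tbl)))
  }
  tbl <- assemble_and_filter_breakdown(tbl, unique(untrimmed),
                                       k = p$assembly_k,
                                       contig_min = p$contig_min_len,
                                       max_mismatch =
                                         p$contaminant_max_mismatch)
  log <- rbind(log, data.frame(stage = "breakdown", rows = nrow(tbl)))
  list(hairpin_table = tbl,
       approach1_table = collapse_unique(approach1_sets, design),
       untrimmed = unique(untrimmed),
       log = log)
}
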