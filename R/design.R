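# The study-design table: one row per sequencing library, mapping it to
# genotype, binary tolerance class, tissue, treatment and replicate.

TISSUE_LEVELS <- c("flag_leaf", "head")
TREATMENT_LEVELS <- c("control", "water_deficit")

validate_design <- function(df) {
  required <- c("library_id", "genotype", "tolerance", "tissue",
                "treatment", "replicate")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0) {
    stop("design table missing column(s): ", paste(missing, collapse = ", "))
  }
  df$tolerance <- as.integer(df$tolerance)
  df$replicate <- as.integer(df$replicate)
  if (any(!df$tissue %in% TISSUE_LEVELS)) {
    stop("unknown tissue level: ",
         paste(unique(setdiff(df$tissue, TISSUE_LEVELS)), collapse = ", "))
  }
  if (any(!df$treatment %in% TREATMENT_LEVELS)) {
    stop("unknown treatment level: ",
         paste(unique(setdiff(df$treatment, TREATMENT_LEVELS)), collapse = ", "))
  }
  if (any(!df$tolerance %in% c(0L, 1L))) {
    stop("tolerance must be binary (1 = tolerant, 0 = sensitive)")
  }
  if (any(df$replicate < 1L)) stop("replicate must be a positive integer")
  if (anyDuplicated(df$library_id)) {
    stop("duplicate library_id: ", df$library_id[duplicated(df$library_id)][1])
  }
  key <- paste(df$genotype, df$tissue, df$treatment, df$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (genotype, tissue, treatment, replicate) combination")
  }
  tol_per_geno <- tapply(df$tolerance, df$genotype,
                         function(x) length(unique(x)))
  if (any(tol_per_geno > 1)) {
    stop("tolerance is not constant within genotype: ",
         names(tol_per_geno)[tol_per_geno > 1][1])
  }
  df
}

#' Read and validate a study-design table
#'
#' Accepts a tab- or comma-separated file with a header, or a data.frame.
#' Columns: `library_id`, `genotype`, `tolerance` (1 = water-deficit tolerant,
#' 0 = sensitive), `tissue` (`flag_leaf`/`head`), `treatment`
#' (`control`/`water_deficit`), `replicate`. Validates that each
#' (genotype, tissue, treatment, replicate) combination is unique and that the
#' tolerance class is constant within a genotype.
#'
#' @param x path to the design file, or a data.frame.
#' @return validated design data.frame.
#' @export
parse_design <- function(x) {
  if (is.character(x)) {
    stopifnot(file.exists(x))
    first <- readLines(x, n = 1)
    sep <- if (grepl("\t", first)) "\t" else ","
    x <- utils::read.table(x, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  }
  validate_design(as.data.frame(x))
}

#' Build a full-factorial study design
#'
#' @param genotypes character vector of genotype names.
#' @param tolerant subset of `genotypes` that is water-deficit tolerant.
#' @param replicates biological replicates per factor cell.
#' @return design data.frame (one row per library).
#' @examples
#' # the full study layout: 4 genotypes x 2 tissues x 2 treatments x 6 reps
#' d <- make_design(c("Tamaroi", "Yawa", "EGA_Bellaroi", "Tjilkuri"),
#'                  tolerant = c("Tamaroi", "Yawa"), replicates = 6)
#' nrow(d)  # 96
#' @export
make_design <- function(genotypes = c("Tamaroi", "Yawa", "EGA_Bellaroi",
                                      "Tjilkuri"),
                        tolerant = c("Tamaroi", "Yawa"),
                        replicates = 6) {
  stopifnot(all(tolerant %in% genotypes))
  df <- expand.grid(replicate = seq_len(replicates),
                    treatment = TREATMENT_LEVELS,
                    tissue = TISSUE_LEVELS,
                    genotype = genotypes,
                    stringsAsFactors = FALSE)
  df$tolerance <- as.integer(df$genotype %in% tolerant)
  df$library_id <- sprintf("%s_%s_%s_r%d",
                           df$genotype,
                           ifelse(df$tissue == "flag_leaf", "FL", "H"),
                           ifelse(df$treatment == "control", "CG", "WG"),
                           df$replicate)
  validate_design(df[, c("library_id", "genotype", "tolerance", "tissue",
                         "treatment", "replicate")])
}

#' Write a design table as TSV
#' @param design design data.frame.
#' @param path output path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
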