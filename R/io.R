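#' Construct a genome record
#'
#' One assembly with its sequences, optional predicted proteins, CheckM-style
#' quality metrics, clade label, habitat and coordinates.
#'
#' @param genome_id unique identifier.
#' @param contigs character vector of nucleotide sequences (ACGTN alphabet).
#' @param proteins optional named character vector of amino-acid sequences.
#' @param completeness,contamination percent in `[0, 100]`.
#' @param clade_label one of [clade_levels()].
#' @param habitat free-text habitat class.
#' @param lat,lon decimal degrees, `NA` when unknown.
#' @return a list of class `genome_record`.
#' @export
genome_record <- function(genome_id, contigs, proteins = NULL,
                          completeness = NA_real_, contamination = NA_real_,
                          clade_label = "other", habitat = NA_character_,
                          lat = NA_real_, lon = NA_real_) {
  if (!is.character(genome_id) || length(genome_id) != 1 || !nzchar(genome_id))
    stop("genome_id must be a non-empty string")
  contigs <- as.character(contigs)
  if (length(contigs) == 0 || any(!nzchar(contigs)))
    stop("contigs must be non-empty sequences")
  if (any(grepl("[^ACGTNacgtn]", contigs)))
    stop("contigs contain characters outside the ACGTN alphabet")
  if (!is.na(completeness) && (completeness < 0 || completeness > 100))
    stop("completeness must be in [0,100]")
  if (!is.na(contamination) && (contamination < 0 || contamination > 100))
    stop("contamination must be in [0,100]")
  clade_label <- match.arg(clade_label, clade_levels())
  if (!is.na(lat) && abs(lat) > 90) stop("lat out of range")
  if (!is.na(lon) && abs(lon) > 180) stop("lon out of range")
  structure(list(genome_id = genome_id, contigs = contigs, proteins = proteins,
                 completeness = completeness, contamination = contamination,
                 clade_label = clade_label, habitat = habitat,
                 lat = lat, lon = lon),
            class = "genome_record")
}

#' Read genome assemblies with their metadata
#'
#' Loads one FASTA file per metadata row and attaches the quality and
#' ecological metadata. The metadata TSV must contain a `genome_id` column and
#' a `fasta` column with paths (absolute, or relative to the TSV's
#' directory); recognised optional columns are `completeness`,
#' `contamination`, `clade_label`, `habitat`, `lat`, `lon`.
#'
#' @param metadata_tsv path to the tab-delimited metadata table.
#' @return named list of [genome_record()] objects, one per metadata row.
#' @export
read_genomes <- function(metadata_tsv) {
  meta <- read_tsv(metadata_tsv)
  if (!all(c("genome_id", "fasta") %in% names(meta)))
    stop("metadata must contain 'genome_id' and 'fasta' columns")
  if (anyDuplicated(meta$genome_id))
    stop("duplicate genome_id in metadata: ",
         paste(unique(meta$genome_id[duplicated(meta$genome_id)]), collapse = ", "))
  base <- dirname(metadata_tsv)
  recs <- lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    path <- row$fasta
    if (!file.exists(path)) path <- file.path(base, row$fasta)
    if (!file.exists(path))
      stop("FASTA file not found for genome ", row$genome_id, ": ", row$fasta)
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) == 0) stop("no sequences in ", path)
    genome_record(
      genome_id = as.character(row$genome_id),
      contigs = as.character(seqs),
      completeness = if ("completeness" %in% names(meta)) as.numeric(row$completeness) else NA_real_,
      contamination = if ("contamination" %in% names(meta)) as.numeric(row$contamination) else NA_real_,
      clade_label = if ("clade_label" %in% names(meta)) as.character(row$clade_label) else "other",
      habitat = if ("habitat" %in% names(meta)) as.character(row$habitat) else NA_character_,
      lat = if ("lat" %in% names(meta)) as.numeric(row$lat) else NA_real_,
      lon = if ("lon" %in% names(meta)) as.numeric(row$lon) else NA_real_)
  })
  names(recs) <- meta$genome_id
  log_stage("read_genomes", n_genomes = length(recs))
  recs
}

#' Read a FASTQ file (plain or gzip)
#'
#' @param path FASTQ path; `.gz` handled transparently.
#' @return list with `reads` (character vector of sequences), `qualities`
#'   (character vector, retained but unused downstream) and `total_reads`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  if (file.size(path) == 0 || (grepl("\\.gz$", path) && length(readLines(path, n = 1L)) == 0))
    return(list(reads = character(0), qualities = character(0), total_reads = 0L))
  # reader warns about dropping (empty) metadata columns; benign
  sr <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(reads = as.character(sr),
       qualities = as.character(Biostrings::quality(sr)),
       total_reads = length(sr))
}

#' Write reads to FASTQ
#'
#' @param reads character vector of sequences.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param ids optional read names, defaults to `read1..readN`.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  dna <- Biostrings::DNAStringSet(setNames(as.character(reads), ids))
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  # constructor warns about dropping (empty) metadata columns; benign
  x <- suppressWarnings(
    Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(qual)))
  Biostrings::writeQualityScaledXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences (DNA or protein).
#' @param path output path.
#' @param type `"dna"` or `"aa"`.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::DNAStringSet(seqs) else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write tab-delimited tables
#'
#' The canonical tabular dialect of the pipeline: tab-delimited, header row,
#' UTF-8, no quoting, missing values as empty fields.
#'
#' @param path file path.
#' @return `read_tsv`: a `data.frame` with character/numeric columns as
#'   stored.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "", check.names = FALSE, fileEncoding = "UTF-8")
}

#' @rdname read_tsv
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}
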