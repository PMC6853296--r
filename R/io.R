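# ---------------------------------------------------------------------------
# Standard-format I/O, manifest, and the insert-range arithmetic.
# ---------------------------------------------------------------------------

#' Read a FASTA file
#'
#' @param path FASTA path (plain or gzip).
#' @return A [Biostrings::DNAStringSet], uppercased, order preserved.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  Biostrings::DNAStringSet(toupper(ss))
}

#' Write a FASTA file
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTQ file into a data frame
#'
#' Validates the 4-line record structure explicitly so that malformed
#' files fail with the offending line number, then returns the records in
#' file order. Sequences are uppercased. Gzip input is handled
#' transparently.
#'
#' @param path FASTQ path.
#' @return Data frame `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop(sprintf("malformed FASTQ %s: %d lines (not a multiple of 4)",
                 path, n), call. = FALSE)
  }
  if (n == 0L) {
    return(data.frame(read_id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  at <- seq(1L, n, by = 4L)
  bad_at <- at[!startsWith(lines[at], "@")]
  if (length(bad_at)) {
    stop(sprintf("malformed FASTQ %s: line %d does not start with '@'",
                 path, bad_at[1L]), call. = FALSE)
  }
  bad_plus <- (at + 2L)[!startsWith(lines[at + 2L], "+")]
  if (length(bad_plus)) {
    stop(sprintf("malformed FASTQ %s: line %d does not start with '+'",
                 path, bad_plus[1L]), call. = FALSE)
  }
  seqs <- toupper(lines[at + 1L])
  quals <- lines[at + 3L]
  bad_len <- at[nchar(seqs) != nchar(quals)]
  if (length(bad_len)) {
    stop(sprintf(
      "malformed FASTQ %s: sequence/quality length mismatch at line %d",
      path, bad_len[1L] + 1L), call. = FALSE)
  }
  data.frame(
    read_id = sub("\\s.*$", "", sub("^@", "", lines[at])),
    seq = seqs, qual = quals, stringsAsFactors = FALSE
  )
}

#' Write a FASTQ file
#'
#' @param reads Data frame `read_id`, `seq`, optionally `qual` (constant
#'   `"I"` Phred+33 qualities are filled in when absent).
#' @param path Output path (gzip when ending in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    strrep("I", nchar(reads$seq))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual),
               con)
  }
  invisible(path)
}

#' Export assignments as SAM
#'
#' One record per read; the winning category is carried in the `XC` tag and
#' the mismatch count in `NM`. Antisense placements are stored
#' reverse-complemented with flag 16, unmapped reads with flag 4.
#'
#' @param assignments A `cp_assignments` data frame.
#' @param refs A `cp_refs` bundle (for the `@SQ` header).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(assignments, refs, path) {
  seqs <- all_ref_chars(refs)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)),
              sprintf("@PG\tID:cpseq\tPN:cpseq\tVN:%s",
                      as.character(packageVersion("cpseq"))))
  a <- assignments
  mapped <- a$category != "unmapped"
  flag <- ifelse(!mapped, 4L, ifelse(a$strand == "-", 16L, 0L))
  seq_out <- a$seq
  minus <- mapped & a$strand == "-"
  if (any(minus)) {
    seq_out[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(a$seq[minus])))
  }
  records <- paste(
    a$read_id, flag,
    ifelse(mapped, a$ref_id, "*"),
    ifelse(mapped, a$start + 1L, 0L),
    ifelse(mapped, 255L, 0L),
    ifelse(mapped, paste0(nchar(a$seq), "M"), "*"),
    "*", 0L, 0L, seq_out, strrep("I", nchar(seq_out)),
    ifelse(mapped, paste0("NM:i:", a$n_mismatch), "NM:i:0"),
    paste0("XC:Z:", a$category),
    sep = "\t"
  )
  writeLines(c(header, records), path)
  invisible(path)
}

#' Export mapped assignments as BED6
#'
#' BED is 0-based half-open, matching the in-memory coordinates.
#'
#' @param assignments A `cp_assignments` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(assignments, path) {
  a <- assignments[assignments$category != "unmapped", , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   a$ref_id, a$start, a$end, a$read_id,
                   pmax(0L, 60L - 30L * a$n_mismatch), a$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Export a coverage profile as bedGraph
#'
#' @param profile A `cp_profile` from [alignment_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path) {
  cov <- profile$coverage
  runs <- rle(cov)
  ends <- cumsum(runs$lengths)
  starts <- c(0L, head(ends, -1L))
  keep <- runs$values != 0
  lines <- sprintf("%s\t%d\t%d\t%d", profile$ref_id,
                   starts[keep], ends[keep], runs$values[keep])
  writeLines(lines, path)
  invisible(path)
}

#' Write a TSV report
#'
#' User-facing tabular exports; any `start`/`end` columns are converted
#' from 0-based half-open to 1-based inclusive.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  if ("start" %in% names(df)) df$start <- df$start + 1L
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimated insert range from cDNA product sizes
#'
#' The sequenced cDNA is 5'-adapter + insert + 3'-adapter, so the insert
#' range is the product-size range minus both adapter lengths,
#' elementwise. With 140--160 bp products and 55 + 63 bp adapters the
#' estimated inserted sequences span 22--42 bp.
#'
#' @param product_sizes `c(min_bp, max_bp)` of the amplified products.
#' @param adapter5_bp,adapter3_bp Adapter lengths in bp.
#' @return Integer `c(min_insert, max_insert)`.
#' @export
compute_insert_range <- function(product_sizes, adapter5_bp, adapter3_bp) {
  stopifnot(length(product_sizes) == 2L, all(product_sizes > 0),
            adapter5_bp > 0, adapter3_bp > 0)
  insert <- as.integer(product_sizes) - as.integer(adapter5_bp) -
    as.integer(adapter3_bp)
  if (any(insert < 0)) {
    stop("adapters longer than product: negative insert size",
         call. = FALSE)
  }
  insert
}

#' Write a run manifest
#'
#' Records the configuration, input checksums, per-stage read counts and
#' seeds of a pipeline run as JSON; re-running with the same configuration
#' and seeds reproduces all outputs byte-identically.
#'
#' @param path Output JSON path.
#' @param config Configuration list (coerced to plain lists).
#' @param stage_counts Named list/vector of per-stage read counts.
#' @param inputs Character vector of input file paths to checksum.
#' @param seed Seed(s) used.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config, stage_counts, inputs = character(0),
                               seed = NULL) {
  manifest <- list(
    tool = "cpseq",
    version = as.character(packageVersion("cpseq")),
    seed = seed,
    config = unclass(config),
    stage_counts = as.list(stage_counts),
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list()
  )
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  file.rename(tmp, path)  # atomic publish
  invisible(path)
}
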