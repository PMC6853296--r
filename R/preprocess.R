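# ---------------------------------------------------------------------------
# 3'-adapter removal and length selection (the read-extraction step).
# ---------------------------------------------------------------------------

#' Trim the 3' adapter from reads
#'
#' Finds, for each read, the leftmost suffix that matches a prefix of the
#' adapter with at least `min_overlap` bases of overlap and at most 10%
#' mismatches of the overlap length (no indels; `N` counts as a mismatch),
#' and removes it. Reads with no acceptable match are returned intact with
#' `found = FALSE`.
#'
#' @param reads Character vector of reads over `{A,C,G,T,N}`.
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum overlap between read suffix and adapter
#'   prefix (default 5).
#' @param max_error_rate Mismatch tolerance as a fraction of the overlap
#'   (default 0.1).
#'
#' @return A data frame with columns `seq` (trimmed read) and `found`.
#' @export
trim_adapter <- function(reads, adapter = cp_default_adapter(),
                         min_overlap = 5L, max_error_rate = 0.1) {
  n <- length(reads)
  if (n == 0L) {
    return(data.frame(seq = character(0), found = logical(0),
                      stringsAsFactors = FALSE))
  }
  reads <- toupper(reads)
  adapter <- toupper(adapter)
  ad_len <- nchar(adapter)
  lens <- nchar(reads)
  max_len <- max(lens)
  # read characters as an n x max_len matrix (padded with "")
  chars <- matrix("", nrow = n, ncol = max_len)
  split_ <- strsplit(reads, "")
  for (i in seq_len(n)) if (lens[i] > 0L) chars[i, seq_len(lens[i])] <-
    split_[[i]]
  ad_chars <- strsplit(adapter, "")[[1]]

  cut_at <- rep(NA_integer_, n)  # 1-based read position where adapter starts
  for (p in seq_len(max_len)) {
    open <- which(is.na(cut_at) & lens - p + 1L >= min_overlap)
    if (!length(open)) next
    ov <- pmin(lens[open] - p + 1L, ad_len)
    allowed <- floor(max_error_rate * ov)
    mism <- integer(length(open))
    for (j in seq_len(min(max(ov), ad_len))) {
      live <- ov >= j
      mism[live] <- mism[live] +
        (chars[open[live], p + j - 1L] != ad_chars[j])
    }
    hit <- mism <= allowed
    cut_at[open[hit]] <- p
  }
  found <- !is.na(cut_at)
  out <- reads
  out[found] <- substr(reads[found], 1L, cut_at[found] - 1L)
  data.frame(seq = out, found = found, stringsAsFactors = FALSE)
}

#' Select reads by length
#'
#' @param reads Character vector (trimmed reads).
#' @param min_len,max_len Inclusive window (defaults 20 and 45 nt).
#' @return List with `kept` (the passing reads), `n_kept`, `n_discarded`.
#' @export
length_select <- function(reads, min_len = 20L, max_len = 45L) {
  keep <- nchar(reads) >= min_len & nchar(reads) <= max_len
  list(kept = reads[keep], keep = keep,
       n_kept = sum(keep), n_discarded = sum(!keep))
}

#' Run adapter trimming and length selection on a read table
#'
#' The read-extraction stage: trims the 3' adapter, optionally keeps
#' untrimmed reads, then applies the length window. The returned summary
#' mirrors the bookkeeping columns of a library-statistics table (input
#' reads, adapter-found, length-selected).
#'
#' @param reads Data frame with `read_id`, `seq` (and optionally `qual`),
#'   e.g. the `reads` element of a `cp_library` or the result of
#'   [read_fastq()].
#' @param config A [pipeline_config()].
#'
#' @return A list of class `cp_preprocessed`: `reads` (data frame
#'   `read_id`, `seq` of the surviving, trimmed reads), and `summary`
#'   (data frame `n_input`, `n_adapter_found`, `n_kept_untrimmed`,
#'   `n_length_selected`).
#' @export
preprocess_reads <- function(reads, config = pipeline_config()) {
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)))
  tr <- trim_adapter(reads$seq, config$adapter_seq,
                     config$min_adapter_overlap)
  keep_tr <- tr$found | config$keep_untrimmed
  cand <- data.frame(read_id = reads$read_id[keep_tr],
                     seq = tr$seq[keep_tr], stringsAsFactors = FALSE)
  sel <- length_select(cand$seq, config$min_len, config$max_len)
  out <- cand[sel$keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(
    reads = out,
    summary = data.frame(
      n_input = nrow(reads),
      n_adapter_found = sum(tr$found),
      n_kept_untrimmed = sum(keep_tr & !tr$found),
      n_length_selected = nrow(out)
    )
  ), class = "cp_preprocessed")
}
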