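# ---------------------------------------------------------------------------
# Prioritized sequential mapping with a bounded Hamming distance.
#
# Engine: all references of a bundle are concatenated into one subject with
# 8-N spacers; Biostrings::matchPattern scans it once per read and strand,
# and hits are filtered to those fully contained in a single reference span
# (a window overlapping a spacer carries N mismatches and cannot represent
# a within-reference placement). Category assignment then follows the fixed
# priority spike_in > cyto_tRNA > rRNA > mito > mRNA > genome.
# ---------------------------------------------------------------------------

# Concatenated-subject index over a named list of category DNAStringSets.
build_mapping_index <- function(categories, spacer_len = 8L) {
  ref_id <- character(0); category <- character(0)
  ref_start <- integer(0); ref_len <- integer(0)
  parts <- character(0)
  pos <- 1L
  spacer <- strrep("N", spacer_len)
  for (cat_ in names(categories)) {
    ss <- categories[[cat_]]
    if (!length(ss)) next
    seqs <- as.character(ss)
    for (i in seq_along(seqs)) {
      ref_id <- c(ref_id, names(seqs)[i])
      category <- c(category, cat_)
      ref_start <- c(ref_start, pos)
      ref_len <- c(ref_len, nchar(seqs[i]))
      parts <- c(parts, seqs[i], spacer)
      pos <- pos + nchar(seqs[i]) + spacer_len
    }
  }
  subject_char <- paste(parts, collapse = "")
  list(
    subject = Biostrings::DNAString(subject_char),
    subject_char = subject_char,
    spans = data.frame(ref_id = ref_id, category = category,
                       ref_start = ref_start, ref_len = ref_len,
                       stringsAsFactors = FALSE),
    kmer_cache = new.env(parent = emptyenv())
  )
}

# Positions (1-based) of every length-L window of the subject, grouped by
# window sequence; cached on the index. The subject is small (tens of kb),
# so exact seeding via a hash of its windows beats building automata.
subject_kmer_table <- function(index, L) {
  key <- as.character(L)
  if (!is.null(index$kmer_cache[[key]])) return(index$kmer_cache[[key]])
  S <- nchar(index$subject_char)
  if (L > S) {
    tab <- list()
  } else {
    starts <- seq_len(S - L + 1L)
    kmers <- substring(index$subject_char, starts, starts + L - 1L)
    tab <- split(starts, kmers)
  }
  index$kmer_cache[[key]] <- tab
  tab
}

# Seed-and-extend bounded-Hamming search for a batch of reads against the
# index subject, one orientation. For k <= 1 every valid placement has at
# least one exact half (pigeonhole), so exact PDict matches of the two
# halves enumerate all candidates, which are then verified by direct
# comparison. Patterns must be ACGT-only (callers route others through
# index_hits). Returns data.frame(read (index into `seqs`), start 1-based
# subject position, n_mismatch).
batch_hits <- function(seqs, index, k) {
  stopifnot(k <= 1L)
  out <- list()
  subj_len <- nchar(index$subject_char)
  for (w in unique(nchar(seqs))) {
    ii <- which(nchar(seqs) == w)
    if (w < 4L || w > subj_len) next
    half <- w %/% 2L
    pieces <- list(c(1L, half), c(half + 1L, w))
    cand_read <- integer(0); cand_start <- integer(0)
    for (pc in pieces) {
      L <- pc[2] - pc[1] + 1L
      tab <- subject_kmer_table(index, L)
      if (!length(tab)) next
      piece_seq <- substr(seqs[ii], pc[1], pc[2])
      slot <- match(piece_seq, names(tab))
      found <- which(!is.na(slot))
      if (!length(found)) next
      pos_lists <- tab[slot[found]]
      n_per <- lengths(pos_lists)
      cand_read <- c(cand_read, rep(ii[found], n_per))
      cand_start <- c(cand_start, unlist(pos_lists, use.names = FALSE) -
                        (pc[1] - 1L))
    }
    if (!length(cand_read)) next
    ok <- cand_start >= 1L & cand_start + w - 1L <= subj_len
    cand_read <- cand_read[ok]; cand_start <- cand_start[ok]
    key <- paste(cand_read, cand_start)
    dup <- duplicated(key)
    cand_read <- cand_read[!dup]; cand_start <- cand_start[!dup]
    if (!length(cand_read)) next
    window <- substr(rep(index$subject_char, length(cand_start)),
                     cand_start, cand_start + w - 1L)
    reads_w <- seqs[cand_read]
    mm <- integer(length(cand_read))
    for (j in seq_len(w)) {
      mm <- mm + (substr(window, j, j) != substr(reads_w, j, j))
    }
    keep <- mm <= k
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        read = cand_read[keep], start = cand_start[keep],
        n_mismatch = mm[keep])
    }
  }
  if (!length(out)) {
    return(data.frame(read = integer(0), start = integer(0),
                      n_mismatch = integer(0)))
  }
  do.call(rbind, out)
}

# All placements of a batch of unique reads on the index, both strands,
# with span containment and category/strand metadata attached. Reads with
# non-ACGT characters or k > 1 fall back to the per-read scan.
batch_index_hits <- function(uniq, index, k) {
  clean <- grepl("^[ACGT]+$", uniq) & nchar(uniq) >= 4L
  res <- list()
  if (any(clean) && k <= 1L) {
    ci <- which(clean)
    fwd <- batch_hits(uniq[ci], index, k)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(uniq[ci])))
    rev <- batch_hits(rc, index, k)
    fwd$strand <- rep("+", nrow(fwd))
    rev$strand <- rep("-", nrow(rev))
    both <- rbind(fwd, rev)
    both$read <- ci[both$read]
    both$ref_id <- NA_character_
    both$category <- NA_character_
    both$local_start <- NA_integer_
    res[[1]] <- both
  }
  slow <- which(!clean | k > 1L)
  for (i in slow) {
    for (s in c("+", "-")) {
      h <- index_hits(uniq[i], index, k, s)
      if (nrow(h)) {
        res[[length(res) + 1L]] <- data.frame(
          read = i, start = NA_integer_, n_mismatch = h$n_mismatch,
          strand = s, ref_id = h$ref_id, category = h$category,
          local_start = h$start, stringsAsFactors = FALSE)
      }
    }
  }
  hits <- do.call(rbind, res)
  if (is.null(hits) || !nrow(hits)) {
    return(data.frame(read = integer(0), ref_id = character(0),
                      category = character(0), local_start = integer(0),
                      width = integer(0), strand = character(0),
                      n_mismatch = integer(0), stringsAsFactors = FALSE))
  }
  # resolve subject positions from the fast path into reference spans
  need <- is.na(hits$start) == FALSE
  if (any(need)) {
    spans <- index$spans
    span_idx <- findInterval(hits$start[need], spans$ref_start)
    w <- nchar(uniq[hits$read[need]])
    inside <- hits$start[need] + w - 1L <=
      spans$ref_start[span_idx] + spans$ref_len[span_idx] - 1L
    hits$ref_id[need] <- ifelse(inside, spans$ref_id[span_idx],
                                NA_character_)
    hits$category[need] <- ifelse(inside, spans$category[span_idx],
                                  NA_character_)
    hits$local_start[need] <- hits$start[need] - spans$ref_start[span_idx]
  }
  hits <- hits[!is.na(hits$ref_id), , drop = FALSE]
  hits$width <- nchar(uniq[hits$read])
  hits[, c("read", "ref_id", "category", "local_start", "width", "strand",
           "n_mismatch")]
}

# All placements of one read on the index subject for one orientation.
# `read` may be a character or an XString already oriented for `strand`
# (callers that loop pre-convert in batch: per-read DNAString conversion
# costs as much as the scan itself). Returns data.frame(ref_id, category,
# start, end, strand, n_mismatch) with 0-based half-open reference
# coordinates.
index_hits <- function(read, index, k, strand, oriented = FALSE) {
  if (is.character(read)) {
    pat <- Biostrings::DNAString(read)
    if (strand == "-" && !oriented) {
      pat <- Biostrings::reverseComplement(pat)
    }
  } else {
    pat <- read
    if (strand == "-" && !oriented) {
      pat <- Biostrings::reverseComplement(pat)
    }
  }
  if (length(pat) > length(index$subject)) {
    return(empty_hits())
  }
  m <- Biostrings::matchPattern(pat, index$subject, max.mismatch = k,
                                with.indels = FALSE, fixed = TRUE)
  if (!length(m)) return(empty_hits())
  starts <- Biostrings::start(m)  # 1-based on subject
  w <- length(pat)
  spans <- index$spans
  span_idx <- findInterval(starts, spans$ref_start)
  inside <- span_idx >= 1L &
    starts + w - 1L <= spans$ref_start[span_idx] + spans$ref_len[span_idx] - 1L
  if (!any(inside)) return(empty_hits())
  starts <- starts[inside]
  span_idx <- span_idx[inside]
  nmm <- Biostrings::neditStartingAt(pat, index$subject,
                                     starting.at = starts,
                                     with.indels = FALSE, fixed = TRUE)
  local0 <- starts - spans$ref_start[span_idx]  # 0-based within reference
  data.frame(
    ref_id = spans$ref_id[span_idx],
    category = spans$category[span_idx],
    start = local0, end = local0 + w,
    strand = strand, n_mismatch = as.integer(nmm),
    stringsAsFactors = FALSE
  )
}

empty_hits <- function() {
  data.frame(ref_id = character(0), category = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             n_mismatch = integer(0), stringsAsFactors = FALSE)
}

#' All bounded-Hamming placements of a read on a reference set
#'
#' Scans every offset of every reference (and, if requested, the reverse
#' strand) and returns the placements with Hamming distance at most `k`.
#' No indels; `N` counts as a mismatch.
#'
#' @param read A read sequence.
#' @param references A named character vector or
#'   [Biostrings::DNAStringSet] of references.
#' @param k Maximum mismatches.
#' @param strands Orientations to search (`"+"`, `"-"`).
#'
#' @return Data frame `ref_id`, `start` (0-based), `end` (half-open),
#'   `strand`, `n_mismatch`, ordered by (`n_mismatch`, `ref_id`, `start`,
#'   `strand`).
#' @export
hamming_hits <- function(read, references, k = 1L, strands = c("+", "-")) {
  if (is.character(references)) {
    references <- Biostrings::DNAStringSet(references)
  }
  index <- build_mapping_index(list(refset = references))
  hits <- do.call(rbind, lapply(strands, function(s)
    index_hits(read, index, k, s)))
  hits <- hits[, setdiff(names(hits), "category"), drop = FALSE]
  hits[order(hits$n_mismatch, hits$ref_id, hits$start,
             match(hits$strand, c("+", "-"))), , drop = FALSE]
}

#' Sequentially map reads to prioritized reference categories
#'
#' Each read is assigned to the first category, in the order
#' `spike_in, cyto_tRNA, rRNA, mito, mRNA, genome`, in which it has at
#' least one placement within the mismatch budget; priority precedes
#' mismatch count (a perfect mRNA hit loses to a 1-mismatch tRNA hit).
#' Within the winning category the placement with the fewest mismatches is
#' kept; remaining ties break deterministically by reference id
#' (lexicographic), then smallest start, then `+` strand. Antisense
#' placements are considered only for the mito, mRNA and genome categories
#' (mature small-RNA references are single-stranded). Reads with no
#' placement anywhere are reported as `unmapped`.
#'
#' @param reads Data frame with `read_id` and `seq` (e.g. the `reads` of a
#'   `cp_preprocessed` object).
#' @param refs A `cp_refs` bundle.
#' @param max_mismatch Mismatch budget (default 1).
#'
#' @return Data frame of class `cp_assignments`, one row per input read:
#'   `read_id`, `seq`, `category` (a mapping category or `"unmapped"`),
#'   `ref_id`, `start` (0-based), `end` (half-open), `strand`,
#'   `n_mismatch` (NA for unmapped reads).
#' @export
map_sequential <- function(reads, refs, max_mismatch = 1L) {
  stopifnot(is.data.frame(reads), all(c("read_id", "seq") %in% names(reads)),
            inherits(refs, "cp_refs"))
  present <- names(refs$categories)[vapply(refs$categories, length, 1L) > 0]
  missing_ <- setdiff(cp_categories(), present)
  if (length(missing_)) {
    warning("empty reference categor(ies) skipped: ",
            paste(missing_, collapse = ", "))
  }
  index <- build_mapping_index(refs$categories[present])
  priority <- intersect(cp_categories(), present)
  anti <- cp_antisense_categories()

  if (nrow(reads) == 0L) {
    out <- data.frame(read_id = character(0), seq = character(0),
                      category = character(0), ref_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_mismatch = integer(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("cp_assignments", "data.frame")
    return(out)
  }

  uniq <- unique(reads$seq)
  hits <- batch_index_hits(uniq, index, max_mismatch)
  # antisense placements only where allowed
  hits <- hits[hits$strand == "+" | hits$category %in% anti, , drop = FALSE]
  # best placement per read: first category in priority order, then fewest
  # mismatches, then ref_id / start / strand
  ord <- order(hits$read, match(hits$category, priority), hits$n_mismatch,
               hits$ref_id, hits$local_start,
               match(hits$strand, c("+", "-")))
  hits <- hits[ord, , drop = FALSE]
  top <- hits[!duplicated(hits$read), , drop = FALSE]

  best <- data.frame(category = rep("unmapped", length(uniq)),
                     ref_id = NA_character_, start = NA_integer_,
                     end = NA_integer_, strand = NA_character_,
                     n_mismatch = NA_integer_, stringsAsFactors = FALSE)
  best$category[top$read] <- top$category
  best$ref_id[top$read] <- top$ref_id
  best$start[top$read] <- top$local_start
  best$end[top$read] <- top$local_start + top$width
  best$strand[top$read] <- top$strand
  best$n_mismatch[top$read] <- top$n_mismatch

  out <- cbind(
    data.frame(read_id = reads$read_id, seq = reads$seq,
               stringsAsFactors = FALSE),
    best[match(reads$seq, uniq), , drop = FALSE]
  )
  rownames(out) <- NULL
  class(out) <- c("cp_assignments", "data.frame")
  out
}

#' Category proportions of mapped reads
#'
#' Fractions of assigned reads per category, computed over mapped,
#' non-spike-in reads (the denominator a category-proportion panel uses).
#'
#' @param assignments A `cp_assignments` data frame.
#' @return Data frame `category`, `n`, `fraction` (descending by `n`);
#'   empty (with a warning) when nothing mapped.
#' @export
category_proportions <- function(assignments) {
  keep <- assignments$category != "unmapped" &
    assignments$category != "spike_in"
  if (!any(keep)) {
    warning("no mapped non-spike-in reads")
    return(data.frame(category = character(0), n = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  tab <- table(assignments$category[keep])
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n), , drop = FALSE]
}
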