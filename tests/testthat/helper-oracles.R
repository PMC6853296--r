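# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain loops over every offset / overlap.

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

# every placement of `read` on every reference with Hamming distance <= k
oracle_hamming <- function(read, refs, k, strands = c("+", "-")) {
  out <- list()
  for (strand in strands) {
    q <- if (strand == "-") oracle_revcomp(read) else read
    qc <- strsplit(q, "")[[1]]
    w <- length(qc)
    for (rid in names(refs)) {
      rc <- strsplit(refs[[rid]], "")[[1]]
      L <- length(rc)
      if (w > L) next
      for (s0 in 0:(L - w)) {
        mm <- sum(qc != rc[(s0 + 1):(s0 + w)])
        if (mm <= k) {
          out[[length(out) + 1L]] <- data.frame(
            ref_id = rid, start = s0, end = s0 + w, strand = strand,
            n_mismatch = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ref_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_mismatch = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$n_mismatch, res$ref_id, res$start,
            match(res$strand, c("+", "-"))), , drop = FALSE]
}

# expected trimming point: enumerate every suffix/prefix overlap
oracle_trim <- function(read, adapter, min_overlap = 5, max_err = 0.1) {
  rc <- strsplit(read, "")[[1]]
  ac <- strsplit(adapter, "")[[1]]
  n <- length(rc)
  for (p in seq_len(n)) {
    ov <- min(n - p + 1L, length(ac))
    if (ov < min_overlap) next
    mm <- sum(rc[p:(p + ov - 1L)] != ac[1:ov])
    if (mm <= floor(max_err * ov)) {
      return(list(seq = substr(read, 1L, p - 1L), found = TRUE))
    }
  }
  list(seq = read, found = FALSE)
}

# brute-force scan over every offset, vectorized across offsets (still
# independent of the mapper's seeding engine: it checks all positions)
oracle_hamming_vec <- function(read, refs, k, strands = c("+", "-")) {
  out <- list()
  for (strand in strands) {
    q <- if (strand == "-") oracle_revcomp(read) else read
    qc <- strsplit(q, "")[[1]]
    w <- length(qc)
    for (rid in names(refs)) {
      rc <- strsplit(refs[[rid]], "")[[1]]
      L <- length(rc)
      if (w > L) next
      mm <- integer(L - w + 1L)
      for (j in seq_len(w)) {
        mm <- mm + (rc[j:(L - w + j)] != qc[j])
      }
      hit <- which(mm <= k)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          ref_id = rid, start = hit - 1L, end = hit - 1L + w,
          strand = strand, n_mismatch = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(ref_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_mismatch = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$n_mismatch, res$ref_id, res$start,
                   match(res$strand, c("+", "-"))), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# sequential category assignment recomputed from the brute-force scan
oracle_category <- function(read, refs_bundle, k) {
  anti <- c("mito", "mRNA", "genome")
  for (cat_ in cp_categories()) {
    seqs <- setNames(as.character(refs_bundle$categories[[cat_]]),
                     names(refs_bundle$categories[[cat_]]))
    strands <- if (cat_ %in% anti) c("+", "-") else "+"
    hits <- oracle_hamming(read, seqs, k, strands)
    if (nrow(hits)) {
      return(cbind(category = cat_, hits[1L, , drop = FALSE]))
    }
  }
  data.frame(category = "unmapped", ref_id = NA_character_,
             start = NA_integer_, end = NA_integer_,
             strand = NA_character_, n_mismatch = NA_integer_,
             stringsAsFactors = FALSE)
}
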