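# 5-mer blocks of the adapter. Any read suffix that the trimmer would accept
# (>= 5 nt overlap with the adapter prefix, <= 10% mismatches) must contain
# at least one of these blocks exactly, so excluding them from the toy
# references guarantees that no substrate sequence can be mistaken for an
# adapter. This keeps trimming exact on simulated data.
adapter_blocks <- function(adapter) {
  n <- nchar(adapter) %/% 5L
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i) substr(adapter, 5L * i - 4L, 5L * i), "")
}

DNA_BASES <- c("A", "C", "G", "T")

# Random DNA free of the given k-mers outside `fixed` positions (1-based).
# Occurrences are repaired locally by resampling their free positions.
random_clean_dna <- function(n, forbidden, fixed = integer(0),
                             template = NULL) {
  x <- if (is.null(template)) sample(DNA_BASES, n, replace = TRUE) else
    strsplit(template, "")[[1]]
  free <- setdiff(seq_len(n), fixed)
  for (iter in 1:200) {
    s <- paste(x, collapse = "")
    bad <- integer(0)
    for (f in forbidden) {
      m <- gregexpr(f, s, fixed = TRUE)[[1]]
      if (m[1] != -1L) {
        bad <- c(bad, unlist(lapply(m, function(p) p:(p + nchar(f) - 1L))))
      }
    }
    bad <- intersect(unique(bad), free)
    if (!length(bad)) return(s)
    x[bad] <- sample(DNA_BASES, length(bad), replace = TRUE)
  }
  stop("could not build a reference avoiding adapter k-mers", call. = FALSE)
}

# Positions p (0-based, 1 <= p <= L-1) at which a fragment boundary sits
# between a C (reference index p-1) and an A (index p).
ca_junctions <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  which(chars[-length(chars)] == "C" & chars[-1] == "A")  # 0-based boundary
}

# TRUE when the sequence admits at least one pair of C|A boundaries whose
# spacing lies inside the fragment-length window.
has_ca_pair <- function(seq, len_range) {
  j <- ca_junctions(seq)
  if (length(j) < 2L) return(FALSE)
  d <- outer(j, j, "-")
  any(d >= len_range[1] & d <= len_range[2])
}

trna_isoacceptor_pool <- c(
  "ValCAC", "GlyGCC", "LysCUU", "GluCUC", "AspGUC", "AlaAGC", "SerGCU",
  "ArgUCU", "LeuCAA", "PheGAA", "ProAGG", "ThrUGU", "IleAAU", "MetCAU"
)

# Anticodon loop used by every toy tRNA (np 32-38). It contains exactly one
# C|A junction (between np 34 and np 35) and cannot create another one at
# its edges (np 32 is T; np 38 is A), so the simulator's anticodon cleavage
# site is unique and known.
TOY_LOOP <- "TTCATAA"

#' Build a toy reference bundle
#'
#' Constructs small stand-in references for every mapping category: mature
#' cytoplasmic tRNAs (76 nt bodies with the post-transcriptional 3' CCA and
#' a fixed anticodon loop at np 32--38 holding a single C|A junction, plus
#' one tRNA-His-like record with a G at np -1), rRNAs, a mitochondrial
#' genome, mRNAs, a genome sequence, and the 37-nt spike-in. mRNA/rRNA/
#' mito/genome sequences are 300--2000 nt and guaranteed to contain C|A
#' junction pairs spaced 20--45 nt apart. All references avoid the 5-mer
#' blocks of `adapter`, which makes 3'-adapter detection on simulated reads
#' exact (no substrate suffix can imitate an adapter prefix).
#'
#' @param seed Integer seed.
#' @param n_trna Number of tRNA records (>= 1; the last is the His record).
#' @param n_mrna,n_rrna Numbers of mRNA and rRNA records (>= 1).
#' @param adapter Adapter whose 5-mers are excluded from the references.
#'
#' @return A list of class `cp_refs` with elements `categories` (named list
#'   of [Biostrings::DNAStringSet], one per category in [cp_categories()]
#'   order), `trna_annotation` (data frame: `ref_id`, `isoacceptor`,
#'   `loop_start`, `loop_end` 0-based inclusive, `has_minus1`,
#'   `minus1_base`, `np1_index` 0-based), and `adapter`.
#' @export
build_toy_references <- function(seed = 1L, n_trna = 6L, n_mrna = 12L,
                                 n_rrna = 2L, adapter = cp_default_adapter()) {
  if (n_trna < 1 || n_mrna < 1 || n_rrna < 1) {
    stop("reference counts must be >= 1", call. = FALSE)
  }
  forbidden <- adapter_blocks(adapter)
  len_range <- c(20L, 45L)
  with_rng(seed, {
    ## --- tRNAs ------------------------------------------------------------
    iso <- c(rep_len(trna_isoacceptor_pool, max(0L, n_trna - 1L)), "HisGUG")
    iso <- make.unique(iso, sep = "v")
    trna_seqs <- character(n_trna)
    ann <- vector("list", n_trna)
    for (i in seq_len(n_trna)) {
      his <- i == n_trna
      # 76-nt body: np 1-31 random, np 32-38 = TOY_LOOP, np 39-73 random,
      # np 74-76 = CCA; His carries an extra G at np -1.
      body <- c(sample(DNA_BASES, 31, TRUE), strsplit(TOY_LOOP, "")[[1]],
                sample(DNA_BASES, 35, TRUE), c("C", "C", "A"))
      fixed <- c(32:38, 74:76)
      s <- random_clean_dna(76L, forbidden, fixed,
                            template = paste(body, collapse = ""))
      if (his) s <- paste0("G", s)
      trna_seqs[i] <- s
      off <- if (his) 1L else 0L  # 0-based index of np 1
      ann[[i]] <- data.frame(
        ref_id = paste0("tRNA-", iso[i]),
        isoacceptor = iso[i],
        loop_start = 31L + off, loop_end = 37L + off,
        has_minus1 = his,
        minus1_base = if (his) "G" else NA_character_,
        np1_index = off,
        stringsAsFactors = FALSE
      )
    }
    ann <- do.call(rbind, ann)
    names(trna_seqs) <- ann$ref_id

    make_substrates <- function(prefix, n, lens = NULL) {
      out <- character(n)
      for (i in seq_len(n)) {
        L <- if (is.null(lens)) sample(300:2000, 1L) else lens[i]
        repeat {
          s <- random_clean_dna(L, forbidden)
          if (has_ca_pair(s, len_range)) break
        }
        out[i] <- s
      }
      names(out) <- sprintf("%s%03d", prefix, seq_len(n))
      out
    }

    rrna <- make_substrates("rRNA", n_rrna)
    mito <- make_substrates("mito_genome", 1L, lens = 1200L)
    mrna <- make_substrates("mRNA", n_mrna)
    genome <- make_substrates("chr", 1L, lens = 3000L)

    categories <- list(
      spike_in = Biostrings::DNAStringSet(
        setNames(cp_spike_in_sequence(), "spike_in_cP_RNA")),
      cyto_tRNA = Biostrings::DNAStringSet(trna_seqs),
      rRNA = Biostrings::DNAStringSet(rrna),
      mito = Biostrings::DNAStringSet(mito),
      mRNA = Biostrings::DNAStringSet(mrna),
      genome = Biostrings::DNAStringSet(genome)
    )
    structure(list(categories = categories, trna_annotation = ann,
                   adapter = adapter),
              class = "cp_refs")
  })
}

#' @export
print.cp_refs <- function(x, ...) {
  cat("cp_refs reference bundle\n")
  for (cat_ in names(x$categories)) {
    ss <- x$categories[[cat_]]
    cat(sprintf("  %-10s %3d sequence(s), %6d nt total\n",
                cat_, length(ss), sum(Biostrings::width(ss))))
  }
  invisible(x)
}

# Character vector of reference sequences for one category.
ref_chars <- function(refs, category) {
  ss <- refs$categories[[category]]
  setNames(as.character(ss), names(ss))
}

#' Write a reference bundle to a directory
#'
#' One FASTA per category (`<category>.fa`) plus the tRNA annotation table
#' (`trna_annotation.tsv`, 0-based loop coordinates as documented in
#' [build_toy_references()]).
#'
#' @param refs A `cp_refs` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_bundle <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cat_ in names(refs$categories)) {
    Biostrings::writeXStringSet(refs$categories[[cat_]],
                                file.path(dir, paste0(cat_, ".fa")))
  }
  write.table(refs$trna_annotation,
              file.path(dir, "trna_annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(refs$adapter, file.path(dir, "adapter.txt"))
  invisible(dir)
}

#' Read a reference bundle written by [write_reference_bundle()]
#'
#' @param dir Directory holding `<category>.fa` files and
#'   `trna_annotation.tsv`.
#' @return A `cp_refs` bundle.
#' @export
read_reference_bundle <- function(dir) {
  categories <- lapply(setNames(nm = cp_categories()), function(cat_) {
    path <- file.path(dir, paste0(cat_, ".fa"))
    if (!file.exists(path)) {
      stop("missing reference FASTA: ", path, call. = FALSE)
    }
    read_fasta(path)
  })
  ann <- read.delim(file.path(dir, "trna_annotation.tsv"),
                    stringsAsFactors = FALSE)
  adapter_path <- file.path(dir, "adapter.txt")
  adapter <- if (file.exists(adapter_path)) readLines(adapter_path)[1] else
    cp_default_adapter()
  structure(list(categories = categories, trna_annotation = ann,
                 adapter = adapter),
            class = "cp_refs")
}
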