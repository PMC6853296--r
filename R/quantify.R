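# ---------------------------------------------------------------------------
# Spike-in-normalized abundance and two-condition fold-change analysis.
#
# norm_rpkm = raw_count * 1e9 / (substrate_length_nt * spike_count):
# reads per kilobase of substrate per spike-in-defined library-size unit.
# Multiplying all substrate counts by k at fixed spike scales norm_rpkm by
# k; scaling the whole library (spike included) leaves it unchanged.
# ---------------------------------------------------------------------------

#' Spike-in read count of a library
#'
#' @param assignments A `cp_assignments` data frame (sequential mapping
#'   with `spike_in` as the top-priority category).
#' @return Integer count. Emits a warning when zero (normalization
#'   impossible).
#' @export
count_spike_in <- function(assignments) {
  n <- sum(assignments$category == "spike_in")
  if (n == 0L) {
    warning("no spike-in reads detected: spike-in normalization disabled")
  }
  n
}

#' Per-substrate read counts from assignments
#'
#' @param assignments A `cp_assignments` data frame.
#' @param category Category to count (default `mRNA`, the substrate class
#'   used in the differential comparison).
#' @return Data frame `substrate_id`, `raw_count`.
#' @export
substrate_counts <- function(assignments, category = "mRNA") {
  keep <- assignments$category == category
  tab <- table(assignments$ref_id[keep])
  data.frame(substrate_id = as.character(names(tab) %||% character(0)),
             raw_count = as.integer(tab), stringsAsFactors = FALSE)
}

#' Spike-in-normalized RPKM
#'
#' @param counts Data frame `substrate_id`, `raw_count` (one sample).
#' @param lengths Named numeric vector of substrate lengths in nt.
#' @param spike_count Spike-in read count of the same sample.
#' @param sample_id Sample label recorded in the output.
#'
#' @return Data frame of class `cp_norm_expr`: `sample_id`, `substrate_id`,
#'   `raw_count`, `substrate_length_nt`, `spike_count`, `norm_rpkm`
#'   (NA with a warning when `spike_count` is 0).
#' @export
normalized_rpkm <- function(counts, lengths, spike_count,
                            sample_id = "sample1") {
  stopifnot(is.data.frame(counts),
            all(c("substrate_id", "raw_count") %in% names(counts)))
  len <- unname(lengths[counts$substrate_id])
  if (anyNA(len)) {
    stop("missing length for substrate(s): ",
         paste(counts$substrate_id[is.na(len)], collapse = ", "),
         call. = FALSE)
  }
  if (any(len <= 0)) stop("substrate lengths must be > 0", call. = FALSE)
  if (spike_count <= 0) {
    warning("spike_count is 0: norm_rpkm undefined")
    norm <- rep(NA_real_, nrow(counts))
  } else {
    norm <- counts$raw_count * 1e9 / (len * spike_count)
  }
  out <- data.frame(
    sample_id = rep_len(sample_id, nrow(counts)),
    substrate_id = counts$substrate_id,
    raw_count = counts$raw_count, substrate_length_nt = len,
    spike_count = rep_len(spike_count, nrow(counts)), norm_rpkm = norm,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cp_norm_expr", "data.frame")
  out
}

#' Aggregate replicate samples per substrate
#'
#' Arithmetic mean of the value column across samples, with the standard
#' deviation when two or more samples are present (NA otherwise). Sample
#' order does not affect the result.
#'
#' @param norm A `cp_norm_expr`-style data frame (multiple `sample_id`s)
#'   or any data frame with `substrate_id` and `value_col`.
#' @param value_col Column to aggregate (default `norm_rpkm`).
#'
#' @return Data frame `substrate_id`, `mean`, `sd`, `n_samples`, plus
#'   `mean_raw_count` when a `raw_count` column is present.
#' @export
replicate_aggregate <- function(norm, value_col = "norm_rpkm") {
  stopifnot(value_col %in% names(norm), "substrate_id" %in% names(norm))
  sp <- split(norm, norm$substrate_id)
  out <- lapply(sp, function(d) {
    v <- d[[value_col]]
    data.frame(
      substrate_id = d$substrate_id[1L],
      mean = mean(v),
      sd = if (length(v) >= 2L) sd(v) else NA_real_,
      n_samples = length(v),
      mean_raw_count = if ("raw_count" %in% names(d)) mean(d$raw_count)
        else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# 2-D mode of (x, y) pairs by fixed-width histogram binning; returns the
# centers of the modal bin (ties: first in column-major bin order).
histogram_mode_2d <- function(x, y, bin_width = 0.25) {
  bx <- floor(x / bin_width)
  by <- floor(y / bin_width)
  key <- paste(bx, by, sep = ",")
  tab <- table(key)
  top <- names(tab)[which.max(tab)]
  parts <- as.numeric(strsplit(top, ",", fixed = TRUE)[[1]])
  c(x = (parts[1] + 0.5) * bin_width, y = (parts[2] + 0.5) * bin_width)
}

#' Per-substrate fold changes of cP-RNAs versus their substrate mRNAs
#'
#' For every substrate passing the count filter in both conditions,
#' computes `fc_cp` (condition-2 / condition-1 mean spike-normalized RPKM
#' from cP-RNA-seq) and `fc_mrna` (same ratio of mRNA-seq RPKM), their
#' log2 values, and the modal (log2 `fc_mrna`, log2 `fc_cp`) pair via a
#' fixed-width 2-D histogram — an explicit estimator of the "aggregation
#' point" of the fold-change scatter.
#'
#' @param cp_cond1,cp_cond2 `cp_norm_expr` data frames (one or more
#'   samples each) for conditions 1 and 2.
#' @param mrna_cond1,mrna_cond2 Data frames `substrate_id`, `rpkm` (one or
#'   more samples) of the external mRNA-seq quantification.
#' @param min_count Minimum mean raw cP read count per substrate in each
#'   condition (default 10; guards against unstable ratios).
#' @param bin_width log2 histogram bin width for the modal summary.
#'
#' @return List of class `cp_fold_changes`: `table` (data frame
#'   `substrate_id`, `fc_cp`, `fc_mrna`, `log2_fc_cp`, `log2_fc_mrna`),
#'   `modal_log2_fc_mrna`, `modal_log2_fc_cp`, `n_dropped`.
#' @export
fold_change_table <- function(cp_cond1, cp_cond2, mrna_cond1, mrna_cond2,
                              min_count = 10, bin_width = 0.25) {
  agg1 <- replicate_aggregate(cp_cond1)
  agg2 <- replicate_aggregate(cp_cond2)
  m1 <- replicate_aggregate(mrna_cond1, value_col = "rpkm")
  m2 <- replicate_aggregate(mrna_cond2, value_col = "rpkm")

  ids <- Reduce(intersect, list(agg1$substrate_id, agg2$substrate_id,
                                m1$substrate_id, m2$substrate_id))
  n_candidates <- length(unique(c(agg1$substrate_id, agg2$substrate_id)))
  a1 <- agg1[match(ids, agg1$substrate_id), ]
  a2 <- agg2[match(ids, agg2$substrate_id), ]
  b1 <- m1[match(ids, m1$substrate_id), ]
  b2 <- m2[match(ids, m2$substrate_id), ]

  ok <- a1$mean_raw_count >= min_count & a2$mean_raw_count >= min_count &
    a1$mean > 0 & b1$mean > 0 & !is.na(a1$mean) & !is.na(a2$mean)
  tab <- data.frame(
    substrate_id = ids[ok],
    fc_cp = a2$mean[ok] / a1$mean[ok],
    fc_mrna = b2$mean[ok] / b1$mean[ok],
    stringsAsFactors = FALSE
  )
  tab$log2_fc_cp <- log2(tab$fc_cp)
  tab$log2_fc_mrna <- log2(tab$fc_mrna)
  modal <- if (nrow(tab) > 0) {
    histogram_mode_2d(tab$log2_fc_mrna, tab$log2_fc_cp, bin_width)
  } else c(x = NA_real_, y = NA_real_)
  structure(list(
    table = tab,
    modal_log2_fc_mrna = unname(modal["x"]),
    modal_log2_fc_cp = unname(modal["y"]),
    n_dropped = n_candidates - nrow(tab)
  ), class = "cp_fold_changes")
}

#' @export
print.cp_fold_changes <- function(x, ...) {
  cat(sprintf(
    "cp_fold_changes: %d substrates (%d dropped); modal log2 FC: mRNA %.2f, cP %.2f\n",
    nrow(x$table), x$n_dropped, x$modal_log2_fc_mrna, x$modal_log2_fc_cp))
  invisible(x)
}

#' Quantify a mapped library: spike count plus normalized substrate RPKM
#'
#' @param assignments A `cp_assignments` data frame.
#' @param refs A `cp_refs` bundle (for substrate lengths).
#' @param sample_id Sample label.
#' @param category Substrate category to quantify (default `mRNA`).
#' @return A `cp_norm_expr` data frame.
#' @export
quantify_library <- function(assignments, refs, sample_id = "sample1",
                             category = "mRNA") {
  spike <- count_spike_in(assignments)
  counts <- substrate_counts(assignments, category)
  lengths <- nchar(ref_chars(refs, category))
  normalized_rpkm(counts, lengths, spike, sample_id)
}
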