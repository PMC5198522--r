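#' Per-library size factors (median-of-ratios, per protocol)
#'
#' Sequencing depth differs between libraries and, more drastically,
#' between the RNA-Seq and ribosome-footprint protocols, so size factors
#' are estimated independently within each protocol. For a protocol the
#' reference expression of gene i is the geometric mean of its counts
#' over that protocol's libraries, computed over the genes with strictly
#' positive counts in all of those libraries; the factor of library j is
#' the median over those genes of count[i,j] / reference[i]. Factors are
#' finally rescaled so their geometric mean within each protocol is 1,
#' which makes them identifiable (absolute library scale is absorbed by
#' the protocol terms of the GLM).
#'
#' If a protocol has no gene positive in every library, the reference
#' set is relaxed (with a warning) to genes positive in at least half of
#' the libraries, using the geometric mean over positive entries only.
#'
#' @param counts Count matrix (genes x samples) or a `count_table` /
#'   `joined_dataset`.
#' @param design An `experiment_design` covering the columns.
#' @return Named positive numeric vector of factors, aligned to the
#'   matrix columns.
#' @export
size_factors <- function(counts, design) {
  if (inherits(counts, "joined_dataset")) {
    design <- counts$design
    counts <- counts$counts
  } else if (inherits(counts, "count_table")) {
    counts <- counts$counts
  }
  validate_design(design, colnames(counts))
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  sf <- rep(NA_real_, ncol(counts))
  names(sf) <- colnames(counts)
  for (p in levels(design$protocol)) {
    idx <- which(design$protocol == p)
    if (length(idx) == 0L) next
    sf[idx] <- .sf_protocol(counts[, idx, drop = FALSE], p)
  }
  sf
}

.sf_protocol <- function(m, label) {
  all_pos <- rowSums(m > 0) == ncol(m)
  if (any(all_pos)) {
    sub <- m[all_pos, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    f <- apply(sub / ref, 2L, stats::median)
  } else {
    half_pos <- rowSums(m > 0) >= ncol(m) / 2
    if (!any(half_pos)) {
      stop("no usable reference gene for size factors in protocol ", label,
           ": no gene is positive in at least half of its libraries")
    }
    warning("no gene positive in every ", label,
            " library; relaxing size-factor reference to genes positive in >= 50% of libraries")
    sub <- m[half_pos, , drop = FALSE]
    ref <- exp(apply(sub, 1L, function(r) mean(log(r[r > 0]))))
    f <- apply(sub / ref, 2L, function(col) stats::median(col[col > 0]))
  }
  if (any(!is.finite(f)) || any(f <= 0)) {
    stop("degenerate size factor in protocol ", label)
  }
  f / exp(mean(log(f)))
}

#' Depth-normalized counts
#'
#' Divides each column by its size factor. Normalized counts are used
#' for reporting translation efficiencies and as the abscissa of the
#' mean-dispersion trend; the likelihood itself keeps raw counts and
#' moves the factors into the GLM offset.
#'
#' @param counts Count matrix or `count_table`.
#' @param sf Size factors aligned to the columns.
#' @return Real-valued matrix of the same shape.
#' @export
normalized_counts <- function(counts, sf) {
  if (inherits(counts, "count_table")) counts <- counts$counts
  if (!is.null(names(sf)) && !is.null(colnames(counts))) {
    if (!identical(names(sf), colnames(counts))) {
      sf <- sf[colnames(counts)]
    }
  }
  if (length(sf) != ncol(counts) || any(!is.finite(sf)) || any(sf <= 0)) {
    stop("size factors not aligned to count columns or not positive")
  }
  sweep(counts, 2L, sf, "/")
}
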