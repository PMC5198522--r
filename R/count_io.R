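#' Read a gene-by-sample count table
#'
#' Reads a delimited text file whose first column holds gene identifiers
#' (the header literal of that column is ignored) and whose remaining
#' columns hold non-negative integer read counts, one column per
#' sequencing library.
#'
#' @param path Path to the count file.
#' @param delimiter Field separator, tab by default.
#' @return A `count_table` object: a list with `gene_ids`, `sample_ids`
#'   and an integer `counts` matrix (genes x samples, dimnames set).
#' @export
read_count_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("count file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a gene-id column plus >= 1 sample column")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("malformed count '%s' at gene '%s', sample '%s' (must be a non-negative integer)",
                 raw[bad[1L, 1L], bad[1L, 2L]], gene_ids[bad[1L, 1L]],
                 sample_ids[bad[1L, 2L]]))
  }
  count_table(gene_ids, sample_ids, num)
}

#' Construct a count table
#'
#' @param gene_ids Character vector of unique gene identifiers.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param counts Matrix of non-negative integers, genes x samples.
#' @return A `count_table` object.
#' @export
count_table <- function(gene_ids, sample_ids, counts) {
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene id: ", gene_ids[anyDuplicated(gene_ids)])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id: ", sample_ids[anyDuplicated(sample_ids)])
  }
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(sample_ids)) {
    stop("counts matrix dimensions do not match gene/sample ids")
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be finite non-negative integers")
  }
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(gene_ids = gene_ids, sample_ids = sample_ids, counts = counts),
            class = "count_table")
}

#' Write a count table to a delimited file
#'
#' Inverse of [read_count_table()]: the written file round-trips exactly.
#'
#' @param ct A `count_table`.
#' @param path Output path.
#' @param delimiter Field separator.
#' @export
write_count_table <- function(ct, path, delimiter = "\t") {
  stopifnot(inherits(ct, "count_table"))
  df <- data.frame(geneID = ct$gene_ids, ct$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read an experiment design table
#'
#' The design maps each sequencing library to its protocol (RNA-Seq or
#' ribosome footprint) and condition (control or treatment). Accepts a
#' comma- or tab-separated file with columns `sample_id`, `protocol`
#' (values `RNA` or `RF`) and `condition` (`control` or `treatment`).
#'
#' @param path Path to the design file.
#' @return An `experiment_design` data.frame with columns `sample_id`,
#'   `protocol` (factor: RNASEQ/RIBO) and `condition` (integer 0/1).
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          stringsAsFactors = FALSE, strip.white = TRUE)
  experiment_design(df$sample_id, df$protocol, df$condition)
}

#' Construct and validate an experiment design
#'
#' @param sample_id Character vector of library identifiers.
#' @param protocol `"RNA"`/`"RNASEQ"` or `"RF"`/`"RIBO"` per sample.
#' @param condition `"control"`/`0` or `"treatment"`/`1` per sample.
#' @return An `experiment_design` data.frame.
#' @export
experiment_design <- function(sample_id, protocol, condition) {
  sample_id <- as.character(sample_id)
  if (length(sample_id) == 0L) stop("design is empty")
  if (anyDuplicated(sample_id)) stop("duplicated sample_id in design")
  prot <- toupper(as.character(protocol))
  prot[prot %in% c("RNA", "RNASEQ", "RNA-SEQ", "MRNA")] <- "RNASEQ"
  prot[prot %in% c("RF", "RIBO", "RPF")] <- "RIBO"
  if (!all(prot %in% c("RNASEQ", "RIBO"))) {
    stop("protocol must be one of RNA/RNASEQ or RF/RIBO")
  }
  cond <- tolower(as.character(condition))
  cond[cond %in% c("control", "ctrl", "0")] <- "0"
  cond[cond %in% c("treatment", "treated", "case", "1")] <- "1"
  if (!all(cond %in% c("0", "1"))) {
    stop("condition must be control/0 or treatment/1")
  }
  out <- data.frame(sample_id = sample_id,
                    protocol = factor(prot, levels = c("RNASEQ", "RIBO")),
                    condition = as.integer(cond),
                    stringsAsFactors = FALSE)
  class(out) <- c("experiment_design", "data.frame")
  out
}

#' Write an experiment design to a CSV file
#' @param design An `experiment_design`.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  df <- data.frame(
    sample_id = design$sample_id,
    protocol = ifelse(design$protocol == "RNASEQ", "RNA", "RF"),
    condition = ifelse(design$condition == 0L, "control", "treatment"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Dispersion needs within-group replication: every (protocol, condition)
# group occupied, and at least one group per protocol with >= 2 libraries.
validate_design <- function(design, sample_ids = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  tab <- table(design$protocol, design$condition)
  if (any(dim(tab) < c(2L, 2L)) || any(tab == 0L)) {
    stop("design must occupy all four (protocol, condition) groups")
  }
  for (p in levels(design$protocol)) {
    if (max(tab[p, ]) < 2L) {
      stop("protocol ", p, " needs at least one group with >= 2 replicates ",
           "for dispersion estimation")
    }
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, design$sample_id)
    if (length(missing) > 0L) {
      stop("samples absent from design: ", paste(missing, collapse = ", "))
    }
  }
  invisible(design)
}

#' Join RNA-Seq and ribosome-footprint count tables with a design
#'
#' Restricts to the genes present in both tables (order taken from the
#' RNA-Seq table), binds the two sample blocks into one matrix and flags
#' which genes are testable. A gene is testable only when both the
#' RNA-Seq and the footprint libraries carry at least one read for it;
#' genes with all-zero counts are reported with missing p-values rather
#' than p = 1.
#'
#' @param rna RNA-Seq `count_table`.
#' @param ribo Ribosome-footprint `count_table`.
#' @param design An `experiment_design` covering every sample in both
#'   tables.
#' @return A `joined_dataset`: list with `gene_ids`, `counts` (unified
#'   matrix), `design` (row-aligned to the matrix columns), and logical
#'   flags `testable` and `zero_protocol`.
#' @export
join_datasets <- function(rna, ribo, design) {
  stopifnot(inherits(rna, "count_table"), inherits(ribo, "count_table"))
  validate_design(design, c(rna$sample_ids, ribo$sample_ids))
  if (length(intersect(rna$sample_ids, ribo$sample_ids)) > 0L) {
    stop("RNA-Seq and footprint tables share sample ids; libraries must be distinct")
  }
  genes <- rna$gene_ids[rna$gene_ids %in% ribo$gene_ids]
  if (length(genes) == 0L) stop("no genes shared between the two count tables")
  counts <- cbind(rna$counts[genes, , drop = FALSE],
                  ribo$counts[genes, , drop = FALSE])
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  class(design) <- c("experiment_design", "data.frame")
  is_rna <- design$protocol == "RNASEQ"
  rna_tot <- rowSums(counts[, is_rna, drop = FALSE])
  ribo_tot <- rowSums(counts[, !is_rna, drop = FALSE])
  structure(list(
    gene_ids = genes,
    counts = counts,
    design = design,
    testable = rna_tot > 0 & ribo_tot > 0,
    zero_protocol = (rna_tot == 0) != (ribo_tot == 0)
  ), class = "joined_dataset")
}

#' @export
print.joined_dataset <- function(x, ...) {
  cat(sprintf("joined_dataset: %d genes (%d testable), %d libraries (%d RNA-Seq, %d RF)\n",
              length(x$gene_ids), sum(x$testable), nrow(x$design),
              sum(x$design$protocol == "RNASEQ"), sum(x$design$protocol == "RIBO")))
  invisible(x)
}
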