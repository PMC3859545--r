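#' Gene-level read counting (union semantics)
#'
#' Assigns each read start to the gene whose span contains it: exactly one
#' gene increments that gene's count, overlap of two or more genes counts as
#' `ambiguous`, and a start outside every gene as `no_feature`, so per
#' sample gene totals + ambiguous + no_feature equal the input size. Strand
#' is respected per sample according to the read set's strandedness flags
#' (or the `stranded` argument for all samples).
#'
#' @param reads data.frame of read starts (contig, start 0-based, strand,
#'   sample_id), e.g. from [simulate_read_starts()].
#' @param ann A `genome_annotation`.
#' @param stranded Logical; NULL (default) uses the per-sample `stranded`
#'   attribute of `reads`, FALSE otherwise.
#' @return A list of class `count_matrix`: integer matrix `counts` (genes x
#'   samples), vectors `no_feature`, `ambiguous`, `lib_size` (total input
#'   reads per sample) and `protocol` (if carried by `reads`).
#' @export
count_reads <- function(reads, ann, stranded = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  gt <- gene_table(ann)
  bad <- setdiff(unique(reads$contig), names(ann$contig_lengths))
  if (length(bad))
    stop("read contigs absent from annotation: ", paste(bad, collapse = ", "))
  samples <- unique(reads$sample_id)
  if (is.null(stranded)) {
    sflag <- attr(reads, "stranded")
    if (is.null(sflag)) sflag <- setNames(rep(FALSE, length(samples)), samples)
  } else {
    sflag <- setNames(rep(stranded, length(samples)), samples)
  }
  genes_gr <- GenomicRanges::GRanges(
    seqnames = gt$contig,
    ranges = IRanges::IRanges(start = gt$start, end = gt$end),
    strand = gt$strand)
  names(genes_gr) <- rownames(gt)
  counts <- matrix(0L, nrow(gt), length(samples),
                   dimnames = list(rownames(gt), samples))
  no_feature <- setNames(integer(length(samples)), samples)
  ambiguous <- setNames(integer(length(samples)), samples)
  lib_size <- setNames(integer(length(samples)), samples)
  for (s in samples) {
    r <- reads[reads$sample_id == s, , drop = FALSE]
    lib_size[s] <- nrow(r)
    if (!nrow(r)) next
    r_gr <- GenomicRanges::GRanges(
      seqnames = r$contig,
      ranges = IRanges::IRanges(start = r$start + 1L, width = 1L),
      strand = r$strand)
    hits <- GenomicRanges::findOverlaps(r_gr, genes_gr,
                                        ignore.strand = !isTRUE(sflag[[s]]))
    nh <- tabulate(S4Vectors::queryHits(hits), nbins = length(r_gr))
    no_feature[s] <- sum(nh == 0)
    ambiguous[s] <- sum(nh > 1)
    uniq <- S4Vectors::queryHits(hits) %in% which(nh == 1)
    tab <- table(S4Vectors::subjectHits(hits)[uniq])
    counts[as.integer(names(tab)), s] <- as.integer(tab)
  }
  structure(list(counts = counts, no_feature = no_feature,
                 ambiguous = ambiguous, lib_size = lib_size,
                 protocol = attr(reads, "protocol")),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples; assigned %s reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

.counts_of <- function(x) if (inherits(x, "count_matrix")) x$counts else x

#' Per-contig read distribution
#'
#' Tallies read starts per contig and sample (the mapping-summary view of a
#' read set) and reports the mitochondrial share per sample.
#'
#' @param reads data.frame of read starts.
#' @return A list of class `contig_summary`: matrix `counts` (contigs x
#'   samples), vector `totals` and vector `mt_share`.
#' @export
contig_distribution <- function(reads) {
  if (!nrow(reads)) {
    return(structure(list(
      counts = matrix(0L, 0, 0), totals = integer(0), mt_share = numeric(0)),
      class = "contig_summary"))
  }
  tab <- table(reads$contig, reads$sample_id)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  totals <- colSums(m)
  mt_share <- if ("MT" %in% rownames(m)) m["MT", ] / totals
              else setNames(rep(0, ncol(m)), colnames(m))
  structure(list(counts = m, totals = totals, mt_share = mt_share),
            class = "contig_summary")
}

#' @export
print.contig_summary <- function(x, ...) {
  cat(sprintf("<contig_summary> %d contigs x %d samples; MT share: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%.1f%%", names(x$mt_share),
                            100 * x$mt_share), collapse = " ")))
  invisible(x)
}

.check_lengths <- function(counts, lengths) {
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop("missing gene length for: ", paste(head(missing, 5), collapse = ", "))
  L <- lengths[rownames(counts)]
  if (any(L <= 0)) stop("gene lengths must be > 0")
  L
}

#' Fragments per kilobase per million mapped reads
#'
#' FPKM_ij = counts_ij * 1e9 / (L_i * N_j), the standard length- and
#' depth-normalized expression for uniform-coverage (total RNA) libraries.
#'
#' @param counts `count_matrix` or plain matrix.
#' @param lengths Named per-gene lengths in bp.
#' @param lib_size Per-sample total mapped reads N_j; defaults to the count
#'   matrix's library sizes (or column sums for a plain matrix).
#' @return Matrix of FPKM values with attribute `method = "FPKM"`.
#' @export
compute_fpkm <- function(counts, lengths, lib_size = NULL) {
  m <- .counts_of(counts)
  if (is.null(lib_size)) {
    lib_size <- if (inherits(counts, "count_matrix")) counts$lib_size
                else colSums(m)
  }
  lib_size <- rep(lib_size, length.out = ncol(m))
  if (any(lib_size <= 0)) stop("library sizes must be > 0")
  L <- .check_lengths(m, lengths)
  out <- m * 1e9 / outer(L, lib_size)
  attr(out, "method") <- "FPKM"
  out
}

#' Normalized read counts for oligo-dT libraries
#'
#' NRC_ij = counts_ij * f(L_i, lam) with f the decay-model length correction
#' of [decay_adjustment_factor()] (default: the first-order "paper" factor
#' 1 + exp(-lam * L)). Compensates the capture deficit of short transcripts
#' under 3'-biased coverage without touching sequencing depth.
#'
#' @inheritParams compute_fpkm
#' @param lam Per-bp decay rate.
#' @param mode "paper" or "exact" (see [decay_adjustment_factor()]).
#' @return Matrix of NRC values with attributes `method = "NRC"`, `lam`,
#'   `mode`.
#' @export
compute_nrc <- function(counts, lengths, lam = 0.0027638,
                        mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  m <- .counts_of(counts)
  L <- .check_lengths(m, lengths)
  out <- m * decay_adjustment_factor(L, lam, mode)
  attr(out, "method") <- "NRC"
  attr(out, "lam") <- lam
  attr(out, "mode") <- mode
  out
}

#' Length- and method-adjusted counts across protocols
#'
#' Makes polyA+ and total RNA columns comparable gene-wise: polyA+ columns
#' become NRC (decay-model length correction), totRNA columns are rescaled
#' to reads per kilobase (counts * 1e3 / L; the per-million depth division
#' is deliberately left to the DE stage's size factors to avoid double
#' normalization). All values are rounded to integers (round-half-to-even)
#' for negative-binomial modeling.
#'
#' @inheritParams compute_nrc
#' @param protocol Named per-sample protocol labels ("polyA+" or "totRNA");
#'   defaults to the ones carried by the count matrix.
#' @return Integer-valued matrix with attribute `method = "adjusted"`.
#' @export
protocol_adjust <- function(counts, lengths, lam = 0.0027638,
                            protocol = NULL, mode = c("paper", "exact")) {
  mode <- match.arg(mode)
  m <- .counts_of(counts)
  if (is.null(protocol)) {
    protocol <- if (inherits(counts, "count_matrix")) counts$protocol
                else attr(counts, "protocol")
  }
  if (is.null(protocol) || !all(colnames(m) %in% names(protocol)))
    stop("every sample needs a protocol label")
  protocol <- protocol[colnames(m)]
  if (!all(protocol %in% c("polyA+", "totRNA")))
    stop("unknown protocol label: ",
         paste(setdiff(protocol, c("polyA+", "totRNA")), collapse = ", "))
  L <- .check_lengths(m, lengths)
  out <- m
  pa <- protocol == "polyA+"
  if (any(pa))
    out[, pa] <- compute_nrc(m[, pa, drop = FALSE], lengths, lam, mode)
  if (any(!pa))
    out[, !pa] <- m[, !pa, drop = FALSE] * 1e3 / L
  out <- round(out)
  attr(out, "method") <- "adjusted"
  attr(out, "lam") <- lam
  attr(out, "protocol") <- protocol
  out
}

#' Rank genes by expression
#'
#' Descending sort by row mean (or one sample's values), ties broken by
#' gene id, mitochondrial genes optionally excluded (the "MT-RNA excluded"
#' view of top-expression tables).
#'
#' @param expr Expression matrix with gene rownames.
#' @param top_n Number of rows to keep (>= 1).
#' @param sample Optional sample id to rank by instead of the row mean.
#' @param contig Optional named per-gene contig labels (needed for
#'   `exclude_mt`).
#' @param exclude_mt Drop genes on contig "MT" before ranking.
#' @return data.frame with gene_id, value, rank.
#' @export
rank_table <- function(expr, top_n, sample = NULL, contig = NULL,
                       exclude_mt = FALSE) {
  if (top_n < 1) stop("top_n must be >= 1")
  m <- .counts_of(expr)
  if (exclude_mt) {
    if (is.null(contig)) stop("exclude_mt requires per-gene contig labels")
    m <- m[contig[rownames(m)] != "MT", , drop = FALSE]
  }
  val <- if (is.null(sample)) rowMeans(m) else m[, sample]
  ord <- order(-val, rownames(m))
  out <- data.frame(gene_id = rownames(m)[ord], value = unname(val[ord]),
                    stringsAsFactors = FALSE)
  out <- head(out, top_n)
  out$rank <- seq_len(nrow(out))
  out
}

#' Correlate two expression vectors
#'
#' Pearson or Spearman correlation over the genes detectable (> 0) and
#' finite in both inputs, optionally on log10 scale (zeros are excluded by
#' the detectability filter).
#'
#' @param exprA,exprB Named per-gene expression vectors.
#' @param method "pearson" or "spearman".
#' @param log_transform Correlate log10 values.
#' @return Correlation coefficient with attribute `n` (genes used).
#' @export
correlate_expression <- function(exprA, exprB,
                                 method = c("pearson", "spearman"),
                                 log_transform = FALSE) {
  method <- match.arg(method)
  shared <- intersect(names(exprA), names(exprB))
  a <- exprA[shared]; b <- exprB[shared]
  keep <- is.finite(a) & is.finite(b) & a > 0 & b > 0
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3)
    stop("fewer than 3 shared genes with detectable expression")
  if (log_transform) { a <- log10(a); b <- log10(b) }
  r <- stats::cor(a, b, method = method)
  attr(r, "n") <- length(a)
  r
}
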