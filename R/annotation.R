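#' @importFrom stats rnbinom rpois runif rlnorm median lm coef pnorm setNames
#' @importFrom utils read.delim write.table head
NULL

# GRCh37 chromosome sizes; the toy annotation places genes inside these bounds
# so coordinates look like real Ensembl-style loci.
.CONTIG_LENGTHS <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566,
  "MT" = 16569
)

#' Construct a transcript model
#'
#' A transcript model is the unit of annotation used throughout the package:
#' a single-exon transcript with one or more polyadenylation sites, each with
#' a relative abundance (the fraction of the gene's molecules ending there).
#' Oligo-dT libraries place read starts upstream of these sites with
#' exponentially decaying density, so the polyA sites and their weights fully
#' determine the expected polyA+ coverage shape.
#'
#' @param transcript_id,gene_id,gene_name Identifiers.
#' @param contig Contig name ("1".."22", "X", "Y", "MT").
#' @param strand "+" or "-".
#' @param tx_start,tx_end 1-based inclusive genomic coordinates.
#' @param polya_sites Numeric vector of polyA-site positions in bp from the
#'   transcript 5' end, strictly increasing, each in (leader_len, L].
#' @param site_weights Relative abundances of the polyA sites; normalized to
#'   sum to 1.
#' @param leader_len Length in bp of the 5' adapter leader (the region a
#'   template-switch oligo occupies); read starts never fall inside it.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_name, contig,
                             strand, tx_start, tx_end,
                             polya_sites = NULL, site_weights = NULL,
                             leader_len = 30L) {
  L <- tx_end - tx_start + 1
  if (L <= 0) stop("transcript length must be positive (tx_end >= tx_start)")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (is.null(polya_sites)) polya_sites <- L
  if (is.null(site_weights)) site_weights <- rep(1, length(polya_sites))
  if (length(polya_sites) != length(site_weights))
    stop("polya_sites and site_weights must have equal length")
  if (any(diff(polya_sites) <= 0))
    stop("polyA positions must be strictly increasing")
  if (any(polya_sites <= leader_len) || any(polya_sites > L))
    stop("polyA positions must lie in (leader_len, L]")
  if (any(site_weights < 0) || sum(site_weights) <= 0)
    stop("site weights must be non-negative with positive sum")
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id, gene_name = gene_name,
    contig = as.character(contig), strand = strand,
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    length = as.integer(L),
    polya_sites = as.numeric(polya_sites),
    site_weights = site_weights / sum(site_weights),
    leader_len = as.integer(leader_len),
    mitochondrial = identical(as.character(contig), "MT")
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s/%s) %s:%d-%d(%s) L=%d, %d polyA site(s)\n",
              x$transcript_id, x$gene_id, x$gene_name, x$contig,
              x$tx_start, x$tx_end, x$strand, x$length,
              length(x$polya_sites)))
  invisible(x)
}

#' Bundle transcripts into a genome annotation
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param contig_lengths Named vector of contig lengths; defaults to the
#'   human chromosome sizes used by the generator.
#' @param abundance Optional named per-gene relative abundance (molar scale)
#'   used by the read simulators.
#' @return An object of class `genome_annotation` with a derived
#'   gene -> transcripts map.
#' @export
genome_annotation <- function(transcripts, contig_lengths = .CONTIG_LENGTHS,
                              abundance = NULL) {
  stopifnot(length(transcripts) > 0)
  for (tx in transcripts) {
    if (!inherits(tx, "transcript_model")) stop("all elements must be transcript_model")
    if (!tx$contig %in% names(contig_lengths))
      stop("unknown contig: ", tx$contig)
    if (tx$tx_end > contig_lengths[[tx$contig]] || tx$tx_start < 1)
      stop("transcript ", tx$transcript_id, " outside contig bounds")
  }
  ids <- vapply(transcripts, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript ids")
  names(transcripts) <- ids
  gene_ids <- vapply(transcripts, `[[`, character(1), "gene_id")
  genes <- split(ids, gene_ids)
  structure(list(
    transcripts = transcripts,
    genes = genes,
    contig_lengths = contig_lengths,
    abundance = abundance
  ), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d transcripts, %d genes on %d contigs\n",
              length(x$transcripts), length(x$genes),
              length(unique(vapply(x$transcripts, `[[`, character(1), "contig")))))
  invisible(x)
}

#' Per-gene table of a genome annotation
#'
#' One row per gene using its longest transcript (the length proxy used for
#' FPKM/NRC throughout).
#'
#' @param ann A `genome_annotation`.
#' @return data.frame with gene_id, gene_name, contig, strand, start, end,
#'   length, mitochondrial.
#' @export
gene_table <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  rows <- lapply(names(ann$genes), function(g) {
    txs <- ann$transcripts[ann$genes[[g]]]
    lens <- vapply(txs, `[[`, integer(1), "length")
    tx <- txs[[which.max(lens)]]
    data.frame(gene_id = g, gene_name = tx$gene_name, contig = tx$contig,
               strand = tx$strand,
               start = min(vapply(txs, `[[`, integer(1), "tx_start")),
               end = max(vapply(txs, `[[`, integer(1), "tx_end")),
               length = max(lens), mitochondrial = tx$mitochondrial,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$gene_id
  out
}

.config_error <- function(field, msg) {
  stop(sprintf("invalid simulation config field '%s': %s", field, msg),
       call. = FALSE)
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. The defaults are
#' the study conditions the downstream analyses assume: a per-base decay rate
#' of 0.0027638 (about 50% loss per 250 bp), a polyA+ mitochondrial read
#' share of 0.635 versus roughly 0.09 for rRNA-depleted libraries, one
#' unstranded polyA+ sample against three strand-specific total RNA samples,
#' and negative-binomial replicate noise.
#'
#' @param n_genes Number of genes to generate (>= 1).
#' @param library_size Reads per sample.
#' @param lam Per-bp exponential decay rate of polyA+ read-start density.
#' @param mt_fraction Fraction of polyA+ reads from the MT contig.
#' @param mt_fraction_totrna Fraction of total RNA reads from the MT contig.
#' @param dispersion Negative-binomial dispersion alpha (variance =
#'   mu + alpha * mu^2); 0 gives Poisson counts.
#' @param fold_changes Optional named list: group name -> named vector of
#'   per-gene fold changes (genes not listed have FC = 1).
#' @param leader_len 5' leader length in bp.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 60, library_size = 2e5,
                              lam = 0.0027638, mt_fraction = 0.635,
                              mt_fraction_totrna = 0.09,
                              dispersion = 0.05, fold_changes = NULL,
                              leader_len = 30, seed = 1) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1)
    .config_error("n_genes", "must be a single number >= 1")
  if (!is.numeric(library_size) || any(library_size < 0))
    .config_error("library_size", "must be non-negative")
  if (!is.numeric(lam) || lam <= 0) .config_error("lam", "must be > 0")
  if (mt_fraction < 0 || mt_fraction >= 1)
    .config_error("mt_fraction", "must be in [0, 1)")
  if (mt_fraction_totrna < 0 || mt_fraction_totrna >= 1)
    .config_error("mt_fraction_totrna", "must be in [0, 1)")
  if (any(dispersion < 0)) .config_error("dispersion", "must be >= 0")
  if (leader_len < 0) .config_error("leader_len", "must be >= 0")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    .config_error("seed", "must be a single finite number")
  structure(list(
    n_genes = as.integer(n_genes), library_size = library_size,
    lam = lam, mt_fraction = mt_fraction,
    mt_fraction_totrna = mt_fraction_totrna,
    dispersion = dispersion, fold_changes = fold_changes,
    leader_len = as.integer(leader_len), seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Read the bundled mitochondrial gene count table
#'
#' Per-gene read counts for the 37 mitochondrially encoded genes (13
#' protein-coding, 2 rRNA, 22 tRNA) across the four platelet samples of the
#' study design (S0 = polyA+, S1-S3 = rRNA-depleted total RNA). Used both as
#' an input for mitochondrial read accounting and to give the generated MT
#' annotation realistic loci and abundances.
#'
#' @return data.frame with gene_id, gene_name, locus, length and the four
#'   per-sample count columns.
#' @export
mt_gene_counts <- function() {
  path <- system.file("extdata", "mt_gene_counts.tsv", package = "plateletseq")
  if (path == "") path <- file.path("inst", "extdata", "mt_gene_counts.tsv")
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Summarize mitochondrial read counts
#'
#' Column sums of a per-gene MT count table, with and without the two
#' mitochondrial rRNA genes (MT-RNR1, MT-RNR2) whose polyA+ counts dwarf the
#' rest of the MT pool.
#'
#' @param mt data.frame as returned by [mt_gene_counts()].
#' @return data.frame with rows `sum` and `sum_without_rrna`.
#' @export
summarize_mt_counts <- function(mt = mt_gene_counts()) {
  count_cols <- setdiff(names(mt), c("gene_id", "gene_name", "locus", "length"))
  keep <- !mt$gene_name %in% c("MT-RNR1", "MT-RNR2")
  out <- rbind(
    colSums(mt[, count_cols, drop = FALSE]),
    colSums(mt[keep, count_cols, drop = FALSE])
  )
  out <- as.data.frame(out)
  rownames(out) <- c("sum", "sum_without_rrna")
  out
}

.parse_locus <- function(locus) {
  # "MT:577-647:1" -> contig, start, end, strand
  parts <- strsplit(locus, ":", fixed = TRUE)[[1]]
  coords <- as.integer(strsplit(parts[2], "-", fixed = TRUE)[[1]])
  strand <- if (length(parts) >= 3 && parts[3] == "-1") "-" else "+"
  list(contig = parts[1], start = coords[1], end = coords[2], strand = strand)
}

#' Generate a toy genome annotation
#'
#' Builds a deterministic (seeded) annotation with the structural features
#' the analyses exercise: the 37-gene mitochondrial set (real loci and
#' polyA+ abundance shares, when `n_genes` allows), Y-linked genes absent in
#' female samples, a chemokine-like gene with two polyA sites (proximal at
#' 708 bp and distal at 1307 bp with a 100:1 usage ratio), a long
#' cytoskeletal-like reference gene used for decay fitting, and random
#' single-site nuclear genes with log-uniform lengths between 200 and
#' 10000 bp and log-normal abundances.
#'
#' @param config A [simulation_config()].
#' @param two_site_positions,two_site_weights PolyA sites (bp from 5') and
#'   usage weights of the designated two-site gene.
#' @param structured When FALSE, skip the structured gene set (MT, Y,
#'   two-site and reference genes) and generate only plain random nuclear
#'   genes — the composition used for protocol-bias-only simulations, where
#'   the length bias must be the sole systematic difference between
#'   libraries.
#' @return A `genome_annotation`; per-gene relative abundances are stored in
#'   its `abundance` field.
#' @export
generate_annotation <- function(config = simulation_config(),
                                two_site_positions = c(708, 1307),
                                two_site_weights = c(100, 1) / 101,
                                structured = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  leader <- config$leader_len
  withr::with_seed(config$seed, {
    txs <- list()
    abundance <- numeric(0)

    use_mt37 <- structured && n >= 45
    mt <- mt_gene_counts()
    if (use_mt37) {
      for (i in seq_len(nrow(mt))) {
        loc <- .parse_locus(mt$locus[i])
        txs[[length(txs) + 1L]] <- transcript_model(
          transcript_id = paste0(mt$gene_id[i], ".t1"),
          gene_id = mt$gene_id[i], gene_name = mt$gene_name[i],
          contig = loc$contig, strand = loc$strand,
          tx_start = loc$start, tx_end = loc$start + mt$length[i] - 1,
          leader_len = min(leader, mt$length[i] - 1L))
        abundance[mt$gene_id[i]] <- mt$S0[i] / sum(mt$S0)
      }
      n_mt <- nrow(mt)
    } else if (!structured) {
      n_mt <- 0L
    } else {
      for (i in 1:2) {
        start <- 600 + (i - 1) * 2000
        txs[[length(txs) + 1L]] <- transcript_model(
          transcript_id = sprintf("MTG%d.t1", i),
          gene_id = sprintf("MTG%d", i), gene_name = sprintf("MT-G%d", i),
          contig = "MT", strand = "+",
          tx_start = start, tx_end = start + 999, leader_len = leader)
        abundance[sprintf("MTG%d", i)] <- 0.5
      }
      n_mt <- 2L
    }
    # normalize MT abundances internally; protocol-level MT share is applied
    # at read-allocation time
    mt_ids <- names(abundance)
    if (length(mt_ids))
      abundance[mt_ids] <- abundance[mt_ids] / sum(abundance[mt_ids])

    specials <- if (!structured) list() else list(
      list(gene = "PPBP", contig = "4", start = 74852754,
           len = max(two_site_positions),
           sites = two_site_positions, w = two_site_weights, mu = 8),
      list(gene = "ACTB", contig = "7", start = 5566781, len = 1852,
           sites = NULL, w = NULL, mu = 4),
      list(gene = "UTY", contig = "Y", start = 15360259, len = 2100,
           sites = NULL, w = NULL, mu = 0.4),
      list(gene = "DDX3Y", contig = "Y", start = 15016019, len = 1600,
           sites = NULL, w = NULL, mu = 0.3)
    )
    for (sp in specials) {
      txs[[length(txs) + 1L]] <- transcript_model(
        transcript_id = paste0(sp$gene, ".t1"), gene_id = sp$gene,
        gene_name = sp$gene, contig = sp$contig, strand = "+",
        tx_start = sp$start, tx_end = sp$start + sp$len - 1,
        polya_sites = sp$sites, site_weights = sp$w, leader_len = leader)
      abundance[sp$gene] <- sp$mu
    }

    n_random <- n - n_mt - length(specials)
    if (n_random < 0)
      .config_error("n_genes", sprintf(
        "must be >= %d to hold the structured gene set", n_mt + length(specials)))
    if (n_random > 0) {
      contigs <- sample(c(as.character(1:22), "X"), n_random, replace = TRUE)
      lens <- round(exp(runif(n_random, log(200), log(10000))))
      offsets <- stats::ave(seq_len(n_random), contigs, FUN = seq_along)
      for (i in seq_len(n_random)) {
        gid <- sprintf("GENE%03d", i)
        start <- 1e6 + (offsets[i] - 1) * 2e4
        txs[[length(txs) + 1L]] <- transcript_model(
          transcript_id = paste0(gid, ".t1"), gene_id = gid, gene_name = gid,
          contig = contigs[i], strand = sample(c("+", "-"), 1),
          tx_start = start, tx_end = start + lens[i] - 1,
          leader_len = min(leader, lens[i] - 1L))
        abundance[gid] <- rlnorm(1, meanlog = 0, sdlog = 1.5)
      }
    }
    genome_annotation(txs, abundance = abundance)
  })
}

#' Write an annotation as Ensembl-style GTF
#'
#' Emits gene, transcript and exon features (one exon per transcript) with
#' `gene_id`, `gene_name` and `transcript_id` attributes, 1-based inclusive
#' coordinates.
#'
#' @param ann A `genome_annotation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "genome_annotation"))
  lines <- character(0)
  gt <- gene_table(ann)
  for (g in rownames(gt)) {
    lines <- c(lines, sprintf(
      '%s\tplateletseq\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
      gt[g, "contig"], gt[g, "start"], gt[g, "end"], gt[g, "strand"],
      g, gt[g, "gene_name"]))
    for (tid in ann$genes[[g]]) {
      tx <- ann$transcripts[[tid]]
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                          g, tid, tx$gene_name)
      lines <- c(lines, sprintf(
        "%s\tplateletseq\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
        tx$contig, tx$tx_start, tx$tx_end, tx$strand, attr_str))
      lines <- c(lines, sprintf(
        "%s\tplateletseq\texon\t%d\t%d\t.\t%s\t.\t%s",
        tx$contig, tx$tx_start, tx$tx_end, tx$strand, attr_str))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
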