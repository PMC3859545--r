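.with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# per-position sampling probabilities of the decay mixture over polyA sites
.polya_position_probs <- function(tx, lam) {
  L <- tx$length
  p <- numeric(L)
  for (k in seq_along(tx$polya_sites)) {
    s <- tx$polya_sites[k]
    support <- (tx$leader_len + 1):s
    dens <- exp(-lam * (s - support))
    p[support] <- p[support] + tx$site_weights[k] * dens / sum(dens)
  }
  p
}

#' Simulate oligo-dT read starts along one transcript
#'
#' Draws read-start positions from a mixture over the transcript's polyA
#' sites: a read from the isoform ending at site s starts at distance u
#' upstream of s with probability proportional to exp(-lam * u), truncated
#' (and renormalized) at the 5' leader boundary so totals are exact.
#'
#' @param tx A [transcript_model()] (must have at least one polyA site).
#' @param n_reads Number of read starts to draw (>= 0).
#' @param lam Per-bp decay rate (> 0).
#' @param seed Optional seed; the draw is a pure function of (tx, n_reads,
#'   lam, seed).
#' @return A `coverage_profile` of per-position counts summing to `n_reads`.
#' @export
simulate_polya_profile <- function(tx, n_reads, lam = 0.0027638, seed = NULL) {
  stopifnot(inherits(tx, "transcript_model"))
  if (length(tx$polya_sites) == 0) stop("transcript has no polyA sites")
  if (n_reads < 0) stop("n_reads must be >= 0")
  if (lam <= 0) stop("lam must be > 0")
  counts <- numeric(tx$length)
  if (n_reads > 0) {
    p <- .polya_position_probs(tx, lam)
    counts <- .with_opt_seed(seed,
      as.numeric(stats::rmultinom(1, size = n_reads, prob = p)))
  }
  coverage_profile(counts, tx$transcript_id)
}

#' Simulate uniform read starts along one transcript
#'
#' The total RNA (rRNA-depleted) counterpart of
#' [simulate_polya_profile()]: start density is uniform over the whole
#' transcript.
#'
#' @inheritParams simulate_polya_profile
#' @return A `coverage_profile` of per-position counts summing to `n_reads`.
#' @export
simulate_uniform_profile <- function(tx, n_reads, seed = NULL) {
  stopifnot(inherits(tx, "transcript_model"))
  if (n_reads < 0) stop("n_reads must be >= 0")
  counts <- numeric(tx$length)
  if (n_reads > 0) {
    counts <- .with_opt_seed(seed,
      as.numeric(stats::rmultinom(1, size = n_reads,
                                  prob = rep(1, tx$length))))
  }
  coverage_profile(counts, tx$transcript_id)
}

#' Default four-sample study design
#'
#' One unstranded polyA+ sample (S0, male) and three strand-specific
#' rRNA-depleted total RNA samples (S1 male, S2 female, S3 male).
#'
#' @return data.frame with sample_id, protocol, sex, stranded.
#' @export
default_design <- function() {
  data.frame(
    sample_id = c("S0", "S1", "S2", "S3"),
    protocol = c("polyA+", "totRNA", "totRNA", "totRNA"),
    sex = c("M", "M", "F", "M"),
    stranded = c(FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# expected relative read share per gene for a protocol:
# polyA+ reads are proportional to molar abundance times the captured decay
# mass; total RNA reads to molar abundance times length. MT genes are then
# rescaled to the protocol's mitochondrial share, and Y genes zeroed for
# female samples.
.gene_weights <- function(ann, protocol, lam, mt_fraction, sex = "M") {
  gt <- gene_table(ann)
  mu <- ann$abundance[rownames(gt)]
  if (is.null(mu)) mu <- setNames(rep(1, nrow(gt)), rownames(gt))
  w <- if (protocol == "polyA+") {
    mu * (1 - exp(-lam * gt$length))
  } else if (protocol == "totRNA") {
    mu * gt$length
  } else stop("unknown protocol label: ", protocol)
  if (sex == "F") w[gt$contig == "Y"] <- 0
  is_mt <- gt$mitochondrial
  if (any(is_mt) && any(!is_mt) && sum(w[is_mt]) > 0) {
    w[is_mt] <- w[is_mt] / sum(w[is_mt]) * mt_fraction
    w[!is_mt] <- w[!is_mt] / sum(w[!is_mt]) * (1 - mt_fraction)
  }
  w / sum(w)
}

#' Simulate genomic read starts for a whole design
#'
#' Allocates each sample's library multinomially across genes (protocol- and
#' sex-aware expected shares, mitochondrial share per protocol), draws
#' per-transcript read-start positions with the decay model (polyA+) or
#' uniformly (totRNA), and maps transcript positions to genomic
#' coordinates. totRNA reads carry the transcript strand (strand-specific
#' library); polyA+ read strands are random.
#'
#' @param ann A `genome_annotation` (gene abundances in its `abundance`
#'   field).
#' @param config A [simulation_config()]; `library_size` may be a single
#'   value or one per sample.
#' @param design Sample sheet as in [default_design()].
#' @return data.frame of read starts with columns contig, start (0-based),
#'   strand, sample_id; sample protocols are attached as attribute
#'   `protocol`.
#' @export
simulate_read_starts <- function(ann, config = simulation_config(),
                                 design = default_design()) {
  stopifnot(inherits(ann, "genome_annotation"))
  stopifnot(inherits(config, "simulation_config"))
  if (!all(design$protocol %in% c("polyA+", "totRNA")))
    stop("unknown protocol label: ",
         paste(setdiff(design$protocol, c("polyA+", "totRNA")), collapse = ", "))
  lib <- rep(config$library_size, length.out = nrow(design))
  gt <- gene_table(ann)
  out <- vector("list", nrow(design))
  withr::with_seed(config$seed, {
    for (j in seq_len(nrow(design))) {
      prot <- design$protocol[j]
      sex <- if ("sex" %in% names(design)) design$sex[j] else "M"
      mtf <- if (prot == "polyA+") config$mt_fraction else config$mt_fraction_totrna
      w <- .gene_weights(ann, prot, config$lam, mtf, sex)
      # planted fold changes perturb the sample's expected read shares
      # (keyed on group, else sex, else protocol; renormalized)
      grp <- if ("group" %in% names(design)) as.character(design$group[j])
             else if ("sex" %in% names(design)) sex else prot
      if (!is.null(config$fold_changes) && grp %in% names(config$fold_changes)) {
        v <- config$fold_changes[[grp]]
        idx <- match(names(v), names(w))
        w[idx[!is.na(idx)]] <- w[idx[!is.na(idx)]] * v[!is.na(idx)]
        w <- w / sum(w)
      }
      n_per_gene <- as.integer(stats::rmultinom(1, size = lib[j], prob = w))
      names(n_per_gene) <- names(w)
      recs <- vector("list", length(n_per_gene))
      for (g in names(n_per_gene)) {
        n <- n_per_gene[[g]]
        if (n == 0) next
        tx <- ann$transcripts[[ann$genes[[g]][1]]]
        prof <- if (prot == "polyA+") {
          simulate_polya_profile(tx, n, config$lam)
        } else {
          simulate_uniform_profile(tx, n)
        }
        tp <- rep.int(seq_along(prof$values), prof$values)
        genomic <- if (tx$strand == "+") tx$tx_start + tp - 1L
                   else tx$tx_end - tp + 1L
        strand <- if (prot == "totRNA") rep(tx$strand, n)
                  else sample(c("+", "-"), n, replace = TRUE)
        recs[[g]] <- data.frame(contig = tx$contig, start = genomic - 1L,
                                strand = strand,
                                sample_id = design$sample_id[j],
                                stringsAsFactors = FALSE)
      }
      out[[j]] <- do.call(rbind, recs)
    }
  })
  reads <- do.call(rbind, out)
  if (is.null(reads))
    reads <- data.frame(contig = character(0), start = integer(0),
                        strand = character(0), sample_id = character(0))
  rownames(reads) <- NULL
  attr(reads, "protocol") <- setNames(design$protocol, design$sample_id)
  attr(reads, "stranded") <- setNames(design$protocol == "totRNA",
                                      design$sample_id)
  reads
}

#' Write read starts as BED6
#'
#' One record per read start (chrom, start, start+1); the name column
#' carries the sample id, score is 0. A `track` header line is always
#' written, so an empty read set yields a header-only file.
#'
#' @param reads data.frame from [simulate_read_starts()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_read_bed <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('track name="read_starts" description="simulated read starts"', con)
  if (nrow(reads)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", reads$contig, reads$start,
                     reads$start + 1L, reads$sample_id, reads$strand)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Simulate a negative-binomial count matrix
#'
#' Draws gene-by-sample counts with NB(mean = s_j * mu_i * FC_i(group),
#' variance = mu + alpha * mu^2); dispersion 0 gives Poisson draws. Per-gene
#' means derive from the annotation's abundances scaled to the library size,
#' or can be supplied directly. Fold changes come from
#' `config$fold_changes` (a named list group -> named per-gene FC vector);
#' unlisted genes are null (FC = 1). Y-linked genes get mean 0 in samples
#' with sex "F". When the design carries a `protocol` column, per-gene means
#' follow the protocol's expected read shares (decay-captured mass for
#' polyA+, length-proportional for totRNA), which is how protocol-bias-only
#' datasets are produced.
#'
#' @param ann A `genome_annotation`, or NULL when `mu` is given.
#' @param design data.frame with sample_id, group and optional protocol,
#'   sex, size_factor columns (>= 2 samples).
#' @param config A [simulation_config()] (dispersion may be a single alpha
#'   or a named per-gene vector).
#' @param mu Optional named per-gene baseline means overriding the
#'   annotation-derived ones.
#' @return Integer matrix (genes x samples) with attributes `protocol` and
#'   `group`.
#' @export
simulate_counts <- function(ann, design, config = simulation_config(),
                            mu = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(design) < 2) stop("at least 2 samples required")
  if (is.null(mu)) {
    stopifnot(inherits(ann, "genome_annotation"))
    gt <- gene_table(ann)
    base <- ann$abundance[rownames(gt)]
  } else {
    base <- mu
    gt <- if (!is.null(ann)) gene_table(ann) else NULL
  }
  if (any(base < 0)) stop("negative per-gene mean")
  genes <- names(base)
  alpha <- config$dispersion
  if (length(alpha) == 1) alpha <- setNames(rep(alpha, length(genes)), genes)
  alpha <- alpha[genes]
  if (any(is.na(alpha)) || any(alpha < 0)) stop("negative or missing dispersion")
  sf <- if ("size_factor" %in% names(design)) design$size_factor
        else rep(1, nrow(design))
  lib <- rep(config$library_size, length.out = nrow(design))
  counts <- matrix(0L, length(genes), nrow(design),
                   dimnames = list(genes, design$sample_id))
  withr::with_seed(config$seed, {
    for (j in seq_len(nrow(design))) {
      m <- base
      if (!is.null(gt) && "protocol" %in% names(design)) {
        prot <- design$protocol[j]
        mtf <- if (prot == "polyA+") config$mt_fraction else config$mt_fraction_totrna
        sex <- if ("sex" %in% names(design)) design$sex[j] else "M"
        m <- .gene_weights(ann, prot, config$lam, mtf, sex)[genes]
      } else {
        m <- m / sum(m)
        if (!is.null(gt) && "sex" %in% names(design) && design$sex[j] == "F")
          m[gt[genes, "contig"] == "Y"] <- 0
      }
      m <- m * lib[j]
      fc <- rep(1, length(genes))
      grp <- as.character(design$group[j])
      if (!is.null(config$fold_changes) && grp %in% names(config$fold_changes)) {
        v <- config$fold_changes[[grp]]
        idx <- match(names(v), genes)
        fc[idx[!is.na(idx)]] <- v[!is.na(idx)]
      }
      m <- m * fc * sf[j]
      pois <- alpha == 0 | m == 0
      k <- integer(length(genes))
      if (any(pois)) k[pois] <- rpois(sum(pois), m[pois])
      if (any(!pois)) k[!pois] <- rnbinom(sum(!pois), mu = m[!pois],
                                          size = 1 / alpha[!pois])
      counts[, j] <- k
    }
  })
  attr(counts, "protocol") <- if ("protocol" %in% names(design))
    setNames(design$protocol, design$sample_id) else NULL
  attr(counts, "group") <- setNames(as.character(design$group),
                                    design$sample_id)
  counts
}

#' Write a count or expression matrix as TSV
#'
#' Genes in rows (first column `gene_id`), samples in columns.
#'
#' @param mat Matrix with gene rownames and sample colnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_count_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
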