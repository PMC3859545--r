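# small deterministic fixtures shared across test files

toy_transcript <- function(L = 2000, sites = NULL, weights = NULL,
                           leader = 30, strand = "+", contig = "1",
                           id = "TX1", gene = "G1") {
  transcript_model(paste0(id, ".t1"), gene, gene, contig, strand,
                   tx_start = 1000, tx_end = 1000 + L - 1,
                   polya_sites = sites, site_weights = weights,
                   leader_len = leader)
}

# two genes on contig "1": G1 spans 1000-1999, G2 spans 1500-2499 (overlap
# 1500-1999); G3 alone on contig "2"
toy_overlap_annotation <- function() {
  t1 <- transcript_model("G1.t1", "G1", "G1", "1", "+", 1000, 1999)
  t2 <- transcript_model("G2.t1", "G2", "G2", "1", "+", 1500, 2499)
  t3 <- transcript_model("G3.t1", "G3", "G3", "2", "-", 5000, 5999)
  genome_annotation(list(t1, t2, t3))
}

read_row <- function(contig, start0, strand = "+", sample = "S") {
  data.frame(contig = contig, start = start0, strand = strand,
             sample_id = sample, stringsAsFactors = FALSE)
}

# brute-force Benjamini-Hochberg step-up, straight from the definition:
# find the largest k with p_(k) <= k/n * q by scanning all thresholds
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running_min <- Inf
  for (i in n:1) {
    running_min <- min(running_min, p[o[i]] * n / i)
    adj[o[i]] <- min(running_min, 1)
  }
  adj
}
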