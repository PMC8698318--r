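# Shared fixtures and independent oracles, built in code.

# Six-gene DEG table: five genes each violating exactly one filter rule plus
# one clean gene.
toy_deg_table <- function() {
  base <- function(gene) data.frame(
    gene = gene, mean_tpm_test = 50, mean_tpm_ref = 10,
    log2fc = 2.3, pvalue = 0.001, padj = 0.01,
    rel_sem_test = 0.1, rel_sem_ref = 0.1,
    lfc_donor1 = 2.0, lfc_donor2 = 2.5, lfc_donor3 = 2.2,
    sig_donor1 = TRUE, sig_donor2 = TRUE, sig_donor3 = TRUE)
  clean <- base("clean")
  v_sig <- base("v_sig"); v_sig$pvalue <- 0.2; v_sig$padj <- 0.5
  v_tpm <- base("v_tpm"); v_tpm$mean_tpm_test <- 1.9; v_tpm$mean_tpm_ref <- 1.5
  v_fc <- base("v_fc"); v_fc$log2fc <- 0.5
  v_fc$lfc_donor1 <- v_fc$lfc_donor2 <- v_fc$lfc_donor3 <- 0.5
  v_sem <- base("v_sem"); v_sem$rel_sem_test <- 0.8
  v_donor <- base("v_donor")
  v_donor$sig_donor2 <- FALSE; v_donor$sig_donor3 <- FALSE
  rbind(clean, v_sig, v_tpm, v_fc, v_sem, v_donor)
}

# Upper-tail hypergeometric probability by enumeration over the draw
# composition (counts of successes i = k..min(K, n) in the draw), computed
# with exact binomial coefficients. Independent of phyper.
hyper_tail_enum <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Brute-force Benjamini-Hochberg step-up adjustment:
# adj_i = min(1, min over j with p_j >= p_i of p_j * m / rank_j).
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    js <- which(r >= r[i])
    min(1, min(p[js] * m / r[js]))
  }, 0)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Regulon recovery metrics against the expression generator's ground truth.
recovery_metrics <- function(regulons, truth) {
  rec <- vapply(regulons, `[[`, "", "regulator")
  planted <- names(truth)
  jac <- vapply(planted, function(tf) {
    i <- match(tf, rec)
    if (is.na(i)) return(0)
    jaccard(truth[[tf]]$targets, regulons[[i]]$targets)
  }, 0)
  dir_ok <- vapply(seq_along(regulons), function(i) {
    tf <- rec[i]
    !tf %in% planted || regulons[[i]]$direction == truth[[tf]]$direction
  }, TRUE)
  list(precision = mean(rec %in% planted),
       recall = mean(planted %in% rec),
       mean_jaccard = mean(jac),
       directions_ok = all(dir_ok))
}

# Full transcriptomic path: simulate -> filter -> z-score -> partition ->
# infer regulons. Simulated TPM values are strictly positive, so log2 needs
# no pseudocount.
run_regulon_pipeline <- function(config) {
  sim <- simulate_expression(config)
  resp <- call_response_genes(sim$de[[1]])
  z <- zscore_genes(log2(sim$tpm))
  parts <- lapply(c(up = "up", down = "down"), function(d) {
    g <- intersect(resp$gene[resp$direction == d], rownames(z))
    if (length(g) >= 4) select_partition(z[g, , drop = FALSE]) else NULL
  })
  regulons <- infer_regulons(z, parts$up, parts$down, sim$prior,
                             timepoints = sim$timepoints)
  list(sim = sim, response = resp, z = z, parts = parts, regulons = regulons)
}
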