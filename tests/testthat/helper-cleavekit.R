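# Shared fixtures and independent oracles for the test suite.

# registry fixture, loaded once per session
the <- new.env()
test_registry <- function() {
  if (is.null(the$registry)) the$registry <- example_registry()
  the$registry
}

proglucagon_seq <- function() precursor_sequence(test_registry(), "P01275")

# write a small FASTA and return its path
write_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(entries), function(h)
    c(paste0(">", h), entries[[h]]))), path)
  path
}

# independent dibasic-cleavage oracle: scan residue pairs directly
oracle_digest <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  L <- length(ch)
  cuts <- integer()
  for (i in 2:max(2, L - 1)) {
    if (i < L && ch[i] %in% c("K", "R") && ch[i - 1] %in% c("K", "R"))
      cuts <- c(cuts, i)
  }
  bounds <- c(0, cuts, L)
  substring(sequence, head(bounds, -1) + 1, bounds[-1])
}

# independent carboxypeptidase-chain oracle via regex stripping
oracle_trim_chain <- function(peptide) {
  chain <- peptide
  while (TRUE) {
    cur <- chain[length(chain)]
    if (nchar(cur) <= 1 || !grepl("[KR]$", cur)) break
    chain <- c(chain, substr(cur, 1, nchar(cur) - 1))
  }
  chain
}

# brute-force average-linkage agglomeration on a distance matrix
oracle_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# exhaustive hypergeometric two-sided Fisher p for a 2x2 table
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# small quant table around an explicit matrix
make_qt <- function(mat, genotype = rep(c("WT", "KO"), each = ncol(mat) / 2),
                    sequences = NULL, modifications = NULL,
                    replicates_per_clone = 3) {
  n <- ncol(mat)
  clone <- paste0(genotype, "-c",
                  ave(seq_len(n), genotype, FUN = function(ix)
                    (seq_along(ix) - 1) %/% replicates_per_clone + 1))
  rep_id <- ave(seq_len(n), clone, FUN = seq_along)
  samples <- data.frame(sample_id = paste0("s", seq_len(n)), clone_id = clone,
                        genotype = genotype, bmp = "minus", replicate = rep_id,
                        stringsAsFactors = FALSE)
  peptides <- data.frame(
    sequence = sequences %||% replicate(nrow(mat), paste(
      sample(strsplit("ACDEFGHILMNQSTVWY", "")[[1]], 10, TRUE), collapse = "")),
    modifications = modifications %||% rep("", nrow(mat)),
    stringsAsFactors = FALSE)
  quant_table(mat, peptides, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# planted substrate/product dipeptide pairs straight from a truth table
planted_pairs <- function(truth) {
  find_dipeptide_pairs(data.frame(
    sequence = truth$sequence,
    modifications = ifelse(truth$amidated, "amidated_C_term", ""),
    accession = truth$accession, start = truth$start, end = truth$end,
    stringsAsFactors = FALSE))
}

pair_key <- function(p) paste(p$accession, p$long_sequence, p$short_sequence)

# independent envelope oracle: closed-form binomial for the two-isotope
# elements, explicit repeated full convolution for O and S
oracle_envelope <- function(comp, n = 5) {
  full_conv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) out[i:(i + length(b) - 1)] <-
        out[i:(i + length(b) - 1)] + a[i] * b
    out
  }
  ab <- list(C = c(0.9893, 0.0107), H = c(0.999885, 0.000115),
             N = c(0.99636, 0.00364), O = c(0.99757, 0.00038, 0.00205),
             S = c(0.9499, 0.0075, 0.0425, 0, 0.0001))
  env <- 1
  for (el in c("C", "H", "N")) {
    cnt <- comp[el]
    if (is.na(cnt) || cnt == 0) next
    p <- ab[[el]][2] / sum(ab[[el]])
    env <- full_conv(env, stats::dbinom(0:cnt, cnt, p))
  }
  for (el in c("O", "S")) {
    cnt <- comp[el]
    if (is.na(cnt) || cnt == 0) next
    d <- ab[[el]] / sum(ab[[el]])
    acc <- 1
    for (k in seq_len(cnt)) acc <- full_conv(acc, d)
    env <- full_conv(env, acc)
  }
  env <- env[seq_len(n)]
  env / sum(env)
}
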