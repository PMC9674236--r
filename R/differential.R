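# Knockout-vs-wildtype differential statistics. Pipeline order is fixed:
# replicate filter -> log2 -> down-shifted imputation -> pooled-variance t and
# permutation q-values -> z-scaling / hierarchical clustering.

#' Log2-transform a quantification table or matrix
#'
#' @param x A \code{quant_table} or numeric matrix with positive values
#'   (\code{NA} preserved). Zeros or negatives are an error: non-detections
#'   must be encoded as missing upstream.
#' @return Same shape as the input, log2 scale.
#' @export
log2_transform <- function(x) {
  mat <- if (inherits(x, "quant_table")) x$abundance else x
  if (any(mat <= 0, na.rm = TRUE))
    stopf("log2_transform requires strictly positive values; encode non-detections as missing")
  out <- log2(mat)
  if (inherits(x, "quant_table")) {
    x$abundance <- out
    x
  } else out
}

#' Imputation parameters for left-shifted missing-value replacement
#'
#' @param downshift Shift of the imputation distribution below the sample
#'   mean, in units of the per-sample standard deviation.
#' @param width Standard deviation of the imputation distribution as a
#'   fraction of the per-sample standard deviation (> 0).
#' @param seed Integer seed.
#' @return List of class \code{imputation_params}.
#' @export
imputation_params <- function(downshift = 1.8, width = 0.3, seed = 1L) {
  if (width <= 0) stopf("width must be > 0")
  structure(list(downshift = downshift, width = width, seed = as.integer(seed)),
            class = "imputation_params")
}

#' Impute missing values from a down-shifted per-sample normal
#'
#' Each missing cell of a log2 matrix is drawn from
#' Normal(mean_s - downshift * sd_s, (width * sd_s)^2), where mean_s and sd_s
#' are the observed mean and sd of that sample (column). Deterministic given
#' the seed; observed cells are untouched.
#'
#' @param mat Log2 matrix with \code{NA} for missing values; every column
#'   needs >= 2 observed values.
#' @param params An \code{\link{imputation_params}}.
#' @return Complete numeric matrix.
#' @export
impute_leftshift <- function(mat, params = imputation_params()) {
  bad <- colSums(!is.na(mat)) < 2
  if (any(bad))
    stopf("column(s) with < 2 observed values cannot be imputed: %s",
          paste(colnames(mat)[bad] %||% which(bad), collapse = ", "))
  withr::with_seed(params$seed, {
    for (j in seq_len(ncol(mat))) {
      miss <- is.na(mat[, j])
      if (!any(miss)) next
      m <- mean(mat[, j], na.rm = TRUE)
      s <- stats::sd(mat[, j], na.rm = TRUE)
      mat[miss, j] <- stats::rnorm(sum(miss), m - params$downshift * s,
                                   params$width * s)
    }
    mat
  })
}

#' Two-sample pooled-variance Student's t test
#'
#' Classical equal-variance t with df = nA + nB - 2 and a two-sided p-value.
#' With zero pooled variance: equal means give t = 0, p = 1; unequal means
#' give an infinite t, p = 0, flagged degenerate.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return List with \code{t}, \code{p}, \code{df}, \code{degenerate}.
#' @export
student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stopf("each group needs >= 2 values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  d <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (d == 0) return(list(t = 0, p = 1, df = df, degenerate = FALSE))
    return(list(t = sign(d) * Inf, p = 0, df = df, degenerate = TRUE))
  }
  t <- d / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, degenerate = FALSE)
}

# vectorized row-wise pooled t for a matrix; idxA/idxB are column indices
row_t_stats <- function(mat, idxA, idxB) {
  na <- length(idxA); nb <- length(idxB)
  A <- mat[, idxA, drop = FALSE]; B <- mat[, idxB, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (na - 1)
  vB <- rowSums((B - mB)^2) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * vA + (nb - 1) * vB) / df
  d <- mA - mB
  t <- ifelse(sp2 > 0, d / sqrt(sp2 * (1 / na + 1 / nb)),
              ifelse(d == 0, 0, sign(d) * Inf))
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df), ifelse(t == 0, 1, 0))
  list(t = t, p = p, df = df, mean_a = mA, mean_b = mB, log2fc = d)
}

# distinct two-group label splits as a matrix of group-A column indices
# (k = group size); exhaustive when feasible, else distinct random draws.
make_splits <- function(n, k, n_perm) {
  total <- choose(n, k)
  if (total <= max(5e5, n_perm)) {
    all_splits <- utils::combn(n, k)
    if (total <= n_perm) {
      warning(sprintf("only %d distinct label splits exist; enumerating all of them",
                      total))
      return(all_splits)
    }
    return(all_splits[, sample.int(total, n_perm), drop = FALSE])
  }
  seen <- new.env(hash = TRUE)
  out <- matrix(0L, k, n_perm)
  got <- 0L
  while (got < n_perm) {
    cand <- sort(sample.int(n, k))
    key <- paste(cand, collapse = ",")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    got <- got + 1L
    out[, got] <- cand
  }
  out
}

#' Permutation-based q-values for a two-group comparison
#'
#' Sample labels are permuted globally (the same split applied to all
#' peptides); null |t| values are pooled across peptides. For peptide i with
#' observed |t_i|, the q-value is the pooled-null FDR estimate
#' \deqn{q_i = [mean over permutations of \#\{null |t| \ge |t_i|\}] /
#'       \#\{observed |t| \ge |t_i|\},}
#' clipped to [0, 1] and made monotone non-increasing in |t| by BH-style
#' suffix minimization. Counting is inclusive on both sides (deterministic tie
#' handling). Distinct label splits are drawn without replacement; when fewer
#' than \code{n_perm} exist they are enumerated exhaustively with a warning.
#' Per-peptide permutation p-values (each row against its own null) are
#' returned alongside.
#'
#' @param mat Complete log2 matrix (peptides x samples).
#' @param labels Two-level factor/character vector over columns.
#' @param n_perm Number of permutations (default 250).
#' @param seed Integer seed.
#' @return List: \code{q}, \code{p_perm}, \code{t}, \code{n_perm_used},
#'   \code{exhaustive}.
#' @export
permutation_qvalues <- function(mat, labels, n_perm = 250L, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stopf("labels must have exactly two levels")
  if (n_perm < 1) stopf("n_perm must be >= 1")
  n <- ncol(mat)
  # canonical split size: the smaller group (relabel-invariant enumeration)
  sizes <- table(labels)
  k <- as.integer(min(sizes))
  small_level <- names(sizes)[which.min(sizes)]
  idxA <- which(labels == small_level)
  idxB <- which(labels != small_level)
  obs <- abs(row_t_stats(mat, idxA, idxB)$t)
  m <- length(obs)
  splits <- withr::with_seed(seed, make_splits(n, k, n_perm))
  P <- ncol(splits)
  nullmat <- matrix(0, m, P)
  for (p in seq_len(P)) {
    ia <- splits[, p]
    nullmat[, p] <- abs(row_t_stats(mat, ia, setdiff(seq_len(n), ia))$t)
  }
  p_perm <- rowMeans(nullmat >= obs)
  pooled <- sort(as.vector(nullmat))
  count_ge <- function(x) length(pooled) - findInterval(x, pooled, left.open = TRUE)
  num <- vapply(obs, count_ge, 0) / P
  obs_sorted <- sort(obs)
  den <- m - findInterval(obs, obs_sorted, left.open = TRUE)
  q_raw <- pmin(1, pmax(0, num / den))
  ord <- order(obs, decreasing = TRUE)
  q_mono <- numeric(m)
  q_mono[ord] <- rev(cummin(rev(q_raw[ord])))
  list(q = q_mono, p_perm = p_perm, t = obs, n_perm_used = P,
       exhaustive = P == choose(n, k))
}

#' Z-scale matrix rows
#'
#' Each row is centered to mean 0 and scaled to population standard deviation
#' 1 (divisor n, not n - 1). Constant rows become all zeros and are flagged in
#' the \code{"constant_rows"} attribute.
#'
#' @param mat Numeric matrix with >= 2 columns.
#' @return Scaled matrix.
#' @export
zscale <- function(mat) {
  if (ncol(mat) < 2) stopf("zscale needs >= 2 values per row")
  mu <- rowMeans(mat)
  sd_pop <- sqrt(rowMeans((mat - mu)^2))
  const <- sd_pop == 0
  out <- (mat - mu) / ifelse(const, 1, sd_pop)
  attr(out, "constant_rows") <- which(const)
  out
}

#' Agglomerative hierarchical clustering of matrix rows
#'
#' Euclidean distance with average linkage by default (configurable). Returns
#' the leaf order, merge heights, the \code{hclust} object and a Newick
#' rendering of the dendrogram.
#'
#' @param mat Numeric matrix with >= 2 rows.
#' @param linkage Linkage method passed to \code{\link[stats]{hclust}}.
#' @param dist_method Distance passed to \code{\link[stats]{dist}}.
#' @return List: \code{order}, \code{heights}, \code{hclust}, \code{newick}.
#' @export
hcluster_rows <- function(mat, linkage = "average", dist_method = "euclidean") {
  if (nrow(mat) < 2) stopf("clustering needs >= 2 rows")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("r", seq_len(nrow(mat)))
  hc <- stats::hclust(stats::dist(mat, method = dist_method), method = linkage)
  newick <- if (nrow(mat) >= 3) {
    ape::write.tree(ape::as.phylo(hc))
  } else {
    sprintf("(%s:%.6g,%s:%.6g);", rownames(mat)[1], hc$height / 2,
            rownames(mat)[2], hc$height / 2)
  }
  list(order = hc$order, heights = hc$height, hclust = hc, newick = newick)
}

#' Knockout-vs-wildtype differential analysis of a quantification table
#'
#' Applies the fixed pipeline: log2 transform, optional down-shifted
#' imputation, pooled-variance Student's t per peptide (log2FC = KO - WT), and
#' permutation q-values. Peptides are called significant at
#' \code{q < q_cutoff}. The no-imputation mode serves comparisons computed on
#' raw log2 abundance (prohormone-level profiles).
#'
#' @param qt A filtered \code{quant_table}.
#' @param ko Genotype label of the knockout group.
#' @param wt Genotype label of the reference group (default "WT").
#' @param n_perm Number of label permutations for the q-value.
#' @param q_cutoff Significance threshold on the q-value.
#' @param impute Apply \code{\link{impute_leftshift}} before testing.
#' @param imputation An \code{\link{imputation_params}}.
#' @param seed Integer seed for the permutations.
#' @return A \code{differential_result} data frame: peptide identity columns,
#'   group means, \code{log2fc}, \code{t}, \code{p}, \code{p_perm}, \code{q},
#'   \code{significant}, \code{direction}.
#' @export
differential_analysis <- function(qt, ko, wt = "WT", n_perm = 250L,
                                  q_cutoff = 0.05, impute = TRUE,
                                  imputation = imputation_params(),
                                  seed = 1L) {
  stopifnot(inherits(qt, "quant_table"))
  keep <- qt$samples$genotype %in% c(ko, wt)
  if (!any(qt$samples$genotype == ko) || !any(qt$samples$genotype == wt))
    stopf("genotypes '%s' and '%s' must both be present", ko, wt)
  mat <- log2(qt$abundance[, keep, drop = FALSE])
  samples <- qt$samples[keep, ]
  if (impute) mat <- impute_leftshift(mat, imputation)
  else if (anyNA(mat))
    stopf("missing values present; impute or filter before testing")
  idxA <- which(samples$genotype == ko)
  idxB <- which(samples$genotype == wt)
  st <- row_t_stats(mat, idxA, idxB)
  pq <- permutation_qvalues(mat, samples$genotype, n_perm = n_perm, seed = seed)
  res <- cbind(qt$peptides,
               data.frame(mean_ko = st$mean_a, mean_wt = st$mean_b,
                          log2fc = st$log2fc, t = st$t, p = st$p,
                          p_perm = pq$p_perm, q = pq$q,
                          significant = pq$q < q_cutoff,
                          direction = ifelse(st$log2fc > 0, "KO-enriched",
                                             "WT-enriched"),
                          stringsAsFactors = FALSE))
  attr(res, "contrast") <- c(ko = ko, wt = wt)
  attr(res, "n_perm_used") <- pq$n_perm_used
  class(res) <- c("differential_result", class(res))
  res
}

#' Split differential results into enriched peptide sets
#'
#' @param res A \code{differential_result}.
#' @return List with data frames \code{ko} (significant, log2FC > 0) and
#'   \code{wt} (significant, log2FC < 0).
#' @export
enriched_sets <- function(res) {
  list(ko = res[res$significant & res$log2fc > 0, , drop = FALSE],
       wt = res[res$significant & res$log2fc < 0, , drop = FALSE])
}
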