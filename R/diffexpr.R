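#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted
#' to genes with nonzero counts in every sample) of the ratio between the
#' sample's count and the gene's geometric mean across samples.
#'
#' @param counts integer count matrix, genes x samples.
#' @return named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts == 0) == 0
  if (!any(ok))
    stop("normalization error: no gene has nonzero counts in all samples")
  lg <- log(counts[ok, , drop = FALSE])
  loggeo <- rowMeans(lg)
  sf <- apply(lg, 2, function(x) exp(stats::median(x - loggeo)))
  stats::setNames(sf, colnames(counts))
}

#' Per-gene NB dispersion by moments with trend shrinkage
#'
#' Raw estimates come from the method of moments on size-factor-normalised
#' counts, `alpha_g = max(0, (s2_g - mu_g) / mu_g^2)` with the variance
#' pooled within groups, then are shrunk toward a fitted mean-dispersion
#' trend `alpha(mu) = a0 + a1/mu`. At few replicates the per-gene moment
#' estimate carries very few degrees of freedom while the trend pools
#' thousands of genes, so the default shrinkage weight is high.
#'
#' @param counts integer count matrix.
#' @param size_factors named size factors (see [estimate_size_factors()]).
#' @param group factor/character of group membership per sample.
#' @param shrink_weight weight on the trend in `(1-w)*raw + w*trend`.
#' @param min_disp floor applied to the result.
#' @return named numeric vector of dispersions with the trend coefficients
#'   in attribute `trend`.
#' @export
estimate_dispersion <- function(counts, size_factors, group,
                                shrink_weight = 0.7, min_disp = 1e-8) {
  counts <- as.matrix(counts)
  group <- as.factor(group)
  if (any(table(group) < 2))
    stop("dispersion error: need at least 2 replicates per group")
  q <- sweep(counts, 2, size_factors[colnames(counts)], "/")
  mu <- rowMeans(q)

  ss <- 0; df <- 0
  for (g in levels(group)) {
    cols <- which(group == g)
    qg <- q[, cols, drop = FALSE]
    ss <- ss + rowSums((qg - rowMeans(qg))^2)
    df <- df + length(cols) - 1L
  }
  s2 <- ss / df
  raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)

  keep <- is.finite(raw) & mu > 0
  fit <- stats::lm(raw[keep] ~ I(1 / mu[keep]))
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0  # singular trend fit (e.g. all means equal)
  a0 <- max(unname(cf[1]), 0)
  a1 <- max(unname(cf[2]), 0)
  trend <- ifelse(mu > 0, a0 + a1 / mu, a0)

  out <- pmax(min_disp, (1 - shrink_weight) * raw + shrink_weight * trend)
  attr(out, "trend") <- c(a0 = a0, a1 = a1)
  stats::setNames(out, rownames(counts))
}

# Per-gene fit of a single group mean on the log scale: the estimate is
# the mean of size-factor-normalised counts (a function of y/sf only, so
# rescaling any sample's counts together with its size factor leaves it
# unchanged exactly), with expected-information NB standard errors
# se(log m) = sqrt((1 + alpha*m) / (n*m)) at known dispersion.
.nb_group_fit <- function(y, sf, alpha) {
  y <- as.matrix(y)
  q <- sweep(y, 2, sf, "/")
  m <- pmax(rowMeans(q), 1e-8)
  list(eta = log(m),
       se_eta = sqrt((1 + alpha * m) / (ncol(y) * m)))
}

#' Negative-binomial Wald test between two groups
#'
#' Fits each group's mean as the average of size-factor-normalised counts
#' with expected-information NB standard errors at the gene-wise
#' dispersion, forms `log2FC = (eta_num - eta_den)/log(2)` with the
#' numerator group first, and tests it against zero with a Wald z
#' statistic on the normal reference. Because the estimate depends on the
#' data only through the normalised counts, rescaling a sample together
#' with its size factor leaves every log2FC unchanged, and swapping the
#' contrast negates them exactly. Genes whose normalised counts summed over the contrasted
#' samples fall below `independent_filter_floor` are excluded from the
#' Benjamini-Hochberg correction (padj reported as NA).
#'
#' @param counts integer count matrix (genes x samples).
#' @param samples sample table with `sample_id` and the contrast factor.
#' @param contrast list/character of (factor, numerator, denominator),
#'   e.g. `c("strain", "resistant", "susceptible")`.
#' @param size_factors,dispersions optional; estimated on the contrasted
#'   samples when NULL.
#' @param alpha,lfc_threshold significance and fold-change thresholds for
#'   the regulation class (strict inequalities; see [classify_volcano()]).
#' @param independent_filter_floor low-count filter on the sum of
#'   normalised counts (default 10, matching the expressed-gene cutoff).
#' @return data.frame with columns gene_id, base_mean, log2fc, se_log2fc,
#'   wald_p, padj, class, ordered by (wald_p, gene_id).
#' @export
wald_test <- function(counts, samples, contrast, size_factors = NULL,
                      dispersions = NULL, alpha = 0.05, lfc_threshold = 1,
                      independent_filter_floor = 10) {
  counts <- as.matrix(counts)
  fac <- contrast[[1]]; num <- contrast[[2]]; den <- contrast[[3]]
  if (!fac %in% names(samples)) stop("contrast error: unknown factor ", fac)
  if (!all(c(num, den) %in% samples[[fac]]))
    stop("contrast error: group absent from design: ",
         paste(setdiff(c(num, den), samples[[fac]]), collapse = ", "))
  sub <- samples[samples[[fac]] %in% c(num, den), ]
  counts <- counts[, sub$sample_id, drop = FALSE]

  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- size_factors[colnames(counts)]
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(counts, sf, sub[[fac]])
  disp <- as.numeric(dispersions)

  ia <- sub$sample_id[sub[[fac]] == num]
  ib <- sub$sample_id[sub[[fac]] == den]
  fa <- .nb_group_fit(counts[, ia, drop = FALSE], sf[ia], disp)
  fb <- .nb_group_fit(counts[, ib, drop = FALSE], sf[ib], disp)

  log2fc <- (fa$eta - fb$eta) / log(2)
  se <- sqrt(fa$se_eta^2 + fb$se_eta^2) / log(2)
  z <- log2fc / se
  q <- sweep(counts, 2, sf, "/")
  base_mean <- rowMeans(q)
  all_zero <- rowSums(counts) == 0
  p <- 2 * stats::pnorm(-abs(z))
  p[all_zero] <- NA_real_
  log2fc[all_zero] <- 0

  pass <- rowSums(q) >= independent_filter_floor & !is.na(p)
  padj <- rep(NA_real_, nrow(counts))
  padj[pass] <- adjust_bh(p[pass])

  res <- data.frame(gene_id = rownames(counts), base_mean = base_mean,
                    log2fc = log2fc, se_log2fc = se, wald_p = p, padj = padj,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$class <- classify_volcano(res, alpha = alpha, lfc = lfc_threshold)
  res[order(res$wald_p, res$gene_id), , drop = FALSE]
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper over the standard step-up procedure
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("domain error: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Volcano regulation classes
#'
#' Strict thresholds: `up` iff `padj < alpha` and `log2fc > lfc`; `down`
#' iff `padj < alpha` and `log2fc < -lfc`; otherwise `ns`. The second tier
#' used for the curated-gene view and the TF stage is `lfc = 2`.
#'
#' @param results data.frame with `log2fc` and `padj`.
#' @param alpha adjusted-p threshold.
#' @param lfc log2 fold-change threshold.
#' @return character vector of classes with a `counts` attribute.
#' @export
classify_volcano <- function(results, alpha = 0.05, lfc = 1) {
  sig <- !is.na(results$padj) & results$padj < alpha
  cls <- ifelse(sig & results$log2fc > lfc, "up",
                ifelse(sig & results$log2fc < -lfc, "down", "ns"))
  attr(cls, "counts") <- c(up = sum(cls == "up"), down = sum(cls == "down"),
                           ns = sum(cls == "ns"))
  cls
}
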