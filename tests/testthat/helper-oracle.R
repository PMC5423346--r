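# Independent oracles.

# 50-digit evaluation of the quantification equation via mpmath (Python),
# fully independent of the package's arithmetic. `df` has columns
# lambda_bbp, delta_m, m0, pld, tau, t1_blood (ms), alpha.
mpmath_cbf <- function(df) {
  stopifnot(all(c("lambda_bbp", "delta_m", "m0", "pld", "tau", "t1_blood",
                  "alpha") %in% names(df)))
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".txt")
  fpy <- tempfile(fileext = ".py")
  on.exit(unlink(c(fin, fout, fpy)), add = TRUE)
  utils::write.csv(format(df, digits = 17, scientific = FALSE), fin,
                   row.names = FALSE, quote = FALSE)
  writeLines(c(
    "import sys, csv",
    "from mpmath import mp, mpf, exp",
    "mp.dps = 50",
    "rows = list(csv.DictReader(open(sys.argv[1])))",
    "with open(sys.argv[2], 'w') as fh:",
    "    for r in rows:",
    "        lam = mpf(r['lambda_bbp'].strip())",
    "        dm = mpf(r['delta_m'].strip())",
    "        m0 = mpf(r['m0'].strip())",
    "        pld = mpf(r['pld'].strip()) / 1000",
    "        tau = mpf(r['tau'].strip()) / 1000",
    "        t1b = mpf(r['t1_blood'].strip()) / 1000",
    "        alpha = mpf(r['alpha'].strip())",
    "        cbf = 6000 * lam * dm * exp(pld / t1b) / \\",
    "            (2 * alpha * t1b * m0 * (1 - exp(-tau / t1b)))",
    "        fh.write(mp.nstr(cbf, 25, strip_zeros=False) + '\\n')"),
    fpy)
  status <- system2("python", c(fpy, fin, fout))
  if (status != 0) stop("mpmath oracle failed")
  as.numeric(readLines(fout))
}

# Random valid parameter/signal sets for oracle comparisons.
random_quant_cases <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(lambda_bbp = runif(n, 0.8, 1.0),
             delta_m = runif(n, -20, 50),
             m0 = runif(n, 100, 5000),
             pld = runif(n, 1000, 2500),
             tau = runif(n, 1000, 2500),
             t1_blood = runif(n, 1200, 1800),
             alpha = runif(n, 0.6, 1.0))
}

quantify_cases <- function(df) {
  vapply(seq_len(nrow(df)), function(i) {
    p <- quant_params(lambda_bbp = df$lambda_bbp[i], pld = df$pld[i],
                      tau = df$tau[i], t1_blood = df$t1_blood[i],
                      alpha = df$alpha[i])
    quantify_voxel(df$delta_m[i], df$m0[i], p)
  }, numeric(1))
}

# ICC oracle: mean squares from an independent ANOVA fit (stats::aov),
# combined by the textbook single-measurement formulas.
icc_oracle <- function(m, form = "twoway") {
  df <- data.frame(y = as.vector(m),
                   subj = factor(as.vector(row(m))),
                   rater = factor(as.vector(col(m))))
  n <- nrow(m)
  k <- ncol(m)
  if (form == "oneway") {
    tab <- stats::anova(stats::aov(y ~ subj, data = df))
    msr <- tab["subj", "Mean Sq"]
    msw <- tab["Residuals", "Mean Sq"]
    return((msr - msw) / (msr + (k - 1) * msw))
  }
  tab <- stats::anova(stats::aov(y ~ subj + rater, data = df))
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  if (form == "consistency")
    return((msr - mse) / (msr + (k - 1) * mse))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Euclidean distance from every voxel center to the nearest TRUE voxel
# center of `mask` (brute force; small grids only).
brute_min_dist <- function(mask, voxel_size) {
  g <- dim(mask)
  ax <- lapply(1:3, function(i) (seq_len(g[i]) - (g[i] + 1) / 2) * voxel_size[i])
  coords <- cbind(
    rep(ax[[1]], times = g[2] * g[3]),
    rep(rep(ax[[2]], each = g[1]), times = g[3]),
    rep(ax[[3]], each = g[1] * g[2]))
  src <- coords[as.vector(mask), , drop = FALSE]
  d <- apply(coords, 1, function(pt)
    sqrt(min(colSums((t(src) - pt)^2))))
  array(d, dim = g)
}
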