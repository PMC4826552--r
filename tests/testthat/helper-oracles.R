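# Independent oracles and fixture builders shared across the test files.
# These deliberately avoid the package's own computation paths.

# Random in-memory dataset with arbitrary chromosome layout and optional
# missing calls (code 1).
rand_dataset <- function(chrom_sizes, n, missing_rate = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- sum(chrom_sizes)
  G <- matrix(sample(c(0L, 2L, 3L), m * n, replace = TRUE,
                     prob = c(0.1, 0.3, 0.6)), nrow = m)
  if (missing_rate > 0) {
    G[matrix(runif(m * n) < missing_rate, nrow = m)] <- 1L
  }
  variants <- data.frame(
    chr = rep(paste0("chr", seq_along(chrom_sizes)), chrom_sizes),
    id = paste0("m", seq_len(m)), cm = 0,
    bp = unlist(lapply(chrom_sizes, function(s) sort(sample.int(1e6, s)))),
    a1 = "A", a2 = "B", stringsAsFactors = FALSE
  )
  samples <- data.frame(
    fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
    pid = "0", mid = "0", sex = 1L, phenotype = NA_real_,
    stringsAsFactors = FALSE
  )
  bed_dataset(variants, samples, G)
}

# Per-genotype collapsing oracle: scalar matrix lookup in a plain loop.
oracle_collapse <- function(g1, g2, M) {
  M <- unclass(M)
  out <- integer(length(g1))
  for (i in seq_along(g1)) out[i] <- M[g1[i] + 1L, g2[i] + 1L]
  out
}

# Closed-form OLS oracle: (X'X)^-1 X'y with textbook Wald t.
oracle_ols <- function(y, d, covars = NULL) {
  keep <- !is.na(y) & !is.na(d)
  if (!is.null(covars)) keep <- keep & complete.cases(covars)
  y <- y[keep]; d <- d[keep]
  X <- cbind(1, if (!is.null(covars)) covars[keep, , drop = FALSE], d)
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  V <- sigma2 * solve(XtX)
  j <- ncol(X)
  tt <- b[j] / sqrt(V[j, j])
  list(beta = b[j], se = sqrt(V[j, j]), t = tt,
       p = 2 * pt(abs(tt), df, lower.tail = FALSE), n = nrow(X))
}

# Logistic IRLS oracle: Newton-Raphson on the log-likelihood from scratch.
oracle_irls <- function(y, d, covars = NULL, tol = 1e-10, maxit = 50) {
  keep <- !is.na(y) & !is.na(d)
  if (!is.null(covars)) keep <- keep & complete.cases(covars)
  y <- y[keep]; d <- d[keep]
  X <- cbind(1, if (!is.null(covars)) covars[keep, , drop = FALSE], d)
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    step <- solve(t(X) %*% (X * W), t(X) %*% (y - mu))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  V <- solve(t(X) %*% (X * (mu * (1 - mu))))
  j <- ncol(X)
  list(beta = unname(b[j]), se = unname(sqrt(V[j, j])))
}

# Carrier-probability oracle: enumerate the 3x3 HWE genotype table and sum the
# cells that collapse to a carrier under the default matrix.
oracle_carrier_prob <- function(maf) {
  geno_p <- c(maf^2, 2 * maf * (1 - maf), (1 - maf)^2)  # hom-min, het, hom-maj
  codes <- c(0L, 2L, 3L)
  M <- unclass(gcdh::collapsing_matrix("recessive-default"))
  total <- 0
  for (i in 1:3) for (j in 1:3) {
    if (M[codes[i] + 1L, codes[j] + 1L] == 0L) {
      total <- total + geno_p[i] * geno_p[j]
    }
  }
  total
}

# Aligned random quantitative phenotype table for a dataset.
rand_pheno <- function(dataset, seed = NULL, covars = 0) {
  if (!is.null(seed)) set.seed(seed)
  ph <- data.frame(fid = dataset$samples$fid, iid = dataset$samples$iid,
                   y = rnorm(dataset$n), stringsAsFactors = FALSE)
  if (covars > 0) {
    for (k in seq_len(covars)) ph[[paste0("c", k)]] <- rnorm(dataset$n)
  }
  ph
}
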