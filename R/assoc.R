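# Native single-marker association scans (linear and logistic, with optional
# covariates) over original or shifted datasets. Missing handling is per-marker
# listwise deletion; degenerate markers yield NA rows, never a fabricated p.

#' Additive dose mapping for genotype codes
#'
#' The regression dose counts A1 (minor) alleles: code 0 (hom minor) -> 2,
#' code 2 (het) -> 1, code 3 (hom major) -> 0, code 1 (missing) -> NA. The same
#' mapping applies to collapsed pseudo-genotypes: under the recessive-default
#' matrix pseudo-doses are \{0, 2\} (carrier dose 2), under the additive
#' alternative \{0, 1, 2\}. Wald p-values are invariant to affine rescaling of
#' the dose, so the choice of coding does not affect scan results.
#'
#' @return numeric vector of length 4, indexed by code + 1.
#' @export
dose_map <- function() c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)

#' Dose matrix of a dataset
#'
#' @param dataset a [bed_dataset()].
#' @return \code{n x m} numeric matrix of additive doses (samples in rows),
#'   NA where the genotype is missing.
#' @export
dose_matrix <- function(dataset) {
  G <- genotype_matrix(dataset)
  D <- dose_map()[t(G) + 1L]
  dim(D) <- c(dataset$n, dataset$m)
  dimnames(D) <- NULL
  D
}

#' Per-variant allele frequency and missingness
#'
#' @param dataset a [bed_dataset()].
#' @return data.frame with \code{id, n_called, freq_a1} (A1 allele frequency
#'   among non-missing calls), \code{maf} (\code{min(freq_a1, 1 - freq_a1)})
#'   and \code{missing_rate}. All-missing variants have NA frequencies.
#' @export
allele_stats <- function(dataset) {
  G <- genotype_matrix(dataset)
  n0 <- rowSums(G == 0L)
  n1 <- rowSums(G == 1L)
  n2 <- rowSums(G == 2L)
  n3 <- rowSums(G == 3L)
  called <- n0 + n2 + n3
  freq <- ifelse(called > 0, (2 * n0 + n2) / (2 * called), NA_real_)
  data.frame(
    id = dataset$variants$id,
    n_called = called,
    freq_a1 = freq,
    maf = pmin(freq, 1 - freq),
    missing_rate = n1 / dataset$n,
    stringsAsFactors = FALSE
  )
}

# Core OLS scan. D: n x m dose matrix (may contain NA); y: response (may
# contain NA); covars: n x c numeric matrix or NULL. Markers whose dose is
# complete on the base sample set are fitted in one vectorised
# Frisch-Waugh-Lovell pass; markers with their own missingness fall back to a
# per-marker fit on their complete cases. Returns beta/se/t/p/n_used/note.
.ols_scan <- function(D, y, covars = NULL) {
  n <- length(y)
  m <- ncol(D)
  keep0 <- !is.na(y)
  if (!is.null(covars)) keep0 <- keep0 & stats::complete.cases(covars)
  ncov <- if (is.null(covars)) 0L else ncol(covars)

  beta <- se <- tstat <- pval <- rep(NA_real_, m)
  n_used <- integer(m)
  note <- character(m)

  fit_one <- function(d, yy, cv) {
    rows <- !is.na(d)
    d <- d[rows]; yy <- yy[rows]
    X <- cbind(1, if (!is.null(cv)) cv[rows, , drop = FALSE], d)
    nk <- length(yy)
    if (nk < ncol(X) + 1L) return(list(note = "insufficient observations"))
    qx <- qr(X)
    if (qx$rank < ncol(X)) return(list(note = "degenerate design"))
    cf <- qr.coef(qx, yy)
    res <- yy - X %*% cf
    df <- nk - ncol(X)
    sigma2 <- sum(res^2) / df
    xtxinv <- chol2inv(qr.R(qx))
    s <- sqrt(sigma2 * xtxinv[ncol(X), ncol(X)])
    b <- cf[ncol(X)]
    tt <- b / s
    list(beta = b, se = s, t = tt, p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
         n = nk, note = "")
  }

  nk0 <- sum(keep0)
  complete_cols <- (colSums(is.na(D[keep0, , drop = FALSE])) == 0L)

  if (any(complete_cols) && nk0 >= ncov + 3L) {
    yk <- y[keep0]
    Z <- cbind(rep(1, nk0), if (!is.null(covars)) covars[keep0, , drop = FALSE])
    qz <- qr(Z)
    ry <- qr.resid(qz, yk)
    Dk <- D[keep0, complete_cols, drop = FALSE]
    RD <- Dk - qr.fitted(qz, Dk)
    Sxx <- colSums(RD^2)
    Sxy <- colSums(RD * ry)
    df <- nk0 - (qz$rank + 1L)
    ok <- Sxx > 1e-8
    b <- ifelse(ok, Sxy / Sxx, NA_real_)
    sse <- pmax(sum(ry^2) - b^2 * Sxx, 0)
    s <- ifelse(ok, sqrt(sse / df / Sxx), NA_real_)
    tt <- b / s
    idx <- which(complete_cols)
    beta[idx] <- b
    se[idx] <- s
    tstat[idx] <- tt
    pval[idx] <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    n_used[idx] <- nk0
    note[idx[!ok]] <- "constant dose"
    n_used[idx[!ok]] <- nk0
    # exact-fit guard: se == 0 gives t = Inf, p = 0; report a floor instead
    exact <- which(complete_cols)[which(ok & s <= 0)]
    if (length(exact)) {
      se[exact] <- 0
      tstat[exact] <- Inf * sign(beta[exact])
      pval[exact] <- .Machine$double.xmin
    }
  } else if (nk0 < ncov + 3L) {
    note[complete_cols] <- "insufficient observations"
  }

  for (j in which(!complete_cols)) {
    d <- D[, j]
    d[!keep0] <- NA
    f <- fit_one(d, y, covars)
    if (is.null(f$beta)) {
      note[j] <- f$note
      n_used[j] <- sum(keep0 & !is.na(D[, j]))
    } else {
      beta[j] <- f$beta; se[j] <- f$se; tstat[j] <- f$t; pval[j] <- f$p
      n_used[j] <- f$n
    }
  }

  data.frame(n_used = n_used, beta = beta, se = se, stat = tstat, p = pval,
             note = note, stringsAsFactors = FALSE)
}

# Core logistic scan (per-marker IRLS via glm.fit). y in {0,1}.
.logit_scan <- function(D, y, covars = NULL, maxit = 25L, epsilon = 1e-8) {
  n <- length(y)
  m <- ncol(D)
  keep0 <- !is.na(y)
  if (!is.null(covars)) keep0 <- keep0 & stats::complete.cases(covars)

  beta <- se <- zstat <- pval <- rep(NA_real_, m)
  n_used <- integer(m)
  note <- character(m)

  for (j in seq_len(m)) {
    rows <- keep0 & !is.na(D[, j])
    nk <- sum(rows)
    n_used[j] <- nk
    d <- D[rows, j]
    X <- cbind(1, if (!is.null(covars)) covars[rows, , drop = FALSE], d)
    if (nk < ncol(X) + 1L) { note[j] <- "insufficient observations"; next }
    if (stats::var(d) < 1e-12) { note[j] <- "constant dose"; next }
    qx <- qr(X)
    if (qx$rank < ncol(X)) { note[j] <- "degenerate design"; next }
    fit <- suppressWarnings(stats::glm.fit(
      X, y[rows], family = stats::binomial(),
      control = stats::glm.control(epsilon = epsilon, maxit = maxit)
    ))
    if (!fit$converged) { note[j] <- "nonconvergence"; next }
    mu <- fit$fitted.values
    if (any(mu > 1 - 1e-8) || any(mu < 1e-8)) {
      if (abs(fit$coefficients[ncol(X)]) > 10) { note[j] <- "separation"; next }
    }
    w <- mu * (1 - mu)
    XtWX <- crossprod(X * sqrt(w))
    cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(cov)) { note[j] <- "singular information"; next }
    b <- fit$coefficients[ncol(X)]
    s <- sqrt(cov[ncol(X), ncol(X)])
    if (!is.finite(s) || s > 100) { note[j] <- "separation"; next }
    beta[j] <- b; se[j] <- s
    zstat[j] <- b / s
    pval[j] <- 2 * stats::pnorm(abs(zstat[j]), lower.tail = FALSE)
  }

  data.frame(n_used = n_used, beta = beta, se = se, stat = zstat, p = pval,
             note = note, stringsAsFactors = FALSE)
}

# Join a phenotype table (or plain vector) to the dataset's sample order.
# Returns list(y, covars). `pheno` may be a numeric vector aligned to the
# samples, or a data.frame with fid/iid keys (e.g. from read_pheno).
.join_pheno <- function(dataset, pheno, pheno_name = NULL,
                        covariate_names = NULL) {
  if (is.numeric(pheno)) {
    if (length(pheno) != dataset$n) {
      stop("phenotype vector length ", length(pheno),
           " does not match sample count ", dataset$n)
    }
    if (length(covariate_names)) {
      stop("covariates require a phenotype table with named columns")
    }
    return(list(y = as.numeric(pheno), covars = NULL))
  }
  stopifnot(is.data.frame(pheno))
  key_data <- paste(dataset$samples$fid, dataset$samples$iid, sep = "\r")
  key_ph <- paste(pheno$fid, pheno$iid, sep = "\r")
  ix <- match(key_data, key_ph)
  if (all(is.na(ix))) stop("no (FID, IID) keys of the phenotype table match the fileset")
  if (is.null(pheno_name)) {
    pheno_name <- setdiff(names(pheno), c("fid", "iid", covariate_names))[1L]
  }
  if (!pheno_name %in% names(pheno)) {
    stop("phenotype column '", pheno_name, "' not found")
  }
  y <- as.numeric(pheno[[pheno_name]])[ix]
  covars <- NULL
  if (length(covariate_names)) {
    missing_cov <- setdiff(covariate_names, names(pheno))
    if (length(missing_cov)) {
      stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
    }
    covars <- as.matrix(pheno[covariate_names])[ix, , drop = FALSE]
    storage.mode(covars) <- "double"
  }
  list(y = y, covars = covars)
}

# Assemble the public result table around a core-scan data.frame.
.scan_result <- function(dataset, core) {
  st <- allele_stats(dataset)
  out <- data.frame(
    id = dataset$variants$id,
    chr = dataset$variants$chr,
    bp = dataset$variants$bp,
    n_used = core$n_used,
    maf = st$maf,
    beta = core$beta,
    se = core$se,
    stat = core$stat,
    p = core$p,
    note = core$note,
    stringsAsFactors = FALSE
  )
  if (inherits(dataset, "shifted_dataset")) {
    out$snp1 <- dataset$pairs$snp1
    out$snp2 <- dataset$pairs$snp2
    out$bp1 <- dataset$pairs$bp1
    out$bp2 <- dataset$pairs$bp2
    out$shift <- dataset$pairs$shift
    # carrier (pseudo-A1) frequency of the collapsed marker
    out$pair_carrier_freq <- st$freq_a1
  }
  out
}

#' Linear association scan
#'
#' Per-marker ordinary least squares of a quantitative phenotype on the
#' additive dose plus optional covariates and an intercept. The test is the
#' Wald t on the dose coefficient, two sided, with residual degrees of freedom.
#' Samples missing the phenotype, any covariate or the marker's genotype are
#' dropped listwise per marker. Markers with no remaining dose variance (or too
#' few observations) are reported as NA rows with a \code{note}.
#'
#' @param dataset a [bed_dataset()] or [shift_genome()] result.
#' @param pheno numeric vector aligned to the samples, or a data.frame with
#'   \code{fid}/\code{iid} keys (see [read_pheno()]).
#' @param pheno_name phenotype column name (default: first non-key,
#'   non-covariate column).
#' @param covariate_names character vector of covariate columns in \code{pheno}.
#' @return data.frame with one row per marker: \code{id, chr, bp, n_used, maf,
#'   beta, se, stat, p, note} (plus pair columns for shifted datasets).
#' @export
linear_scan <- function(dataset, pheno, pheno_name = NULL,
                        covariate_names = NULL) {
  jp <- .join_pheno(dataset, pheno, pheno_name, covariate_names)
  core <- .ols_scan(dose_matrix(dataset), jp$y, jp$covars)
  .scan_result(dataset, core)
}

#' Logistic association scan
#'
#' Per-marker maximum-likelihood logistic regression of a binary phenotype on
#' the additive dose plus optional covariates; Wald z test on the dose
#' coefficient. Phenotypes coded \{1, 2\} (PLINK case/control) are recoded to
#' \{0, 1\} with a message. Convergence tolerance 1e-8 on the deviance, at most
#' 25 IRLS iterations; non-convergence and (quasi-)complete separation are
#' flagged in \code{note} with NA results.
#'
#' @inheritParams linear_scan
#' @return as [linear_scan()], with \code{stat} the Wald z.
#' @export
logistic_scan <- function(dataset, pheno, pheno_name = NULL,
                          covariate_names = NULL) {
  jp <- .join_pheno(dataset, pheno, pheno_name, covariate_names)
  y <- jp$y
  vals <- sort(unique(y[!is.na(y)]))
  if (identical(vals, c(1, 2))) {
    message("recoding phenotype {1, 2} (control/case) to {0, 1}")
    y <- y - 1
  } else if (!all(vals %in% c(0, 1))) {
    stop("binary phenotype must be coded {0,1} or {1,2}; found values: ",
         paste(utils::head(vals, 5), collapse = ", "))
  }
  core <- .logit_scan(dose_matrix(dataset), y, jp$covars)
  .scan_result(dataset, core)
}
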