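# Fractional polynomials of age (Royston-Altman basis). Powers are drawn
# from the conventional set {-2, -1, -0.5, 0, 0.5, 1, 2, 3}; power 0 denotes
# log(age), and a repeated power p denotes the pair {age^p, age^p * log(age)}.
# These are the regression bases used for the age-varying mean and SD of the
# transformed amplitude ratio.

.FP_POWERS <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fractional-polynomial design matrix
#'
#' @param age Positive ages (years).
#' @param powers Numeric vector of length 0, 1 or 2 from the power set
#'   `{-2, -1, -0.5, 0, 0.5, 1, 2, 3}`; length 0 gives an intercept-only
#'   design. A repeated power `p` yields columns `age^p` and
#'   `age^p * log(age)`.
#' @return Numeric matrix with an intercept column followed by one column per
#'   fractional-polynomial term.
#' @export
fp_design <- function(age, powers = numeric(0)) {
  stopifnot(is.numeric(age), all(age > 0))
  n <- length(age)
  if (length(powers) == 0L)
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  if (length(powers) > 2L)
    stop("fractional polynomials of degree > 2 are not supported",
         call. = FALSE)
  powers <- sort(powers)
  term <- function(p) if (p == 0) log(age) else age^p
  if (length(powers) == 2L && powers[1] == powers[2]) {
    x1 <- term(powers[1])
    cols <- cbind(x1, x1 * log(age))
  } else {
    cols <- do.call(cbind, lapply(powers, term))
  }
  colnames(cols) <- paste0("fp", seq_len(ncol(cols)))
  cbind("(Intercept)" = 1, cols)
}

#' Evaluate a fitted fractional polynomial
#'
#' @param age Positive ages (years).
#' @param powers Power vector as in [fp_design()].
#' @param beta Coefficients (intercept first), matching the design columns.
#' @return Numeric vector of fitted values.
#' @export
fp_eval <- function(age, powers, beta) {
  X <- fp_design(age, powers)
  if (ncol(X) != length(beta))
    stop("coefficient length does not match the fractional-polynomial basis",
         call. = FALSE)
  drop(X %*% beta)
}

# All candidate power vectors up to a given degree (8 FP1 models,
# 36 FP2 models including repeated powers), preceded by the null
# (intercept-only) model and, for degree >= 1, always including the linear
# model among the FP1 set (power 1 is in the set).
.fp_candidates <- function(degree) {
  cands <- list(numeric(0))
  if (degree >= 1L)
    cands <- c(cands, lapply(.FP_POWERS, function(p) p))
  if (degree >= 2L) {
    idx <- which(upper.tri(diag(length(.FP_POWERS)), diag = TRUE),
                 arr.ind = TRUE)
    cands <- c(cands, lapply(seq_len(nrow(idx)), function(i)
      sort(c(.FP_POWERS[idx[i, 1]], .FP_POWERS[idx[i, 2]]))))
  }
  cands
}

# Precompute thin-Q factors for every candidate design on a fixed age vector,
# so that per-candidate residual sums of squares for many different response
# vectors (one per Box-Cox lambda) cost only a small matrix product.
.fp_prepare <- function(age, degree) {
  cands <- .fp_candidates(degree)
  lapply(cands, function(p) {
    X <- fp_design(age, p)
    qrX <- qr(X)
    list(powers = p, X = X, qr = qrX,
         Q = qr.Q(qrX), rank = qrX$rank, npar = ncol(X))
  })
}

# RSS of response y against a prepared candidate.
.fp_rss <- function(prep, y) {
  qty <- crossprod(prep$Q, y)
  max(sum(y^2) - sum(qty^2), 0)
}

# Coefficients and fitted values for a prepared candidate.
.fp_fit <- function(prep, y) {
  beta <- qr.coef(prep$qr, y)
  beta[is.na(beta)] <- 0
  list(powers = prep$powers, beta = unname(beta),
       fitted = drop(prep$X %*% beta))
}

# Closed-test model selection (Royston-Altman style): starting from the most
# complex degree, keep a simpler model unless the more complex one improves
# the deviance significantly at level alpha. Returns the index into `preps`.
.fp_select <- function(preps, y, alpha = 0.05) {
  n <- length(y)
  rss <- vapply(preps, .fp_rss, numeric(1), y = y)
  npar <- vapply(preps, function(p) p$npar, numeric(1))
  deg <- vapply(preps, function(p) length(p$powers), numeric(1))
  best_at <- function(d) {
    i <- which(deg == d)
    i[which.min(rss[i])]
  }
  dmax <- max(deg)
  keep <- best_at(0)
  for (d in seq_len(dmax)) {
    cand <- best_at(d)
    dev <- n * (log(rss[keep]) - log(rss[cand]))
    df <- npar[cand] - npar[keep]
    pval <- stats::pchisq(max(dev, 0), df = max(df, 1), lower.tail = FALSE)
    if (is.finite(pval) && pval < alpha) keep <- cand
  }
  keep
}
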