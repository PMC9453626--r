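# Inferential utilities implemented from their definitions:
# repeated-measures correlation, Benjamini-Hochberg FDR, circular
# statistics, paired contrasts.

#' Repeated-measures correlation
#'
#' The common within-subject correlation: x and y are centred within each
#' subject and the pooled centred values are correlated.  Degrees of
#' freedom are `N - k - 1` for `N` total pairs and `k` subjects; the
#' p-value comes from `t = r * sqrt(df / (1 - r^2))`.
#'
#' @param subject subject identifier vector.
#' @param x,y numeric vectors, same length as `subject`.
#' @return list of class `rmcorr_result`: `r_rm`, `df`, `p`, `n_subjects`,
#'   `n_pairs`.
#' @export
rmcorr <- function(subject, x, y) {
  stopifnot(length(subject) == length(x), length(x) == length(y))
  ok <- stats::complete.cases(subject, x, y)
  subject <- subject[ok]; x <- x[ok]; y <- y[ok]
  subject <- as.factor(subject)
  k <- nlevels(subject)
  n <- length(x)
  if (k < 2) stop("need at least 2 subjects")
  if (any(table(subject) < 2)) stop("need at least 2 pairs per subject")
  df <- n - k - 1
  if (df < 1) stop("insufficient degrees of freedom")
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  if (stats::sd(xc) == 0 || stats::sd(yc) == 0)
    stop("zero within-subject variance")
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) {
    p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(r_rm = r, df = df, p = p, n_subjects = k, n_pairs = n),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("rmcorr: r = %.4f, df = %d, p = %.4g (%d subjects, %d pairs)\n",
              x$r_rm, x$df, x$p, x$n_subjects, x$n_pairs))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `p_(i) * m / i` with running-minimum monotonicity
#' enforcement, returned in the input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  adj[ro]
}

#' Circular mean and resultant length
#'
#' Mean direction of the unit vectors of the phases and the magnitude R of
#' their resultant (1 = perfectly concentrated).  Rotation-equivariant:
#' shifting all phases by delta shifts the mean by delta (mod 360).
#'
#' @param deg phases in degrees.
#' @return list with `mean_deg` in `[0, 360)` (NA when R is numerically 0,
#'   flagged `undefined`), `R` in `[0, 1]`, `n`.
#' @export
circular_stats <- function(deg) {
  stopifnot(length(deg) >= 1)
  th <- deg * pi / 180
  cx <- mean(cos(th)); sx <- mean(sin(th))
  R <- sqrt(cx^2 + sx^2)
  if (R < 1e-12)
    return(list(mean_deg = NA_real_, R = 0, n = length(deg),
                undefined = TRUE))
  list(mean_deg = (atan2(sx, cx) * 180 / pi) %% 360, R = min(R, 1),
       n = length(deg), undefined = FALSE)
}

#' Circular standard deviation
#'
#' `sqrt(-2 log R)` in degrees; the standard dispersion measure of a
#' circular sample.
#'
#' @param deg phases in degrees.
#' @return circular SD in degrees (Inf when R = 0).
#' @export
circular_sd <- function(deg) {
  R <- circular_stats(deg)$R
  if (R <= 0) return(Inf)
  sqrt(-2 * log(R)) * 180 / pi
}

#' Paired two-sided contrast (paired t-test from its definition)
#'
#' @param a,b equal-length paired numeric vectors, n >= 2.
#' @return list: `t`, `df`, `p`, `mean_diff`, `degenerate` (TRUE when the
#'   differences have zero variance; `t` is then 0 for a zero mean
#'   difference and +/-Inf otherwise, with p = 1 or 0).
#' @export
paired_contrast <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  sd_d <- stats::sd(d)
  df <- n - 1
  if (sd_d == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(list(t = t, df = df, p = if (t == 0) 1 else 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (sd_d / sqrt(n))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Hochberg step-up adjustment
#'
#' Used for condition-level post hocs (electrode-style maps use
#' [bh_fdr()]).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
hochberg_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(seq_len(m) * p[o]))
  adj[ro]
}
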