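#' Pearson correlation with explained variance
#'
#' Product-moment correlation on pairwise-complete values, with the share of
#' variance explained (r squared) and a two-sided p value from the usual t
#' transform. A zero-variance input is flagged (`NA` result with a note)
#' rather than silently returning a spurious coefficient.
#'
#' @param x,y numeric vectors of equal length.
#' @param conf_level confidence level of the Fisher-z interval.
#' @return a one-row `data.frame`: `r, r_squared, n, p, ci_lo, ci_hi, note`.
#' @export
pearson_with_r2 <- function(x, y, conf_level = 0.95) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) pv_stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in x or y; correlation undefined")
    return(data.frame(r = NA_real_, r_squared = NA_real_, n = n, p = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_,
                      note = "zero variance"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  r <- unname(ct$estimate)
  data.frame(r = r, r_squared = r^2, n = n, p = ct$p.value,
             ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2], note = "")
}

#' Raw varimax criterion of a loading matrix
#'
#' The quantity maximized by varimax rotation: the sum over factors of the
#' variance of the squared loadings. With `normalize = TRUE` (Kaiser
#' normalization) rows are scaled to unit communality before evaluation,
#' matching the "normalized varimax" convention.
#'
#' @param L variables-by-factors loading matrix.
#' @param normalize apply Kaiser row normalization first.
#' @return a scalar; larger is more "simple structure".
#' @export
varimax_criterion <- function(L, normalize = TRUE) {
  if (normalize) {
    h <- sqrt(rowSums(L^2)); h[h == 0] <- 1
    L <- L / h
  }
  p <- nrow(L)
  sum(colSums(L^4) - colSums(L^2)^2 / p)
}

#' Kaiser-normalized varimax rotation
#'
#' Orthogonal rotation by iterative planar (pairwise) rotations. Rows are
#' scaled to unit communality first (Kaiser normalization), rotated until
#' the relative improvement of the varimax criterion falls below `eps`, and
#' rescaled back. Communalities are exactly invariant under the rotation.
#'
#' @param L variables-by-factors loading matrix (at least 1 factor; a
#'   single factor is returned unrotated).
#' @param normalize apply Kaiser row normalization (default TRUE).
#' @param eps relative convergence tolerance on the criterion.
#' @param max_iter sweep cap; non-convergence is an error with diagnostics.
#' @return a list: `loadings` (rotated), `rotmat` (orthogonal rotation
#'   matrix, `loadings = L %*% rotmat`), `iterations`, `criterion`.
#' @export
varimax_rotation <- function(L, normalize = TRUE, eps = 1e-6, max_iter = 500) {
  L <- as.matrix(L)
  k <- ncol(L)
  R <- diag(k)
  if (k < 2L)
    return(list(loadings = L, rotmat = R, iterations = 0L,
                criterion = varimax_criterion(L, normalize)))
  h <- rep(1, nrow(L))
  if (normalize) {
    h <- sqrt(rowSums(L^2)); h[h == 0] <- 1
    L <- L / h
  }
  p <- nrow(L)
  crit <- varimax_criterion(L, normalize = FALSE)
  it <- 0L
  repeat {
    it <- it + 1L
    for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
      x <- L[, a]; y <- L[, b]
      u <- x^2 - y^2; v <- 2 * x * y
      A <- sum(u); B <- sum(v)
      C <- sum(u^2 - v^2); D <- 2 * sum(u * v)
      num <- D - 2 * A * B / p
      den <- C - (A^2 - B^2) / p
      phi <- -atan2(num, den) / 4
      if (abs(phi) < 1e-12) next
      G <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
      L[, c(a, b)] <- L[, c(a, b)] %*% G
      R[, c(a, b)] <- R[, c(a, b)] %*% G
    }
    new_crit <- varimax_criterion(L, normalize = FALSE)
    delta <- new_crit - crit
    if (delta <= eps * max(crit, .Machine$double.eps)) break
    if (it >= max_iter)
      stop(sprintf(
        "varimax did not converge in %d sweeps (criterion %.8g, last change %.3g)",
        max_iter, new_crit, delta))
    crit <- new_crit
  }
  list(loadings = L * h, rotmat = R, iterations = it,
       criterion = varimax_criterion(L * h, normalize = normalize))
}

#' Principal components with eigenvalue-1 retention and varimax rotation
#'
#' Standardizes the variables, eigendecomposes their correlation matrix,
#' retains the components with eigenvalue at or above `min_eigenvalue`
#' (Kaiser criterion), and rotates the retained loadings with
#' Kaiser-normalized varimax. Loadings with absolute value above
#' `salient_cutoff` are flagged salient. Each rotated factor is
#' sign-oriented so its largest-magnitude loading is positive, and factors
#' are ordered by decreasing explained variance after rotation.
#'
#' @param x data.frame or matrix of numeric measures (complete cases used).
#' @param min_eigenvalue retention threshold on the correlation-matrix
#'   eigenvalues (default 1).
#' @param salient_cutoff absolute loading threshold for the salient mask
#'   (default 0.7).
#' @param rotate rotate the retained loadings (default TRUE; with a single
#'   retained factor rotation is a no-op).
#' @return a list of class `pavca_pca`: `loadings` (rotated), `unrotated`,
#'   `eigenvalues` (all), `n_retained`, `prop_variance` and `cum_variance`
#'   (per rotated factor), `communality`, `salient` (logical matrix),
#'   `rotation`, `n`, `n_dropped` (incomplete rows).
#' @export
pca_varimax <- function(x, min_eigenvalue = 1, salient_cutoff = 0.7,
                        rotate = TRUE) {
  x <- as.data.frame(x)
  if (ncol(x) < 2L) pv_stop("need at least 2 variables")
  keep <- stats::complete.cases(x)
  n_dropped <- sum(!keep)
  x <- as.matrix(x[keep, , drop = FALSE])
  if (nrow(x) < ncol(x) + 1L) pv_stop("too few complete cases")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    pv_stop(sprintf("zero variance in variable '%s'",
                    colnames(x)[sds == 0][1]))
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  kret <- sum(values >= min_eigenvalue)
  if (kret < 1L) pv_stop("no component reaches the minimum eigenvalue")
  A <- eig$vectors[, seq_len(kret), drop = FALSE] %*%
    diag(sqrt(values[seq_len(kret)]), kret)
  rownames(A) <- colnames(x)
  rot <- if (rotate && kret > 1L) varimax_rotation(A) else
    list(loadings = A, rotmat = diag(kret), iterations = 0L)
  L <- rot$loadings
  ## orient: dominant loading positive; order by explained variance
  sgn <- apply(L, 2, function(cl) sign(cl[which.max(abs(cl))]))
  sgn[sgn == 0] <- 1
  L <- sweep(L, 2, sgn, "*")
  ev <- colSums(L^2)
  ord <- order(ev, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  ev <- ev[ord]
  colnames(L) <- paste0("F", seq_len(kret))
  out <- list(
    loadings = L,
    unrotated = A,
    eigenvalues = values,
    n_retained = kret,
    prop_variance = ev / ncol(x),
    cum_variance = cumsum(ev / ncol(x)),
    communality = rowSums(L^2),
    salient = abs(L) > salient_cutoff,
    rotation = if (rotate && kret > 1L) "varimax (Kaiser-normalized)" else "none",
    salient_cutoff = salient_cutoff,
    n = nrow(x),
    n_dropped = n_dropped)
  class(out) <- "pavca_pca"
  out
}

#' @export
print.pavca_pca <- function(x, digits = 3, ...) {
  cat(sprintf("PCA: %d of %d components retained (eigenvalue >= 1), rotation: %s, n = %d\n",
              x$n_retained, length(x$eigenvalues), x$rotation, x$n))
  cat("Proportion of variance:",
      paste(sprintf("%.1f%%", 100 * x$prop_variance), collapse = ", "),
      sprintf("(cumulative %.1f%%)\n", 100 * max(x$cum_variance)))
  L <- round(x$loadings, digits)
  star <- ifelse(x$salient, "*", " ")
  disp <- matrix(paste0(format(L), star), nrow(L), ncol(L),
                 dimnames = dimnames(L))
  print(disp, quote = FALSE)
  cat(sprintf("(* |loading| > %.2f)\n", x$salient_cutoff))
  invisible(x)
}
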