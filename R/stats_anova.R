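#' Mixed-design repeated-measures ANOVA
#'
#' Univariate mixed-design F tests with Type III sums of squares and
#' sum-to-zero contrasts, the classical error strata (the between-subject
#' error for between-subject terms; the subject-by-within-factor interaction
#' for each within term and its between interactions), no sphericity
#' correction, and classical eta squared (SS of the term over the total SS).
#'
#' Internally the within-subject design is mapped onto an orthonormal
#' contrast basis: for each subset `w` of within factors the subject
#' profiles are projected onto the Kronecker product of orthonormal
#' factor contrasts (for factors in `w`) and normalized unit vectors (for
#' the rest), and every between-subject term is tested on that projection
#' with a Type III hypothesis matrix. Because the basis is orthonormal the
#' resulting sums of squares are in the units of the raw data and, on
#' balanced designs, add up to the total SS across all terms and error
#' strata.
#'
#' Subjects missing any within-subject cell are excluded casewise; the count
#' is stored in the `"n_excluded"` attribute. Rows with `NA` in the response
#' or any factor are dropped first.
#'
#' @param data long-format data.frame: one row per subject-by-within-cell
#'   observation.
#' @param dv name of the response column.
#' @param between character vector of between-subject factor columns (may be
#'   empty).
#' @param within character vector of within-subject (repeated) factor
#'   columns (may be empty; then an ordinary between-subjects ANOVA is run,
#'   one independent observation per row).
#' @param subject name of the subject identifier column.
#' @param eta `"classical"` (SS term / SS total, the default) or
#'   `"partial"` (SS term / (SS term + SS error of its stratum)).
#' @return a `data.frame` (class `pavca_anova`) with one row per model term:
#'   `term, SS, df_num, df_den, F, p, eta_squared, error_term, error_SS`.
#'   Attributes: `ss_total`, `n_subjects`, `n_excluded`, `strata` (error
#'   stratum SS/df table).
#' @export
mixed_rm_anova <- function(data, dv, between = character(), within = character(),
                           subject = "subject_id",
                           eta = c("classical", "partial")) {
  eta <- match.arg(eta)
  cols <- c(subject, between, within, dv)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    pv_stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  d <- as.data.frame(data)[, cols]
  nm <- function(pre, v) if (length(v)) paste0(pre, seq_along(v)) else character(0)
  names(d) <- c(".subj", nm(".b", between), nm(".w", within), ".y")
  ## here and below: complete cases only, then casewise exclusion
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (!nrow(d)) pv_stop("no complete cases")
  bcols <- nm(".b", between)
  wcols <- nm(".w", within)
  for (cn in c(".subj", bcols, wcols)) d[[cn]] <- factor(d[[cn]])

  n_excluded <- 0L
  if (length(within)) {
    wl <- lapply(wcols, function(cn) levels(d[[cn]]))
    n_wcell <- prod(lengths(wl))
    cell <- interaction(d[wcols], drop = FALSE, lex.order = FALSE)
    tab <- table(d$.subj, cell)
    if (any(tab > 1L))
      pv_stop("duplicate observations in a subject-by-within cell")
    complete <- rownames(tab)[rowSums(tab) == n_wcell]
    n_excluded <- nlevels(d$.subj) - length(complete)
    d <- d[d$.subj %in% complete, , drop = FALSE]
    d$.subj <- droplevels(d$.subj)
    if (!nlevels(d$.subj)) pv_stop("no subject has complete within-subject data")
    ## within-cell index in expand.grid order (first factor fastest)
    idx <- 0L; mult <- 1L
    for (j in seq_along(wcols)) {
      idx <- idx + (as.integer(d[[wcols[j]]]) - 1L) * mult
      mult <- mult * length(wl[[j]])
    }
    d$.wcell <- idx + 1L
    Y <- matrix(NA_real_, nlevels(d$.subj), n_wcell,
                dimnames = list(levels(d$.subj), NULL))
    Y[cbind(as.integer(d$.subj), d$.wcell)] <- d$.y
    subj_rows <- match(levels(d$.subj), d$.subj)
  } else {
    ## no repeated factor: every row is its own experimental unit
    Y <- matrix(d$.y, ncol = 1)
    subj_rows <- seq_len(nrow(d))
    wl <- list()
  }

  ## between-subject design (sum-to-zero, full factorial)
  bdat <- d[subj_rows, bcols, drop = FALSE]
  if (length(between)) {
    for (cn in bcols) bdat[[cn]] <- droplevels(bdat[[cn]])
    if (length(within)) {
      chk <- unique(d[, c(".subj", bcols)])
      if (nrow(chk) != nlevels(d$.subj))
        pv_stop("a subject appears under more than one between-group cell")
    }
    fml <- stats::as.formula(paste("~", paste(bcols, collapse = "*")))
    ctr <- stats::setNames(rep(list("contr.sum"), length(bcols)), bcols)
    X <- stats::model.matrix(fml, bdat, contrasts.arg = ctr)
    term_lab <- attr(stats::terms(fml), "term.labels")
    lab_map <- stats::setNames(between, bcols)
    term_lab_pretty <- vapply(strsplit(term_lab, ":"), function(p)
      paste(lab_map[p], collapse = ":"), "")
  } else {
    X <- matrix(1, nrow(Y), 1, dimnames = list(NULL, "(Intercept)"))
    attr(X, "assign") <- 0L
    term_lab_pretty <- character(0)
  }
  asg <- attr(X, "assign")
  if (qr(X)$rank < ncol(X))
    pv_stop("singular between-subjects design (empty cell?)")
  XtX <- crossprod(X)
  XtXi <- solve(XtX)
  n_subj <- nrow(Y)
  p_btw <- ncol(X)
  if (n_subj <= p_btw) pv_stop("not enough subjects for the between design")

  ## orthonormal within-contrast blocks
  orth_contr <- function(l) {
    qr.Q(qr(cbind(1, stats::contr.sum(l))))[, -1, drop = FALSE]
  }
  Cs <- lapply(wl, function(lv) orth_contr(length(lv)))
  Us <- lapply(wl, function(lv) matrix(1 / sqrt(length(lv)), length(lv), 1))

  grand <- mean(Y)
  ss_total <- sum((Y - grand)^2)

  subsets <- if (length(within)) {
    do.call(expand.grid, rep(list(c(FALSE, TRUE)), length(within)))
  } else data.frame(matrix(logical(0), nrow = 1, ncol = 0))

  rows <- list(); strata <- list()
  for (si in seq_len(nrow(subsets))) {
    inw <- as.logical(subsets[si, ])
    M <- matrix(1, 1, 1)
    for (j in seq_along(wl))              # factor j innermost in the cell order
      M <- kronecker(if (inw[j]) Cs[[j]] else Us[[j]], M)
    Z <- Y %*% M
    q <- ncol(Z)
    Bhat <- XtXi %*% crossprod(X, Z)
    R <- Z - X %*% Bhat
    sse <- sum(R * R)
    df_err <- (n_subj - p_btw) * q
    wlab <- paste(within[inw], collapse = ":")
    err_lab <- if (nzchar(wlab)) paste0("subject:", wlab) else "subject"
    strata[[length(strata) + 1L]] <-
      data.frame(stratum = err_lab, SS = sse, df = df_err)
    for (t in unique(asg)) {
      if (t == 0L && !any(inw)) next      # grand mean: not a reportable term
      sel <- which(asg == t)
      LB <- Bhat[sel, , drop = FALSE]
      V <- XtXi[sel, sel, drop = FALSE]
      H <- crossprod(LB, solve(V, LB))
      ss <- sum(diag(as.matrix(H)))
      df_num <- length(sel) * q
      blab <- if (t == 0L) "" else term_lab_pretty[t]
      lab <- paste(c(if (nzchar(blab)) blab, if (nzchar(wlab)) wlab),
                   collapse = ":")
      Fv <- (ss / df_num) / (sse / df_err)
      rows[[length(rows) + 1L]] <- data.frame(
        term = lab, SS = ss, df_num = df_num, df_den = df_err, F = Fv,
        p = stats::pf(Fv, df_num, df_err, lower.tail = FALSE),
        eta_squared = if (eta == "classical") ss / ss_total else ss / (ss + sse),
        error_term = err_lab, error_SS = sse)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pavca_anova", "data.frame")
  attr(out, "ss_total") <- ss_total
  attr(out, "n_subjects") <- n_subj
  attr(out, "n_excluded") <- n_excluded
  attr(out, "strata") <- do.call(rbind, strata)
  attr(out, "eta") <- eta
  out
}

#' @export
print.pavca_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Mixed RM-ANOVA (Type III, %s eta^2); %d subjects, %d excluded casewise\n",
              attr(x, "eta") %||% "classical",
              attr(x, "n_subjects"), attr(x, "n_excluded")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted pairwise comparisons of group means against a
#' pooled error term (Tukey-Kramer for unequal group sizes). The error
#' mean square and its degrees of freedom should come from the stratum that
#' matches the probed effect (the between-subject error for a between
#' factor, the subject-by-within error for a within factor).
#'
#' @param means named vector of group means.
#' @param n per-group sample sizes (scalar or vector aligned with `means`).
#' @param ms_error pooled error mean square.
#' @param df_error degrees of freedom of the error term.
#' @param conf_level confidence level for the simultaneous intervals.
#' @return a `data.frame` with one row per pair: `contrast, diff, se, q,
#'   p_adj, lwr, upr`. Zero rows when fewer than two groups.
#' @export
tukey_hsd <- function(means, n, ms_error, df_error, conf_level = 0.95) {
  k <- length(means)
  if (is.null(names(means))) names(means) <- paste0("g", seq_len(k))
  n <- rep_len(n, k)
  if (k < 2L)
    return(data.frame(contrast = character(0), diff = numeric(0),
                      se = numeric(0), q = numeric(0), p_adj = numeric(0),
                      lwr = numeric(0), upr = numeric(0)))
  pr <- utils::combn(k, 2)
  diff <- means[pr[2, ]] - means[pr[1, ]]
  se <- sqrt(ms_error / 2 * (1 / n[pr[1, ]] + 1 / n[pr[2, ]]))
  qstat <- abs(diff) / se
  p <- stats::ptukey(qstat, nmeans = k, df = df_error, lower.tail = FALSE)
  hw <- stats::qtukey(conf_level, nmeans = k, df = df_error) * se
  data.frame(
    contrast = paste(names(means)[pr[2, ]], "-", names(means)[pr[1, ]]),
    diff = unname(diff), se = unname(se), q = unname(qstat),
    p_adj = unname(p), lwr = unname(diff - hw), upr = unname(diff + hw),
    row.names = NULL)
}

#' @rdname tukey_hsd
#' @param y response vector; `g` grouping vector. Convenience wrapper that
#'   derives the cell means and the pooled within-group error from the data.
#' @param g grouping vector.
#' @export
tukey_hsd_groups <- function(y, g, conf_level = 0.95) {
  g <- factor(g)
  keep <- stats::complete.cases(y, g)
  y <- y[keep]; g <- droplevels(g[keep])
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  df_err <- length(y) - nlevels(g)
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df_err
  tukey_hsd(means, ns, mse, df_err, conf_level = conf_level)
}
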