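# independent oracles: plain-loop recomputations, no package internals

# PavCA index recomputed straight from raw events of one subject-session,
# without any intermediate session summary
oracle_index_from_events <- function(events, cs = 8) {
  ev <- as.data.frame(events)
  ev <- ev[order(ev$time_s), ]
  ons <- ev[ev$event == "cs_onset" & ev$trial > 0, ]
  nT <- nrow(ons)
  lat_lev <- lat_fc <- numeric(nT)
  n_lev <- n_fc <- 0
  hit_lev <- hit_fc <- 0
  for (i in seq_len(nT)) {
    tr <- ons$trial[i]; t0 <- ons$time_s[i]
    t1 <- ev$time_s[ev$event == "cs_offset" & ev$trial == tr][1]
    lv <- ev$time_s[ev$event == "lever_deflection" & ev$trial == tr]
    lv <- lv[lv >= t0 & lv < t1]
    fc <- ev$time_s[ev$event == "foodcup_entry" & ev$trial == tr]
    fc <- fc[fc >= t0 & fc < t1]
    n_lev <- n_lev + length(lv); n_fc <- n_fc + length(fc)
    hit_lev <- hit_lev + (length(lv) > 0); hit_fc <- hit_fc + (length(fc) > 0)
    lat_lev[i] <- if (length(lv)) min(lv) - t0 else cs
    lat_fc[i] <- if (length(fc)) min(fc) - t0 else cs
  }
  pd <- hit_lev / nT - hit_fc / nT
  rb <- if (n_lev + n_fc == 0) 0 else (n_lev - n_fc) / (n_lev + n_fc)
  ls <- (mean(lat_fc) - mean(lat_lev)) / cs
  (pd + rb + ls) / 3
}

# brute-force RM-ANOVA by explicit summation over marginal means
# (balanced complete designs, one observation per subject-by-within cell)
oracle_rm_anova <- function(df, dv, between = character(), within = character(),
                            subject = "subject_id") {
  df <- as.data.frame(df)
  y <- df[[dv]]
  N <- length(y)
  facs <- c(between, within)
  for (f in c(subject, facs)) df[[f]] <- factor(df[[f]])
  lev <- lapply(df[facs], levels)
  subsets_of <- function(x)
    unlist(lapply(0:length(x), function(k) utils::combn(x, k, simplify = FALSE)),
           recursive = FALSE)
  mean_at <- function(vars, combo) {
    keep <- rep(TRUE, N)
    for (i in seq_along(vars)) keep <- keep & df[[vars[i]]] == combo[[i]]
    mean(y[keep])
  }
  term_ss <- function(T) {
    combos <- expand.grid(lev[T], stringsAsFactors = FALSE)
    eff <- numeric(nrow(combos))
    for (r in seq_len(nrow(combos))) {
      cb <- as.list(combos[r, , drop = FALSE])
      tot <- 0
      for (U in subsets_of(T)) {
        sgn <- (-1)^(length(T) - length(U))
        m <- if (length(U)) mean_at(U, cb[U]) else mean(y)
        tot <- tot + sgn * m
      }
      eff[r] <- tot
    }
    list(SS = (N / nrow(combos)) * sum(eff^2),
         df = prod(vapply(T, function(f) length(lev[[f]]) - 1L, 1L)))
  }
  subj_ids <- levels(df[[subject]])
  n_subj <- length(subj_ids)
  bcell <- if (length(between))
    vapply(subj_ids, function(s)
      paste(sapply(between, function(f) as.character(df[[f]][df[[subject]] == s][1])),
            collapse = "|"), "")
  else rep("all", n_subj)
  n_bcell <- length(unique(bcell))
  k_per_subj <- N / n_subj
  m_subj <- vapply(subj_ids, function(s) mean(y[df[[subject]] == s]), 0)
  m_bcell <- vapply(subj_ids, function(s) mean(y[bcell[match(df[[subject]], subj_ids)] == bcell[match(s, subj_ids)]]), 0)
  err <- list()
  err[["."]] <- list(SS = k_per_subj * sum((m_subj - m_bcell)^2),
                     df = n_subj - n_bcell)
  for (w in subsets_of(within)) {
    if (!length(w)) next
    combos <- expand.grid(lev[w], stringsAsFactors = FALSE)
    ss <- 0
    for (si in seq_along(subj_ids)) {
      s <- subj_ids[si]
      in_s <- df[[subject]] == s
      in_c <- bcell[match(df[[subject]], subj_ids)] == bcell[si]
      for (r in seq_len(nrow(combos))) {
        cb <- as.list(combos[r, , drop = FALSE])
        e <- 0
        for (U in subsets_of(w)) {
          sgn <- (-1)^(length(w) - length(U))
          keep <- rep(TRUE, N)
          for (i in seq_along(U)) keep <- keep & df[[U[i]]] == cb[[U[i]]]
          e <- e + sgn * (mean(y[in_s & keep]) - mean(y[in_c & keep]))
        }
        ss <- ss + e^2
      }
    }
    r_rep <- k_per_subj / nrow(combos)
    err[[paste(sort(w), collapse = "|")]] <-
      list(SS = r_rep * ss,
           df = (n_subj - n_bcell) * prod(vapply(w, function(f) length(lev[[f]]) - 1L, 1L)))
  }
  terms <- Filter(length, subsets_of(facs))
  out <- do.call(rbind, lapply(terms, function(T) {
    t_ss <- term_ss(T)
    w <- intersect(T, within)
    e <- err[[if (length(w)) paste(sort(w), collapse = "|") else "."]]
    Fv <- (t_ss$SS / t_ss$df) / (e$SS / e$df)
    data.frame(term = paste(T, collapse = ":"), SS = t_ss$SS, df_num = t_ss$df,
               df_den = e$df, F = Fv,
               p = stats::pf(Fv, t_ss$df, e$df, lower.tail = FALSE),
               error_SS = e$SS)
  }))
  rownames(out) <- NULL
  out
}

# Tukey adjusted p by permutation of the max studentized range statistic
oracle_tukey_perm <- function(y, g, B = 100000) {
  g <- factor(g)
  k <- nlevels(g); n <- length(y)
  ns <- as.vector(table(g))
  G <- outer(g, levels(g), "==") * 1
  qstats <- function(yy) {
    m <- as.vector(crossprod(G, yy)) / ns
    mse <- (sum(yy^2) - sum(ns * m^2)) / (n - k)
    pr <- utils::combn(k, 2)
    abs(m[pr[2, ]] - m[pr[1, ]]) /
      sqrt(mse / 2 * (1 / ns[pr[1, ]] + 1 / ns[pr[2, ]]))
  }
  q_obs <- qstats(y)
  qmax <- numeric(B)
  for (b in seq_len(B)) qmax[b] <- max(qstats(y[sample.int(n)]))
  vapply(q_obs, function(q) mean(qmax >= q), 0)
}

random_orthogonal <- function(k) {
  qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
}
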