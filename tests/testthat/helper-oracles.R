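# Independent brute-force oracles and small-cohort generators used across
# the suite. These are deliberately naive re-derivations from first
# principles: loops over sorted times and exhaustive pair enumeration,
# sharing no code with the package's estimators.

# random competing-risk cohort; tie_prob > 0 rounds times onto a coarse grid
random_cohort_raw <- function(n, tie_prob = 0.5, p_cens = 0.3, p_comp = 0.3) {
  tm <- rexp(n, 0.5) + 0.01
  if (runif(1) < tie_prob) tm <- ceiling(tm * 4) / 4
  p1 <- max(1 - p_cens - p_comp, 0.05)
  ev <- sample(0:2, n, replace = TRUE,
               prob = c(p_cens, p1, p_comp) / (p_cens + p1 + p_comp))
  list(time = tm, event = ev)
}

# product-limit survival by explicit looping over sorted unique times
oracle_km <- function(time, status, t_eval) {
  ut <- sort(unique(time))
  s <- 1
  for (u in ut) {
    if (u > t_eval) break
    n_risk <- sum(time >= u)
    d <- sum(time == u & status == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# Aalen-Johansen cause-k incidence by explicit looping
oracle_aj <- function(time, event, t_eval, cause = 1) {
  ut <- sort(unique(time))
  s_prev <- 1
  f <- 0
  for (u in ut) {
    n_risk <- sum(time >= u)
    d_all <- sum(time == u & event != 0)
    d_k <- sum(time == u & event == cause)
    if (u <= t_eval) f <- f + s_prev * d_k / n_risk
    s_prev <- s_prev * (1 - d_all / n_risk)
    if (u > t_eval) break
  }
  f
}

# exhaustive pair enumeration; `inf_flag` marks subjects treated as
# event-free beyond every time; `tau` truncates anchor event times;
# in ipcw mode partners qualify when later or competing, and the pair takes
# the anchor's weight
oracle_concordance <- function(time, status, risk, inf_flag = NULL,
                               tau = Inf, ipcw = FALSE, competing = NULL,
                               weight = NULL) {
  n <- length(time)
  if (is.null(inf_flag)) inf_flag <- rep(FALSE, n)
  if (is.null(weight)) weight <- rep(1, n)
  if (is.null(competing)) competing <- rep(FALSE, n)
  conc <- disc <- tied <- 0
  for (i in seq_len(n)) {
    if (status[i] != 1 || inf_flag[i] || time[i] > tau) next
    for (j in seq_len(n)) {
      if (j == i) next
      ok <- if (ipcw) {
        time[j] > time[i] || competing[j]
      } else {
        inf_flag[j] || time[j] > time[i] ||
          (time[j] == time[i] && status[j] == 0 && !inf_flag[j])
      }
      if (!ok) next
      if (risk[i] > risk[j]) conc <- conc + weight[i]
      else if (risk[i] < risk[j]) disc <- disc + weight[i]
      else tied <- tied + weight[i]
    }
  }
  if (conc + disc + tied == 0) return(NA_real_)
  (conc + 0.5 * tied) / (conc + disc + tied)
}

# tiny wrapper: cohort tibble from vectors with a single risk column
make_cohort <- function(time, event, risk = NULL, horizon = 2, ...) {
  if (is.null(risk)) risk <- rep(0.5, length(time))
  df <- tibble::tibble(id = seq_along(time), time = time, event = event, ...)
  df[[paste0("risk_", horizon, "y")]] <- risk
  as_cohort(df, horizons = horizon)
}
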