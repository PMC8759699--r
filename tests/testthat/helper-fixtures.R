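# Shared fixtures: all built in code at test time.

# Preset with every noise source switched off: the centre subject.
noise_free_preset <- function(label) {
  p <- cohort_preset(label)
  p$between_subject_cv <- 0
  p$measurement_cv <- 0
  p$measurement_cv_insulin <- 0
  p
}

# Small hand-built series on a short schedule.
toy_series <- function(times = c(-60, 0, 2, 5, 7, 10, 15, 19, 22, 25, 30,
                                 35, 40, 50, 60, 75, 90, 120, 150, 180),
                       glucose = NULL, insulin = NULL,
                       id = "s1", group = "foal") {
  n <- length(times)
  if (is.null(glucose)) glucose <- seq(300, 100, length.out = n)
  if (is.null(insulin)) insulin <- rep(10, n)
  subject_series(id, group, times, glucose, insulin)
}

cohort_ids_for_test <- function(co) {
  vapply(co$subjects, function(s) s$subject_id, character(1))
}

# Write a cohort data frame to a temp CSV and return the path.
write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Exact two-sided Mann-Whitney p by enumerating all C(n, nx) group
# labelings of the pooled sample (mirrors the tail-doubling convention).
brute_force_mw_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  n <- length(pooled)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(x, y)
  combos <- utils::combn(n, nx)
  us <- apply(combos, 2, function(idx) {
    u_stat(pooled[idx], pooled[-idx])
  })
  m <- nx * (n - nx)
  p <- if (u_obs > m / 2) 2 * mean(us >= u_obs) else 2 * mean(us <= u_obs)
  min(1, p)
}

# Exact two-sided Spearman p by enumerating all n! pairings in R.
brute_force_spearman_p <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rhos <- vapply(perms(ry), function(p) abs(stats::cor(rx, p)), numeric(1))
  mean(rhos >= obs - 1e-12)
}
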