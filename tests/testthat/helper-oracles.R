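# Independent oracles and small fixture builders used across test files.

# Brute-force adjusted-qini oracle: re-ranks each arm from scratch and counts
# survivors with explicit loops, independently of the package's vectorized
# implementation.
qini_oracle_curve <- function(scores, treated, survived, grid, ids) {
  treated <- as.logical(treated)
  y <- as.integer(as.logical(survived))
  ids <- as.character(ids)
  arm_order <- function(sel) {
    sc <- scores[sel]; id <- ids[sel]
    idx <- seq_along(sc)
    # selection sort by (score desc, id asc): deliberately naive
    for (i in seq_along(idx)) {
      best <- i
      for (j in seq_along(idx)) {
        if (j <= i - 1) next
        if (sc[idx[j]] > sc[idx[best]] ||
            (sc[idx[j]] == sc[idx[best]] && id[idx[j]] < id[idx[best]]))
          best <- j
      }
      tmp <- idx[i]; idx[i] <- idx[best]; idx[best] <- tmp
    }
    y[sel][idx]
  }
  t_out <- arm_order(treated)
  c_out <- arm_order(!treated)
  N_t <- length(t_out); N_c <- length(c_out)
  sapply(grid, function(phi) {
    if (phi == 0) return(0)
    n_t <- ceiling(phi * N_t); n_c <- ceiling(phi * N_c)
    n_t1 <- 0; for (k in seq_len(n_t)) n_t1 <- n_t1 + t_out[k]
    n_c1 <- 0; for (k in seq_len(n_c)) n_c1 <- n_c1 + c_out[k]
    n_t1 / N_t - n_c1 * n_t / (N_t * n_c)
  })
}

# Rule-by-rule KDIGO oracle: evaluates every staging rule independently and
# returns the highest stage any rule assigns.
kdigo_oracle <- function(scr_ratio, scr_increase_48h, scr_absolute,
                         uo_rate_6h, uo_rate_12h, uo_rate_24h,
                         anuria_12h, on_rrt) {
  stages <- 0L
  if (scr_ratio >= 1.5 && scr_ratio < 2.0) stages <- c(stages, 1L)
  if (scr_increase_48h >= 0.3) stages <- c(stages, 1L)
  if (uo_rate_6h < 0.5) stages <- c(stages, 1L)
  if (scr_ratio >= 2.0 && scr_ratio < 3.0) stages <- c(stages, 2L)
  if (uo_rate_12h < 0.5) stages <- c(stages, 2L)
  if (scr_ratio >= 3.0) stages <- c(stages, 3L)
  if (scr_absolute >= 4.0) stages <- c(stages, 3L)
  if (uo_rate_24h < 0.3) stages <- c(stages, 3L)
  if (anuria_12h) stages <- c(stages, 3L)
  if (on_rrt) stages <- c(stages, 3L)
  max(stages)
}

# Randomized 50/50 synthetic cohort with the default heterogeneous effect.
randomized_cohort <- function(n, seed, ...) {
  generate_cohort(sim_config(n_patients = n, treat_fraction_target = 0.5,
                             confounding_strength = 0, seed = seed, ...))
}

# Default full feature set of the synthetic schema.
schema_features <- function() names(default_covariate_spec())
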