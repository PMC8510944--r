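# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: factorial enumeration for the exact test,
# cell-mean sums of squares for the split-plot ANOVA.

# Two-sided Fisher p by brute-force enumeration over the hypergeometric
# support, with probabilities from factorials directly.
enumerate_fisher_p <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  prob_of <- function(x) {
    # P(table | margins) = choose(r1, x) choose(r2, c1 - x) / choose(n, c1)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, prob_of, numeric(1))
  p_obs <- prob_of(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Split-plot F statistics from cell/subject means (balanced designs).
# data: subject, group, time, value; every subject has every timepoint.
splitplot_oracle <- function(data) {
  d <- data
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$time <- factor(d$time)
  N <- nrow(d)
  k <- nlevels(d$time)
  grand <- mean(d$value)
  subj_means <- tapply(d$value, d$subject, mean)
  subj_group <- tapply(as.character(d$group), d$subject, `[`, 1)
  group_means <- tapply(d$value, d$group, mean)
  time_means <- tapply(d$value, d$time, mean)
  cell_means <- tapply(d$value, list(d$group, d$time), mean)
  n_per_group <- table(subj_group)

  ss_group <- k * sum(n_per_group * (group_means[names(n_per_group)] -
                                       grand)^2)
  ss_subj_within <- k * sum((subj_means - group_means[subj_group])^2)
  n_subj_total <- length(subj_means)
  ss_time <- n_subj_total * sum((time_means - grand)^2)
  ss_cells <- 0
  for (g in rownames(cell_means)) for (tt in colnames(cell_means)) {
    ss_cells <- ss_cells + n_per_group[[g]] *
      (cell_means[g, tt] - grand)^2
  }
  ss_gt <- ss_cells - ss_group - ss_time
  ss_total <- sum((d$value - grand)^2)
  ss_resid <- ss_total - ss_group - ss_subj_within - ss_time - ss_gt

  df_group <- nlevels(d$group) - 1
  df_subj <- n_subj_total - nlevels(d$group)
  df_time <- k - 1
  df_gt <- df_group * df_time
  df_resid <- df_subj * df_time

  F_group <- (ss_group / df_group) / (ss_subj_within / df_subj)
  F_time <- (ss_time / df_time) / (ss_resid / df_resid)
  F_gt <- (ss_gt / df_gt) / (ss_resid / df_resid)
  list(F_group = F_group, F_time = F_time, F_gt = F_gt,
       df = c(group = df_group, subj = df_subj, time = df_time,
              gt = df_gt, resid = df_resid))
}

# Analytic wall pressure behind a normal shock reflecting off a rigid wall:
# p5/p2 as a function of the incident pressure ratio p2/p1.
reflected_pressure_ratio <- function(p21, gamma = 1.4) {
  ((3 * gamma - 1) * p21 - (gamma - 1)) /
    ((gamma - 1) * p21 + (gamma + 1))
}

# Sod reference solution sampled on cell centers at time t
sod_reference <- function(x, t, x0 = 0.5, gamma = 1.4) {
  sol <- riemann_exact(c(1, 0, 1), c(0.125, 0, 0.1), gamma)
  riemann_sample(sol, (x - x0) / t)
}
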