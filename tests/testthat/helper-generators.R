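# Direct longitudinal-design generator (no game simulation): two visits per
# subject with the study's age structure and a linear mixed-effects outcome
# with known coefficients.

make_lmm_cohort <- function(n = 120, b_long = 0.27, b_cs = 0.3, b_int = 0,
                            sd_subj = 1, sd_eps = 1, seed = 1) {
  set.seed(seed)
  age1 <- runif(n, 14, 25)
  interval <- pmax(0.5, rnorm(n, 1.48, 0.29))
  age <- c(age1, age1 + interval)
  subject_id <- rep(sprintf("s%03d", 1:n), 2)
  sex <- rep(sample(c("female", "male"), n, replace = TRUE), 2)
  d <- data.frame(subject_id, age, sex)
  d <- decompose_age(d)
  u <- rep(rnorm(n, 0, sd_subj), 2)
  d$y <- 10 + b_long * d$longitudinal_age + b_cs * d$cross_sectional_age +
    b_int * d$longitudinal_age * d$cross_sectional_age +
    u + rnorm(2 * n, 0, sd_eps)
  d
}
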