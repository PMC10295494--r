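# Small deterministic cohort built in code, used by io/derive tests.
toy_cohort <- function(n = 6) {
  set.seed(20260101)
  dbp <- round(stats::runif(n, 75, 95), 1)
  dia <- round(stats::runif(n, 28, 38), 2)
  data.frame(
    id = sprintf("T%02d", seq_len(n)),
    age = round(stats::runif(n, 50, 75), 1),
    sex = rep(c("male", "female"), length.out = n),
    height = round(stats::runif(n, 1.55, 1.85), 2),
    body_mass = round(stats::runif(n, 55, 95), 1),
    sbp = dbp + round(stats::runif(n, 35, 70), 1),
    dbp = dbp,
    ao_diastolic_diameter = dia,
    ao_systolic_diameter = dia * (1 + stats::runif(n, 0.005, 0.08)),
    eat_thickness = round(stats::runif(n, 4, 16), 2),
    eat_volume = round(stats::runif(n, 25, 110), 2),
    stringsAsFactors = FALSE
  )
}

# A record carrying the cohort-level mean measurements, for composition
# checks of the derivation chain.
mean_record <- function() {
  data.frame(
    id = "MEAN", age = 63.48, sex = "female", height = 1.67,
    body_mass = 74.16, sbp = 143.20, dbp = 88.40,
    ao_diastolic_diameter = 33.42, ao_systolic_diameter = 34.50,
    eat_thickness = 9.51, eat_volume = 60.03,
    stringsAsFactors = FALSE
  )
}

# Brute-force pairwise (tie-corrected U statistic) AUC oracle.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
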