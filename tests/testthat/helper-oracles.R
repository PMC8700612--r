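# Independent single-expression oracles for the printed dosing formulas and
# the supporting statistics. Deliberately written as one-liners with literal
# constants so they share no code with the implementation under test.

oracle_ref_cr1 <- function(W, H, G, A)
  exp(1.8 - 0.028 * W + 0.00005 * W^2 + 0.0087 * H + 0.06 * G - 0.0021 * A)

oracle_ref_cr2 <- function(W, H, G, A)
  exp(1.621 - 0.020 * W + 0.008 * H + 0.06 * G - 0.002 * A)

oracle_dose1 <- function(W, H, G, A, CRT)
  550 - (oracle_ref_cr1(W, H, G, A) - CRT) / 0.00756

oracle_dose2 <- function(W, H, G, A, CRT)
  550 * CRT / oracle_ref_cr2(W, H, G, A)

# brute-force normal-equations OLS
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - sy / n)^2)
  list(slope = slope, intercept = intercept, r_squared = 1 - ss_res / ss_tot)
}

# closed-form inversion of the large-sample lognormal R^2 expression
oracle_sigma <- function(target_r2, x) {
  mu <- mean(x); s <- var(x)
  sqrt(log((s / target_r2 + mu^2) / (s + mu^2)))
}

# uniform random patients spanning the plausibility box
random_patients <- function(n, seed) {
  set.seed(seed)
  as_patients(data.frame(
    id = sprintf("r%05d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_years = runif(n, 15, 95),
    height_cm = runif(n, 140, 200),
    weight_kg = runif(n, 40, 140)
  ))
}

sex_code01 <- function(sex) ifelse(sex == "male", 1, 0)
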