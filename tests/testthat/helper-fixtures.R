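# shared fixtures and independent oracles

default_schema <- bmi_schema()

make_prev <- function(p, stratum = "F", schema = default_schema,
                      effective_n = NA_real_, year = NA_integer_) {
  prevalence_table(stratum = rep(stratum, length(p)),
                   category = schema$label[seq_along(p)],
                   proportion = p, effective_n = effective_n, year = year)
}

rr_row <- function(rr, lo = rr, hi = rr, cancer = "c", sex = "F", inc = 5) {
  rr_table(cancer, sex, inc, rr, lo, hi)
}

paper_rr_path <- system.file("extdata", "wcrf_rr_table1.csv", package = "pifcost")
paper_t2_path <- system.file("extdata", "attribution_2030_table2.csv",
                             package = "pifcost")

# longhand DerSimonian-Laird oracle: moment estimator of tau^2 from
# Cochran's Q, then inverse-variance pooling with w* = 1/(se^2 + tau^2)
dl_oracle <- function(log_rr, se) {
  w <- 1 / se^2
  ybar <- sum(w * log_rr) / sum(w)
  Q <- sum(w * (log_rr - ybar)^2)
  k <- length(log_rr)
  c_fac <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / c_fac)
  ws <- 1 / (se^2 + tau2)
  mu <- sum(ws * log_rr) / sum(ws)
  se_mu <- sqrt(1 / sum(ws))
  list(mu = mu, se = se_mu, tau2 = tau2,
       ci = mu + c(-1, 1) * qnorm(0.975) * se_mu)
}

# brute-force PIF oracle: expected cancer cases enumerated in a finite
# population whose category counts realise the proportions exactly
pif_bruteforce <- function(counts, counts_cf, rr) {
  base <- sum(counts * rr)
  (base - sum(counts_cf * rr)) / base
}
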