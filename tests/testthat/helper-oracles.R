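# independent brute-force oracle: age every birth cohort to the reference
# year with an explicit per-cohort, per-year survival loop (no reuse of the
# package's survival function)
brute_force_prevalence <- function(incidence, rates, max_age, reference_year,
                                   component = "point") {
  total <- 0
  by_age <- numeric(max_age + 1)
  for (birth_year in (reference_year - max_age):reference_year) {
    i0 <- incidence[[component]][match(birth_year, incidence$year)]
    age_now <- reference_year - birth_year
    alive <- i0
    if (age_now > 0) {
      for (a in 0:(age_now - 1)) alive <- alive * (1 - rates[a + 1])
    }
    if (age_now > max_age) alive <- 0
    by_age[age_now + 1] <- by_age[age_now + 1] + alive
    total <- total + alive
  }
  list(total = total, by_age = by_age)
}
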