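# Independent brute-force oracles, kept deliberately naive: they loop over
# years and rebuild every survival product from scratch rather than reusing
# the engine's vectorised cumulative products.

# discounted person-years by year-by-year enumeration
oracle_dpy <- function(initial_count, q, rate) {
  total <- 0
  for (t in seq_along(q) - 1L) {
    alive <- initial_count
    for (s in seq_len(t)) alive <- alive * (1 - q[s])
    total <- total + alive * (1 + rate)^(-t)
  }
  total
}

# survivors at the start of each year, same naive style
oracle_survivors <- function(initial_count, q) {
  vapply(seq_along(q) - 1L, function(t) {
    alive <- initial_count
    for (s in seq_len(t)) alive <- alive * (1 - q[s])
    alive
  }, numeric(1))
}

# closed-form annuity-due factor sum_{t=0}^{T-1} (1+r)^-t
annuity_due <- function(T, r) {
  if (r == 0) return(T)
  v <- 1 / (1 + r)
  (1 - v^T) / (1 - v)
}

random_schedule <- function(start_age, q_max = 0.2) {
  ages <- start_age:64
  data.frame(age = ages, q = stats::runif(length(ages), 0, q_max))
}

small_panel <- function(seed = 101, n = 4) {
  gen_dataset(synth_spec(n_countries = n, seed = seed))
}
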