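# Shared fixtures and independent oracles for the test suite.

# Small annotation catalog with a controllable shared-name block.
toy_catalog <- function(species, n, shared_names = character(),
                        prefix = species) {
  n_shared <- length(shared_names)
  ann <- c(shared_names,
           sprintf("%s private protein %04d", prefix,
                   seq_len(max(0, n - n_shared))))
  new_annotation_catalog(
    data.frame(transcript_id = sprintf("%s_t%04d", species, seq_len(n)),
               annotation = ann[seq_len(n)], stringsAsFactors = FALSE),
    species_id = species)
}

toy_survival <- function(temps, dead, total = 10L, tubes = 1L,
                         species = "sp") {
  rows <- do.call(rbind, lapply(seq_along(temps), function(i) {
    data.frame(species = species, temperature = temps[i],
               tube_id = paste0("tube", seq_len(tubes)),
               n_total = total,
               n_dead = rep(dead[i], tubes), stringsAsFactors = FALSE)
  }))
  new_survival_table(rows)
}

# Independent ML oracle: direct Nelder-Mead maximization of the binomial
# log-likelihood, no IRLS.
logistic_ml_oracle <- function(obs) {
  nll <- function(b) {
    eta <- b[1] + b[2] * obs$temperature
    -sum(obs$n_dead * eta - obs$n_total * log1p(exp(eta)))
  }
  start <- c(-mean(obs$temperature), 1)
  fit <- optim(start, nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 20000))
  fit2 <- optim(fit$par, nll, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 20000))
  fit2$par
}

# Naive recomputation of the TMM trimmed weighted mean: explicit sort
# and subset, one sample at a time.
tmm_oracle <- function(m, logratio_trim = 0.30, sum_trim = 0.05) {
  lib <- colSums(m)
  f75 <- sapply(seq_len(ncol(m)),
                function(j) quantile(m[, j], 0.75, names = FALSE) / lib[j])
  ref <- which.min(abs(f75 - mean(f75)))
  raw <- sapply(seq_len(ncol(m)), function(j) {
    keep <- m[, j] > 0 & m[, ref] > 0
    o <- m[keep, j]
    r <- m[keep, ref]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- (log2(o / lib[j]) + log2(r / lib[ref])) / 2
    w <- 1 / ((lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r))
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    lo_m <- floor(n * logratio_trim) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * sum_trim) + 1
    hi_a <- n + 1 - lo_a
    keep2 <- rank(M) >= lo_m & rank(M) <= hi_m &
      rank(A) >= lo_a & rank(A) <= hi_a
    2^(sum((M * w)[keep2]) / sum(w[keep2]))
  })
  raw / exp(mean(log(raw)))
}

# Full-enumeration Fisher oracle: every table with the observed margins,
# probabilities from lgamma-based hypergeometric mass.
fisher_enum_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  point <- function(a) {
    exp(lgamma(r1 + 1) - lgamma(a + 1) - lgamma(r1 - a + 1) +
          lgamma(r2 + 1) - lgamma(c1 - a + 1) - lgamma(r2 - c1 + a + 1) -
          (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(n - c1 + 1)))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(support, point, 0)
  p_obs <- point(m[1, 1])
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

within_id <- function(spec, id) {
  spec$species_id <- id
  spec
}

# A miniature six-species study for fast end-to-end tests.
tiny_study <- function(seed = 1L) {
  simulate_study(default_study_specs(scale = 1 / 200), seed = seed,
                 n_orthogroups = 120L, shared_pool_size = 600L)
}
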