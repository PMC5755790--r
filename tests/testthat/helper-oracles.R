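# Independent oracles, deliberately sharing no code with the package.

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# 2x2 tables with the observed margins.
fisher_p_enum <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up, written out directly.
bh_enum <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- val
    prev <- val
  }
  q
}

# Set-arithmetic Tanimoto on 0/1 membership vectors.
tanimoto_bits <- function(universe_size, a, b) {
  va <- vb <- logical(universe_size)
  va[a] <- TRUE
  vb[b] <- TRUE
  sum(va & vb) / sum(va | vb)
}

# Fingerprinted toy library, computed once per test run.
fixture_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(
        fingerprint_compounds(make_compound_library()))
    }
    cache
  }
})

fixture_drugs <- function() {
  lib <- fixture_library()
  lib[lib$role == "drug", ]
}

fixture_metabolites <- function() {
  lib <- fixture_library()
  lib[lib$role == "metabolite", ]
}

# Screening fixture: toy network with transporter and co-substrate.
screening_model <- function() {
  make_toy_model(fixture_spec(transporter_bound = 1000,
                              cosubstrate_bound = 1000))
}
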