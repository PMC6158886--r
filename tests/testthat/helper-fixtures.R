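# Shared fixtures: small fitness summaries and random lattices built in code.

# fitness summary over the 16 genotypes with given strain means / sems
make_summary <- function(w, sem = 0, environment = "X") {
  codes <- genotype_codes()
  data.frame(genotype = codes, environment = environment,
             w = rep_len(w, 16), sem = rep_len(sem, 16),
             stringsAsFactors = FALSE)
}

# exactly multiplicative lattice from per-gene factors
multiplicative_summary <- function(factors, sem = 0, environment = "X") {
  codes <- genotype_codes()
  w <- vapply(codes, function(cd) prod(factors[reduced_genes(cd)]), numeric(1))
  make_summary(unname(w), sem, environment)
}

# random fitness lattice
random_summary <- function(seed) {
  set.seed(seed)
  make_summary(runif(16, 0.7, 1.3), runif(16, 0.005, 0.05))
}

# independent brute-force gate oracle: histogram density ranking with the
# same grid definition, ordering events by (density desc, index asc)
oracle_gate <- function(fsc, ssc, fraction, nbins) {
  rx <- quantile(fsc, c(0.01, 0.99), names = FALSE)
  ry <- quantile(ssc, c(0.01, 0.99), names = FALSE)
  cut_idx <- function(v, r) {
    i <- findInterval(v, seq(r[1], r[2], length.out = nbins + 1),
                      rightmost.closed = TRUE)
    pmin(pmax(i, 1L), nbins)
  }
  key <- paste(cut_idx(fsc, rx), cut_idx(ssc, ry))
  dens <- as.vector(table(key)[key])
  sort(order(-dens, seq_along(fsc))[seq_len(ceiling(fraction * length(fsc)))])
}

# independent brute-force evaluation of the printed four-gene expansion
# epsilon'_ABCD = e_ABCD - triples + pairs, and of epsilon'_ABC
expansion_net <- function(M, summary) {
  eps <- function(S) overall_deviation(S, summary)$epsilon
  k <- length(M)
  subs <- unlist(lapply(2:k, function(m) utils::combn(M, m, simplify = FALSE)),
                 recursive = FALSE)
  sum(vapply(subs, function(S) (-1)^(k - length(S)) * eps(S), numeric(1)))
}
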