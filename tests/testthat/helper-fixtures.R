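# Shared fixtures, all generated in code. Expensive objects are built once
# per test run and memoised in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small GRM shared by several likelihood/fit tests
small_grm <- function(n = 300, m = 2000, seed = 7)
  fixture(sprintf("grm_%d_%d_%d", n, m, seed),
          function() grm_eigen(simulate_grm(n, m, seed = seed)))

# random sparse IP structure + admissible theta for property-style loops
random_ip_instance <- function(k, nA = 1, nE = 1, rge = FALSE) {
  st <- make_structure("ip", k, nA = nA, nE = nE, rge = rge)
  npar <- count_parameters(st)
  nm <- parameter_names(st)
  th <- numeric(npar)
  common <- grepl("^lambda[AE]_", nm)
  spec <- grepl("^lambda[AE]S_", nm)
  th[common] <- runif(sum(common), 0.2, 0.45)
  th[spec] <- runif(sum(spec), 0.3, 0.6)
  th[grepl("^rGE_", nm)] <- atanh(runif(sum(grepl("^rGE_", nm)), -0.6, 0.6))
  list(structure = st, theta = th)
}

# naive dense MVN log-density, independent of the package's chol routine
naive_mvn_loglik <- function(x, S) {
  p <- length(x)
  ld <- determinant(S, logarithm = TRUE)$modulus[1]
  as.numeric(-0.5 * (p * log(2 * pi) + ld + t(x) %*% solve(S) %*% x))
}

# exhaustive minimum vertex cover size for small graphs (adjacency matrix)
min_vertex_cover_size <- function(adj) {
  n <- nrow(adj)
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(edges) == 0) return(0L)
  for (size in 0:n) {
    for (set in utils::combn(n, size, simplify = FALSE)) {
      covered <- apply(edges, 1L, function(e) any(e %in% set))
      if (all(covered)) return(size)
    }
  }
  n
}
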