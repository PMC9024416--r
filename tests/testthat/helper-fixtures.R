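# small deterministic fixtures used across test files

toy_counts <- function() {
  m <- matrix(c(1, 2, 3,
                4, 5, 6), nrow = 2, byrow = TRUE)
  dimnames(m) <- list(c("s1", "s2"), c("otuA", "otuB", "otuC"))
  storage.mode(m) <- "integer"
  m
}

# balanced 4-taxon tree: ((A:1,B:1):1,(C:1,D:1):1);
toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

random_counts <- function(n_samples, n_otus, lambda = 10, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus)
    m[rowSums(m) == 0, 1] <- 1L
    dimnames(m) <- list(paste0("s", seq_len(n_samples)),
                        paste0("otu", seq_len(n_otus)))
    storage.mode(m) <- "integer"
    m
  })
}

# two well-separated compositional clusters
two_cluster_counts <- function(n_per = 4, n_otus = 20, shift = 6, seed = 1) {
  withr::with_seed(seed, {
    base1 <- exp(rnorm(n_otus)); base2 <- base1 * exp(c(rep(shift, 5),
                                                        rep(-shift, 5),
                                                        rep(0, n_otus - 10)))
    mk <- function(base, k) t(sapply(seq_len(k), function(i)
      rmultinom(1, 2000, base * exp(rnorm(n_otus, 0, 0.1)))[, 1]))
    m <- rbind(mk(base1, n_per), mk(base2, n_per))
    dimnames(m) <- list(paste0("s", seq_len(2 * n_per)),
                        paste0("otu", seq_len(n_otus)))
    storage.mode(m) <- "integer"
    m
  })
}

write_tsv_fixture <- function(m, path, id = "sample_id") {
  df <- data.frame(row = rownames(m), m, check.names = FALSE)
  names(df)[1] <- id
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# enumerate all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(assign, next_max) {
    k <- length(assign)
    if (k == n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (g in seq_len(next_max + 1L))
      grow(c(assign, g), max(next_max, g))
  }
  grow(integer(0), 0L)
  out
}

# Newman weighted modularity of a partition, computed from first principles
modularity_of <- function(adj, membership) {
  m2 <- sum(adj)                       # 2m for weighted graphs
  if (m2 == 0) return(NA_real_)
  k <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(ncol(adj)))
    if (membership[i] == membership[j])
      q <- q + adj[i, j] - k[i] * k[j] / m2
  q / m2
}
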