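# small hand-built survey tables used across test files

make_survey <- function(n_per_cluster = 3, clusters = 2, seed = 1,
                        region = NULL) {
  set.seed(seed)
  J <- clusters
  n <- n_per_cluster * J
  cl <- rep(seq_len(J), each = n_per_cluster)
  df <- data.frame(
    child_id = seq_len(n),
    cluster_id = cl,
    lon = c(10, 40, 70, 25, 55, 85)[cl %% 6 + 1] + cl,
    lat = c(20, 60, 30, 80, 50, 10)[cl %% 6 + 1] + 2 * cl,
    y_ari = rbinom(n, 1, 0.3),
    y_diarrhoea = rbinom(n, 1, 0.3),
    y_stunting = rbinom(n, 1, 0.3))
  if (!is.null(region)) df$region <- rep_len(region, n)
  survey_table(df)
}

# survey table realising a given 2x2 cross-table of two conditions
survey_from_2x2 <- function(tab) {
  y_a <- c(rep(0, tab[1, 1]), rep(0, tab[1, 2]),
           rep(1, tab[2, 1]), rep(1, tab[2, 2]))
  y_b <- c(rep(0, tab[1, 1]), rep(1, tab[1, 2]),
           rep(0, tab[2, 1]), rep(1, tab[2, 2]))
  n <- length(y_a)
  survey_table(data.frame(
    child_id = seq_len(n), cluster_id = rep(1:2, length.out = n),
    lon = rep(c(0, 10), length.out = n), lat = rep(c(0, 10), length.out = n),
    y_ari = y_a, y_diarrhoea = y_b, y_stunting = rep(0:1, length.out = n)))
}

region_counts_path <- function() {
  system.file("extdata", "somalia_region_counts.csv", package = "coregmap")
}
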