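# Small in-code fixtures shared across test files.

random_thickness_matrix <- function(n_subjects = 3, seed = 1) {
  atlas <- load_atlas()
  set.seed(seed)
  matrix(runif(n_subjects * 66, 2, 3), n_subjects, 66,
         dimnames = list(sprintf("s%02d", seq_len(n_subjects)),
                         atlas_region_keys(atlas)))
}

# fabricated MCN with every pair significant, for density arithmetic tests
fake_full_mcn <- function(n_regions = 66, seed = 3) {
  set.seed(seed)
  x <- matrix(rnorm(500 * n_regions), 500, n_regions)
  r <- cor(x)
  regions <- sprintf("R%02d", seq_len(n_regions))
  dimnames(r) <- list(regions, regions)
  sig <- matrix(TRUE, n_regions, n_regions)
  diag(sig) <- FALSE
  structure(list(r = r, p = matrix(0, n_regions, n_regions),
                 sig_mask = sig, n_subjects = 500, alpha = 0.05,
                 regions = regions),
            class = "mcn")
}

path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

star_graph <- function(n) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}

complete_graph <- function(n) {
  a <- matrix(1, n, n)
  diag(a) <- 0
  a
}
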